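# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded internals never
#' perturb the global random stream. A NULL seed evaluates the expression
#' with the current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for replicate k of a master seed. Chosen so that
# changing the number of replicates never reshuffles earlier replicates.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) %% 2147483647 + 1664525 * as.numeric(k)) %% 2147483647
}

# Basal area of a stem in cm^2 from its dbh in cm.
basal_area_cm2 <- function(dbh_cm) pi * (dbh_cm / 2)^2
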