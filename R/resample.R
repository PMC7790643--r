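# Subsampled significance engine: paired tests on per-cell statistics
# recomputed over repeated within-cell grid-point subsamples.

#' Specify a grid-point subsampling scheme
#'
#' Controls the resampling protocol used to even out sampling effort across
#' cells: in every replicate, `n` grid points are drawn without replacement
#' inside each cell, the per-cell statistic is recomputed on that subsample,
#' the paired test is run across cells, and the p-value collected; the mean
#' of the `r` p-values is the reported statistic.
#'
#' @param n grid points drawn per cell (default 10).
#' @param r number of replicates (default 1000).
#' @param seed master seed; replicate `k` uses an independent child stream so
#'   `r` can be increased without reshuffling earlier replicates.
#' @param pairing `"matched_points"` (default) draws the same point ids in
#'   both periods; `"independent"` draws separately per period.
#' @return a list of class `subsample_spec`.
#' @export
subsample_spec <- function(n = 10, r = 1000, seed = NULL,
                           pairing = c("matched_points", "independent")) {
  pairing <- match.arg(pairing)
  if (!is.numeric(n) || n < 1) stop("config error: n must be >= 1")
  if (!is.numeric(r) || r < 1) stop("config error: r must be >= 1")
  structure(list(n = as.integer(n), r = as.integer(r), seed = seed,
                 pairing = pairing), class = "subsample_spec")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired samples. Zero differences are
#' dropped (classical Wilcoxon treatment); the exact null distribution is
#' used when there are at most 25 nonzero untied differences, otherwise the
#' normal approximation with tie and continuity correction. If every
#' difference is zero the test is undefined and p = 1 is returned.
#'
#' @param x,y equal-length numeric vectors of per-cell values (periods 1, 2).
#' @return two-sided p-value in `[0, 1]`.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- y - x
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' Paired Student t test
#'
#' Two-sided p-value on the mean paired difference. With zero variance of
#' the differences the statistic is undefined: p = 1 when the common
#' difference is 0, otherwise p = 0 (flagged with attribute `degenerate`).
#'
#' @param x,y equal-length numeric vectors, length at least 2.
#' @return two-sided p-value in `[0, 1]`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- y - x
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(structure(p, degenerate = TRUE))
  }
  stats::t.test(d)$p.value
}

test_fun <- function(test) {
  switch(test,
         paired_wilcoxon = paired_wilcoxon,
         paired_t = paired_t,
         stop("unknown test: ", test))
}

# Draw the per-cell point subsets for replicate k. Cells are visited in
# sorted name order (and point ids sorted within cells) so the draw -- and
# hence every downstream statistic -- is invariant to the ordering of the
# cells argument.
draw_subsample <- function(cells, spec, k) {
  ord <- order(names(cells))
  with_seed(child_seed(spec$seed, k), {
    ids1 <- ids2 <- vector("list", length(cells))
    names(ids1) <- names(ids2) <- names(cells)
    for (i in ord) ids1[[i]] <- sample(sort(cells[[i]]), spec$n)
    if (spec$pairing == "matched_points") ids2 <- ids1
    else for (i in ord) ids2[[i]] <- sample(sort(cells[[i]]), spec$n)
    list(ids1 = ids1, ids2 = ids2)
  })
}

# Core engine: stat_fun(records, ids_by_cell) must return a cells x K matrix
# (or a vector for K = 1) of per-cell statistics. Returns the r x K matrix of
# p-values plus per-replicate effect signs.
subsample_engine <- function(records_t1, records_t2, cells, stat_fun,
                             test = "paired_wilcoxon",
                             spec = subsample_spec()) {
  cells <- as_cells(cells)
  short <- lengths(cells) < spec$n
  if (any(short))
    stop("cell with fewer than n = ", spec$n, " points: ",
         names(cells)[short][1])
  tf <- test_fun(test)
  p <- NULL
  sg <- NULL
  for (k in seq_len(spec$r)) {
    ids <- draw_subsample(cells, spec, k)
    X <- stat_fun(records_t1, ids$ids1)
    Y <- stat_fun(records_t2, ids$ids2)
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (is.null(p)) {
      p <- matrix(NA_real_, spec$r, ncol(X),
                  dimnames = list(NULL, colnames(X)))
      sg <- p
    }
    for (j in seq_len(ncol(X))) {
      p[k, j] <- tf(X[, j], Y[, j])
      sg[k, j] <- sign(mean(Y[, j] - X[, j]))
    }
  }
  list(p = p, sign = sg)
}

#' Subsampled paired test of temporal change in one statistic
#'
#' Runs the subsampling protocol around a paired test for a single per-cell
#' statistic and returns the distribution of replicate p-values.
#'
#' @param records_t1,records_t2 record data frames for the two periods
#'   (same cohort, retained species).
#' @param cells a `fishnet` or named list of point ids per cell; every cell
#'   must hold at least `spec$n` points.
#' @param stat_fun function `(records, ids_by_cell) -> numeric per cell`,
#'   e.g. from [stat_species()].
#' @param test `"paired_wilcoxon"` or `"paired_t"`.
#' @param spec a [subsample_spec()].
#' @return object of class `pvalue_dist`: the replicate `p_values`, their
#'   mean (`mean_p`, the headline statistic), the 2.5/50/97.5 percent
#'   quantiles, and `effect_sign` (median over replicates of the sign of the
#'   mean per-cell change).
#' @export
subsample_test <- function(records_t1, records_t2, cells, stat_fun,
                           test = c("paired_wilcoxon", "paired_t"),
                           spec = subsample_spec()) {
  test <- match.arg(test)
  out <- subsample_engine(records_t1, records_t2, cells, stat_fun, test, spec)
  new_pvalue_dist(out$p[, 1], out$sign[, 1], spec, test)
}

new_pvalue_dist <- function(p, sg, spec, test) {
  q <- stats::quantile(p, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(p_values = p, mean_p = mean(p),
                 q025 = q[1], q500 = q[2], q975 = q[3],
                 effect_sign = stats::median(sg),
                 n = spec$n, r = spec$r, seed = spec$seed,
                 pairing = spec$pairing, test = test),
            class = "pvalue_dist")
}

#' @export
print.pvalue_dist <- function(x, ...) {
  cat(sprintf(
    "Subsampled %s (n = %d, r = %d): mean p = %.4g [%.4g, %.4g], effect sign %+d\n",
    x$test, x$n, x$r, x$mean_p, x$q025, x$q975, as.integer(x$effect_sign)))
  invisible(x)
}

#' Per-cell statistic builder for species or pooled groups
#'
#' Returns a closure computing, for each cell and each group of species, the
#' chosen measure on a grid-point subsample. Group values are sums of member
#' species values (counts and basal area are summed before normalization for
#' relative abundance), so a single-species group is the species itself.
#'
#' @param groups named list of character vectors of species codes (or a
#'   character vector of single species).
#' @param measure `"occurrence"`, `"relative_abundance"` or `"basal_area"`.
#' @return function `(records, ids_by_cell) -> cells x groups matrix`.
#' @export
stat_species <- function(groups, measure = c("occurrence",
                                             "relative_abundance",
                                             "basal_area")) {
  measure <- match.arg(measure)
  if (is.character(groups)) groups <- stats::setNames(as.list(groups), groups)
  all_sp <- sort(unique(unlist(groups)))
  function(records, ids) {
    m <- community_matrix(records, ids, measure = measure, species = all_sp)
    vals <- vapply(groups,
                   function(g) rowSums(as.matrix(m)[, g, drop = FALSE]),
                   numeric(length(ids)))
    matrix(vals, nrow = length(ids), ncol = length(groups),
           dimnames = list(names(ids), names(groups)))
  }
}

#' Subsampled change tests for every species
#'
#' Applies the subsampling protocol once (shared subsamples across species)
#' and tests each species' per-cell values between periods.
#'
#' @inheritParams subsample_test
#' @param species character vector of species codes to test.
#' @param measure per-cell measure, see [community_matrix()].
#' @return data frame with one row per species: `species_or_group`,
#'   `measure`, `mean_p`, `q025`, `q500`, `q975`, `effect_sign`, `n`, `r`.
#' @export
species_change_tests <- function(records_t1, records_t2, cells, species,
                                 measure = "occurrence",
                                 test = "paired_wilcoxon",
                                 spec = subsample_spec()) {
  sf <- stat_species(species, measure)
  out <- subsample_engine(records_t1, records_t2, cells, sf, test, spec)
  summarize_pmatrix(out, species, measure, spec)
}

summarize_pmatrix <- function(out, groups, measure, spec) {
  q <- apply(out$p, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(species_or_group = groups,
             measure = measure,
             mean_p = colMeans(out$p),
             q025 = q[1, ], q500 = q[2, ], q975 = q[3, ],
             effect_sign = apply(out$sign, 2, stats::median),
             n = spec$n, r = spec$r,
             seed = if (is.null(spec$seed)) NA_real_ else spec$seed,
             stringsAsFactors = FALSE, row.names = NULL)
}
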