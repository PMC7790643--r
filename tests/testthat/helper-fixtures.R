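# Shared fixtures, all built in code.

# Minimal complete survey: one grid point sampled in both periods, all four
# quadrants, one mature tree each.
tiny_survey_df <- function() {
  data.frame(
    point_id = "P001", x = 0, y = 0,
    period = rep(c("T1", "T2"), each = 4),
    quadrant = rep(1:4, 2),
    species = c("ACRU", "PIST", "FRAM", "ACSA2", "ACRU", "ACRU", "QURU",
                "FAGR"),
    dbh_cm = c(12, 25, 30.5, 11, 14, 40, 18, 22),
    distance_m = c(2.5, 3.1, 0.8, 6.2, 1.9, 4.4, 2.2, 5.0),
    stringsAsFactors = FALSE)
}

write_tiny_survey <- function(df = tiny_survey_df()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Random community matrix with positive row sums and some variation.
random_community <- function(n_cells, n_species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_cells * n_species, 3), n_cells, n_species,
              dimnames = list(sprintf("C%02d", seq_len(n_cells)),
                              sprintf("SP%02d", seq_len(n_species))))
  zero <- rowSums(m) == 0
  m[zero, 1] <- 1
  if (all(apply(m, 2, function(v) length(unique(v)) == 1))) m[1, 1] <- m[1, 1] + 1
  m
}

# Small default simulation used across tests: 20 cells x 12 stakes.
small_sim <- function(seed = 42, ...) {
  simulate_resurvey(scenario_config(seed = seed, ...))
}

small_fishnet <- function(sim) {
  build_fishnet(sim$points, mesh_x = 200, mesh_y = 300, offsets = 0)
}

# Cohort/period record split for a simulation.
sim_records <- function(sim, cohort = "mature") {
  rec <- split_cohorts(sim$records)[[cohort]]
  list(t1 = rec[rec$period == "T1", ], t2 = rec[rec$period == "T2", ],
       species = sort(unique(rec$species)))
}

# Exact two-sided signed-rank p-value by enumeration of all sign
# assignments of the absolute differences (independent oracle).
wilcoxon_sign_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
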