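# Synthetic two-period point-quarter resurvey generator: species pools with
# correlated traits, smooth spatial intensity fields, scenario transforms
# (turnover, homogenization, differentiation, abundance and trait shifts),
# and exact sampling of the nearest-tree-per-quadrant protocol.

#' Generate a synthetic species pool
#'
#' Draws species with guild labels, tolerance scores on `[1, 5]` (shade and
#' drought negatively correlated through a Gaussian copula), log-normal seed
#' masses, temperature preferences, and baseline regional relative
#' intensities with a log-normal rank-abundance structure.
#'
#' @param n_species number of species (>= 2).
#' @param guild_mix named proportions for `northern`, `central`,
#'   `carolinian`; allocated deterministically (largest remainder).
#' @param rho strength of the negative shade-drought correlation in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @return data frame of class `species_pool`: `species`, `guild`, `shade`,
#'   `drought`, `waterlogging`, `seed_mass_mg`, `temp_pref_c`, `intensity`
#'   (baseline shares summing to 1).
#' @export
make_species_pool <- function(n_species = 15,
                              guild_mix = c(northern = 0.5, central = 0.3,
                                            carolinian = 0.2),
                              rho = 0.5, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species")
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("config error: rho must lie in [0, 1]")
  guild_mix <- guild_mix / sum(guild_mix)
  counts <- floor(guild_mix * n_species)
  rem <- n_species - sum(counts)
  if (rem > 0) {
    extra <- order(guild_mix * n_species - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  with_seed(seed, {
    z1 <- stats::rnorm(n_species)
    z2 <- -rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_species)
    w <- stats::rlnorm(n_species, 0, 1)
    pool <- data.frame(
      species = sprintf("SP%02d", seq_len(n_species)),
      guild = rep(names(counts), counts),
      shade = 1 + 4 * stats::pnorm(z1),
      drought = 1 + 4 * stats::pnorm(z2),
      waterlogging = stats::runif(n_species, 1, 5),
      seed_mass_mg = stats::rlnorm(n_species, log(50), 1.5),
      temp_pref_c = stats::rnorm(n_species, 7.5, 1.5),
      intensity = w / sum(w),
      stringsAsFactors = FALSE)
    class(pool) <- c("species_pool", "data.frame")
    pool
  })
}

#' Trait table of a species pool
#' @param pool a `species_pool`.
#' @return trait data frame in the format of [read_traits()].
#' @export
pool_traits <- function(pool) {
  data.frame(species = pool$species, shade = pool$shade,
             drought = pool$drought, waterlogging = pool$waterlogging,
             seed_mass_mg = pool$seed_mass_mg, temp_pref_c = pool$temp_pref_c,
             stringsAsFactors = FALSE)
}

#' Guild table of a species pool
#' @param pool a `species_pool`.
#' @return guild data frame in the format of [read_guilds()].
#' @export
pool_guilds <- function(pool) {
  data.frame(species = pool$species, guild = pool$guild,
             stringsAsFactors = FALSE)
}

#' Configure a synthetic resurvey scenario
#'
#' Defines the stake lattice (50 m within rows, 100 m between rows by
#' default), the spatial structure of the intensity fields, the cohort dbh
#' models and densities, the period-1 start-point jitter, and the temporal
#' scenario applied to the second period:
#' \describe{
#'   \item{null}{an independent realization of the same spatial process;}
#'   \item{turnover}{cyclic relabelling of species within spatial blocks
#'     (preserves local diversity, pure replacement);}
#'   \item{homogenization}{cell profiles shrunk toward the regional mean by
#'     `lambda`;}
#'   \item{differentiation}{deviations from the regional mean inflated by
#'     `1 + lambda`;}
#'   \item{abundance_shift}{target species (or guild) intensities multiplied
#'     by `multiplier`, others renormalized;}
#'   \item{trait_shift}{per-stake composition exponentially tilted so the
#'     stake-level CWM of `trait` shifts by exactly `shift`.}
#' }
#'
#' @param scenario scenario name.
#' @param lambda effect size in `[0, 1]` for
#'   homogenization/differentiation.
#' @param target_species,target_guild target of `abundance_shift`.
#' @param multiplier intensity multiplier for `abundance_shift`.
#' @param trait,shift trait name and CWM shift for `trait_shift`.
#' @param n_rows,n_cols stake lattice dimensions.
#' @param col_spacing,row_spacing stake spacing (m) within and between rows.
#' @param smoothness length scale (m) of the Gaussian intensity bumps.
#' @param field_sd log-intensity field amplitude.
#' @param n_bumps Gaussian bumps per species field.
#' @param jitter_t1 mean period-1 start-point displacement (m), default
#'   7.41; direction uniform, length exponential.
#' @param density stems per m^2 per cohort.
#' @param window_radius radius (m) of the Poisson window searched around a
#'   start point.
#' @param dbh list of cohort log-normal dbh parameters (mature truncated at
#'   `[10, Inf)`, sapling at `(0, 10)`).
#' @param block_mesh block size (m) for the turnover relabelling.
#' @param cohorts cohorts the scenario transform is applied to.
#' @param seed master seed for the whole generate path.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("null", "turnover", "homogenization",
                                         "differentiation", "abundance_shift",
                                         "trait_shift"),
                            lambda = 0, target_species = NULL,
                            target_guild = NULL, multiplier = 2,
                            trait = "shade", shift = 0.5,
                            n_rows = 12, n_cols = 20,
                            col_spacing = 50, row_spacing = 100,
                            smoothness = 20, field_sd = 2, n_bumps = 500,
                            jitter_t1 = 7.41,
                            density = c(mature = 0.04, sapling = 0.04),
                            window_radius = 25,
                            dbh = list(mature = c(meanlog = 3.2, sdlog = 0.5),
                                       sapling = c(meanlog = 1.2, sdlog = 0.5)),
                            block_mesh = c(200, 300),
                            cohorts = c("mature", "sapling"),
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("config error: lambda must lie in [0, 1]")
  structure(list(scenario = scenario, lambda = lambda,
                 target_species = target_species, target_guild = target_guild,
                 multiplier = multiplier, trait = trait, shift = shift,
                 n_rows = n_rows, n_cols = n_cols,
                 col_spacing = col_spacing, row_spacing = row_spacing,
                 smoothness = smoothness, field_sd = field_sd,
                 n_bumps = n_bumps, jitter_t1 = jitter_t1,
                 density = density, window_radius = window_radius,
                 dbh = dbh, block_mesh = block_mesh, cohorts = cohorts,
                 seed = seed),
            class = "scenario_config")
}

# Smooth log-intensity field: sum of Gaussian bumps with random centres and
# weights, evaluated at the given coordinates.
gauss_field <- function(at, extent, ell, sd_, k) {
  cx <- stats::runif(k, extent[1], extent[2])
  cy <- stats::runif(k, extent[3], extent[4])
  w <- stats::rnorm(k)
  f <- numeric(nrow(at))
  for (j in seq_len(k))
    f <- f + w[j] * exp(-((at[, 1] - cx[j])^2 + (at[, 2] - cy[j])^2) /
                          (2 * ell^2))
  sd_ * f
}

# Per-start-point species shares for one period: baseline intensities
# modulated by independent short-range fields (gap-scale patch mosaic).
# The field's correlation range is deliberately short relative to the cell
# mesh so cell-level composition deviations are approximately independent:
# a long-range field would act as a period-level regional shift, which is
# confounded with every scenario effect and breaks the exchangeability of
# the null.
base_shares <- function(pool, cfg, at, extent) {
  S <- nrow(pool)
  f <- vapply(seq_len(S), function(s)
    gauss_field(as.matrix(at), extent, cfg$smoothness, cfg$field_sd,
                cfg$n_bumps),
    numeric(nrow(at)))
  raw <- sweep(exp(f), 2, pool$intensity, "*")
  raw / rowSums(raw)
}

# Scenario transform of the period-2 share matrix (points x species).
apply_scenario <- function(p2, pool, cfg, pts) {
  switch(cfg$scenario,
    null = p2,
    homogenization = {
      pbar <- colMeans(p2)
      (1 - cfg$lambda) * p2 + cfg$lambda * rep(pbar, each = nrow(p2))
    },
    differentiation = {
      pbar <- colMeans(p2)
      out <- pmax(rep(pbar, each = nrow(p2)) +
                    (1 + cfg$lambda) * sweep(p2, 2, pbar), 0)
      out / rowSums(out)
    },
    turnover = {
      bx <- floor((pts$x - min(pts$x)) / cfg$block_mesh[1])
      by <- floor((pts$y - min(pts$y)) / cfg$block_mesh[2])
      block <- as.integer(factor(paste(bx, by)))
      S <- ncol(p2)
      k <- block %% (S - 1) + 1          # nonzero shift per block
      out <- p2
      for (b in unique(k)) {
        i <- which(k == b)
        out[i, ] <- p2[i, (seq_len(S) - 1 + b) %% S + 1]
      }
      out
    },
    abundance_shift = {
      targets <- cfg$target_species
      if (!is.null(cfg$target_guild))
        targets <- union(targets, pool$species[pool$guild %in% cfg$target_guild])
      if (length(targets) == 0) stop("abundance_shift needs a target")
      j <- pool$species %in% targets
      p2[, j] <- p2[, j] * cfg$multiplier
      p2 / rowSums(p2)
    },
    trait_shift = {
      t_j <- trait_values(pool_traits(pool), cfg$trait)[pool$species]
      tilt_shares(p2, t_j, cfg$shift)
    })
}

# Exponential tilt of each row so its trait-weighted mean moves by delta.
tilt_shares <- function(p, t_j, delta) {
  out <- p
  for (i in seq_len(nrow(p))) {
    pi_ <- p[i, ]
    cwm0 <- sum(pi_ * t_j)
    target <- cwm0 + delta
    if (target >= max(t_j[pi_ > 0])) {  # unattainable: all mass on max trait
      out[i, ] <- as.numeric(t_j == max(t_j[pi_ > 0])) * pi_
      out[i, ] <- out[i, ] / sum(out[i, ])
      next
    }
    f <- function(b) {
      q <- pi_ * exp(b * (t_j - cwm0))
      sum(q * t_j) / sum(q) - target
    }
    b <- stats::uniroot(f, c(0, 5), extendInt = "upX", tol = 1e-10)$root
    q <- pi_ * exp(b * (t_j - cwm0))
    out[i, ] <- q / sum(q)
  }
  out
}

#' Simulate per-stake species intensities for both periods
#'
#' Draws the stake lattice, the period start points (period 1 displaced from
#' the stakes by the configured jitter, period 2 at the stakes), independent
#' smooth intensity fields per period, and applies the scenario transform to
#' the second period for the configured cohorts.
#'
#' @param pool a `species_pool`.
#' @param cfg a [scenario_config()] (its `seed` drives everything).
#' @return list with `points` (stake table), `start` (per-period sampling
#'   start coordinates), `shares` (per period and cohort: points x species
#'   share matrices), `pool`, `config`.
#' @export
simulate_intensities <- function(pool, cfg = scenario_config()) {
  with_seed(cfg$seed, {
    pts <- expand.grid(col = seq_len(cfg$n_cols) - 1,
                       row = seq_len(cfg$n_rows) - 1,
                       KEEP.OUT.ATTRS = FALSE)
    points <- data.frame(
      point_id = sprintf("P%03d", seq_len(nrow(pts))),
      x = pts$col * cfg$col_spacing,
      y = pts$row * cfg$row_spacing, stringsAsFactors = FALSE)
    extent <- c(min(points$x), max(points$x), min(points$y), max(points$y))
    n <- nrow(points)
    ang <- stats::runif(n, 0, 2 * pi)
    len <- stats::rexp(n, 1 / cfg$jitter_t1)
    start <- list(
      T1 = cbind(x = points$x + len * cos(ang), y = points$y + len * sin(ang)),
      T2 = cbind(x = points$x, y = points$y))
    p1 <- base_shares(pool, cfg, start$T1, extent)
    p2 <- base_shares(pool, cfg, start$T2, extent)
    p2s <- apply_scenario(p2, pool, cfg, points)
    shares <- list(
      T1 = list(mature = p1, sapling = p1),
      T2 = list(mature = if ("mature" %in% cfg$cohorts) p2s else p2,
                sapling = if ("sapling" %in% cfg$cohorts) p2s else p2))
    list(points = points, start = start, shares = shares, pool = pool,
         config = cfg)
  })
}

# Truncated log-normal dbh sampler via inverse CDF.
rdbh <- function(n, cohort, dbh_par) {
  p <- dbh_par[[cohort]]
  cut <- stats::plnorm(10, p["meanlog"], p["sdlog"])
  u <- if (cohort == "mature") stats::runif(n, cut, 1)
       else stats::runif(n, 0, cut)
  stats::qlnorm(u, p["meanlog"], p["sdlog"])
}

#' Sample point-quarter tree records from simulated intensities
#'
#' Realizes the nearest tree in each of the four quadrants around every
#' start point, per period and cohort, from a marked Poisson process of the
#' configured density within the 25 m window: the quadrant count is Poisson,
#' the nearest distance is drawn exactly as `R * sqrt(Beta(1, N))` given `N`
#' trees, the species follows the local intensity shares, and dbh comes from
#' the cohort's truncated log-normal model. Quadrants whose window holds no
#' tree are omitted (and counted in attribute `n_omitted`), mirroring
#' missing-corner field reality.
#'
#' @param intens output of [simulate_intensities()].
#' @param seed RNG seed (defaults to a child of the config seed).
#' @return record data frame in the [read_survey()] schema; at most 4
#'   records per (point, period, cohort).
#' @export
sample_point_quarter <- function(intens, seed = NULL) {
  cfg <- intens$config
  if (is.null(seed)) seed <- child_seed(cfg$seed, 777)
  with_seed(seed, {
    out <- list()
    n_omitted <- 0L
    npts <- nrow(intens$points)
    qarea <- pi * cfg$window_radius^2 / 4
    for (period in c("T1", "T2")) {
      for (cohort in c("mature", "sapling")) {
        lam <- cfg$density[[cohort]] * qarea
        N <- stats::rpois(npts * 4, lam)
        keep <- N > 0
        n_omitted <- n_omitted + sum(!keep)
        idx <- rep(seq_len(npts), each = 4)[keep]
        quad <- rep(1:4, npts)[keep]
        m <- sum(keep)
        dist <- cfg$window_radius * sqrt(stats::rbeta(m, 1, N[keep]))
        shares <- intens$shares[[period]][[cohort]]
        cum <- t(apply(shares, 1, cumsum))
        cum[, ncol(cum)] <- 1   # guard against rounding in the last bin
        u <- stats::runif(m)
        sp_idx <- max.col(cum[idx, , drop = FALSE] >= u, ties.method = "first")
        out[[paste(period, cohort)]] <- data.frame(
          point_id = intens$points$point_id[idx],
          x = intens$points$x[idx], y = intens$points$y[idx],
          period = period, quadrant = quad,
          species = intens$pool$species[sp_idx],
          dbh_cm = rdbh(m, cohort, cfg$dbh),
          distance_m = dist, stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, out)
    rownames(rec) <- NULL
    structure(rec, n_omitted = n_omitted)
  })
}

#' Simulate a complete two-period point-quarter resurvey
#'
#' Convenience wrapper: builds (or accepts) a species pool, simulates the
#' intensity surfaces under the scenario, and samples the tree records.
#' Fully deterministic under the config seed.
#'
#' @param config a [scenario_config()].
#' @param pool optional `species_pool`; by default one is drawn from a child
#'   seed of the config seed.
#' @return object of class `pq_simulation`: `points`, `records`,
#'   `intensities` (ground truth), `pool`, `config`.
#' @export
simulate_resurvey <- function(config = scenario_config(), pool = NULL) {
  if (is.null(pool))
    pool <- make_species_pool(seed = child_seed(config$seed, 1))
  intens <- simulate_intensities(pool, config)
  records <- sample_point_quarter(intens)
  structure(list(points = intens$points, records = records,
                 intensities = intens, pool = pool, config = config),
            class = "pq_simulation")
}

#' @export
print.pq_simulation <- function(x, ...) {
  cat("Synthetic point-quarter resurvey:", nrow(x$records), "records at",
      nrow(x$points), "stakes;", nrow(x$pool), "species; scenario",
      x$config$scenario,
      if (x$config$scenario %in% c("homogenization", "differentiation"))
        sprintf("(lambda = %g)", x$config$lambda) else "", "\n")
  invisible(x)
}

#' Write a simulation to survey/trait/guild CSV files
#'
#' Emits `survey.csv`, `traits.csv` and `guilds.csv` in the schemas consumed
#' by [read_survey()], [read_traits()] and [read_guilds()], plus a
#' `truth.json` sidecar with the scenario configuration.
#'
#' @param sim a `pq_simulation`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey(sim$records, file.path(dir, "survey.csv"))
  utils::write.csv(pool_traits(sim$pool), file.path(dir, "traits.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(pool_guilds(sim$pool), file.path(dir, "guilds.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  cfg$dbh <- lapply(cfg$dbh, as.list)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' True per-cell composition profiles of a simulation
#'
#' Averages the noiseless per-stake intensity shares over the member stakes
#' of each fishnet cell.
#'
#' @param sim a `pq_simulation`.
#' @param fishnet a [build_fishnet()] result on the simulation's stakes.
#' @param period `"T1"` or `"T2"`.
#' @param cohort `"mature"` or `"sapling"`.
#' @return cells x species matrix of mean shares.
#' @export
true_cell_profiles <- function(sim, fishnet, period = "T2",
                               cohort = "mature") {
  shares <- sim$intensities$shares[[period]][[cohort]]
  rownames(shares) <- sim$points$point_id
  cells <- as_cells(fishnet)
  prof <- t(vapply(cells, function(p)
    colMeans(shares[p, , drop = FALSE]), numeric(ncol(shares))))
  colnames(prof) <- sim$pool$species
  prof
}

#' Noiseless multivariate dispersion of a simulation
#'
#' Mean Hellinger distance of true cell profiles to their centroid, per
#' period; a direct computation on the intensities with no sampling noise,
#' used for scenario diagnostics.
#'
#' @inheritParams true_cell_profiles
#' @return named numeric vector, one value per period.
#' @export
true_dispersion <- function(sim, fishnet, cohort = "mature") {
  vapply(c("T1", "T2"), function(per) {
    h <- hellinger(true_cell_profiles(sim, fishnet, per, cohort))
    ctr <- colMeans(h)
    mean(sqrt(rowSums(sweep(h, 2, ctr)^2)))
  }, numeric(1))
}

#' Rejection-rate calibration experiment
#'
#' Generates repeated synthetic resurveys under a scenario grid, runs the
#' dispersion test, PERMANOVA and the subsampled univariate engine on each,
#' and tabulates rejection rates at the given level with 95 percent binomial
#' confidence intervals. The dispersion/PERMANOVA rates use the direct
#' (unsubsampled) permutation p-values; the univariate rate uses the
#' subsampled mean p of the most abundant species' relative abundance.
#'
#' @param scenario scenario name, see [scenario_config()].
#' @param lambda vector of effect sizes to sweep.
#' @param n_datasets simulated datasets per grid cell.
#' @param alpha rejection level.
#' @param n_perm permutations for the dispersion/PERMANOVA tests.
#' @param spec [subsample_spec()] for the univariate engine.
#' @param cohort cohort analysed.
#' @param mesh fishnet mesh (m) used to group stakes into cells.
#' @param seed master seed; dataset `k` uses an independent child stream.
#' @param ... further arguments passed to [scenario_config()].
#' @return data frame with one row per (lambda, test): rejection rate,
#'   binomial CI, and for the dispersion test the share of datasets
#'   reporting the homogenization direction.
#' @export
run_calibration <- function(scenario = "null", lambda = 0, n_datasets = 200,
                            alpha = 0.05, n_perm = 199,
                            spec = subsample_spec(n = 10, r = 30),
                            cohort = "mature", mesh = c(200, 300),
                            seed = NULL, ...) {
  rows <- list()
  for (lam in lambda) {
    rej <- matrix(FALSE, n_datasets, 3,
                  dimnames = list(NULL, c("dispersion", "permanova",
                                          "subsample")))
    homog <- logical(n_datasets)
    for (k in seq_len(n_datasets)) {
      dseed <- child_seed(seed, (which(lambda == lam) - 1) * n_datasets + k)
      cfg <- scenario_config(scenario = scenario, lambda = lam, seed = dseed,
                             ...)
      sim <- simulate_resurvey(cfg)
      ana <- calibrate_one(sim, cohort, mesh, n_perm, spec, dseed)
      rej[k, ] <- c(ana$p_disp <= alpha, ana$p_perma <= alpha,
                    ana$mean_p < alpha)
      homog[k] <- ana$direction == "homogenization"
    }
    ci <- apply(rej, 2, function(v) {
      ok <- sum(v)
      c(rate = mean(v), stats::binom.test(ok, n_datasets)$conf.int)
    })
    rows[[length(rows) + 1]] <- data.frame(
      scenario = scenario, lambda = lam,
      test = colnames(rej), rejection_rate = ci[1, ],
      ci_lo = ci[2, ], ci_hi = ci[3, ],
      homogenization_rate = mean(homog), n_datasets = n_datasets,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

# One calibration analysis: direct dispersion/PERMANOVA across periods plus
# the subsampled Wilcoxon on the most abundant species.
calibrate_one <- function(sim, cohort, mesh, n_perm, spec, seed) {
  fn <- build_fishnet(sim$points, mesh_x = mesh[1], mesh_y = mesh[2],
                      offsets = 0)
  split_rec <- split_cohorts(sim$records)
  rec <- split_rec[[cohort]]
  r1 <- rec[rec$period == "T1", ]
  r2 <- rec[rec$period == "T2", ]
  sp <- sort(unique(rec$species))
  m1 <- community_matrix(r1, fn, "relative_abundance", species = sp)
  m2 <- community_matrix(r2, fn, "relative_abundance", species = sp)
  h <- hellinger(rbind(m1, m2))
  d <- stats::dist(h)
  grp <- factor(rep(c("T1", "T2"), each = nrow(m1)))
  dt <- dispersion_test(d, grp, n_perm = n_perm, seed = child_seed(seed, 11))
  pm <- permanova(d, grp, n_perm = n_perm, seed = child_seed(seed, 12))
  top <- names(which.max(colSums(m1 + m2)))
  spec$seed <- child_seed(seed, 13)
  st <- subsample_test(r1, r2, fn, stat_species(top, "relative_abundance"),
                       test = "paired_wilcoxon", spec = spec)
  list(p_disp = dt$p_perm, p_perma = pm$p_perm, direction = dt$direction,
       mean_p = st$mean_p)
}
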