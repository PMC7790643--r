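# End-to-end analysis: ingest -> matrices -> subsampled tests ->
# beta-diversity -> traits -> report bundle.

#' Default analysis configuration
#'
#' Returns the full configuration list consumed by [run_analysis()], with
#' the study-protocol defaults: mature/sapling split at 10 cm dbh, 1 percent
#' rare-species screen over both periods, fishnet optimized over the given
#' candidate meshes with at least 10 points per cell, n = 10 points
#' subsampled per cell over r = 1000 replicates, and 9999 permutations for
#' the multivariate tests. Any element can be overridden via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    survey = NULL, traits = NULL, guilds = NULL,
    pooling = character(0),
    cohort_threshold = 10,
    min_fraction = 0.01,
    fishnet = list(mesh_x = c(100, 150, 200, 250, 300),
                   mesh_y = c(100, 150, 200, 250, 300),
                   offsets = c(0, 0.25, 0.5, 0.75), min_points = 10),
    subsample = list(n = 10, r = 1000, pairing = "matched_points"),
    n_perm = 9999,
    measures = c("occurrence", "relative_abundance", "basal_area"),
    traits_tested = TRAIT_NAMES,
    beta_family = "podani",
    cohorts = c("mature", "sapling"),
    seed = NULL,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read an analysis configuration file
#'
#' YAML key/value document mirroring [default_config()]; unspecified keys
#' keep their defaults. Relative input paths are resolved against the
#' config file's directory.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- do.call(default_config, y)
  base <- dirname(normalizePath(path))
  for (key in c("survey", "traits", "guilds")) {
    p <- cfg[[key]]
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      cfg[[key]] <- file.path(base, p)
  }
  if (!is.null(cfg$pooling)) cfg$pooling <- unlist(cfg$pooling)
  cfg
}

resolve_inputs <- function(config) {
  sv <- config$survey
  if (is.null(sv)) stop("config error: no survey input")
  if (inherits(sv, "pq_simulation")) {
    points <- sv$points
    records <- sv$records
    if (is.null(config$traits)) config$traits <- pool_traits(sv$pool)
    if (is.null(config$guilds)) config$guilds <- pool_guilds(sv$pool)
  } else {
    if (is.character(sv)) sv <- read_survey(sv, config$cohort_threshold)
    if (!inherits(sv, "pq_survey")) stop("config error: unusable survey input")
    points <- sv$points
    records <- sv$records
  }
  traits <- config$traits
  if (is.character(traits)) traits <- read_traits(traits)
  guilds <- config$guilds
  if (is.character(guilds)) guilds <- read_guilds(guilds)
  if (is.null(traits) || is.null(guilds))
    stop("config error: trait and guild tables are required")
  list(points = points, records = records, traits = validate_traits(traits),
       guilds = guilds)
}

# Subsampled protocol wrapped around the multivariate tests: per replicate,
# rebuild the relative-abundance matrices from the subsample, then run the
# dispersion test and PERMANOVA on Hellinger distances.
subsampled_multivariate <- function(r1, r2, cells, species, spec, n_perm) {
  cells <- as_cells(cells)
  p_disp <- p_perma <- numeric(spec$r)
  dir_homog <- logical(spec$r)
  for (k in seq_len(spec$r)) {
    ids <- draw_subsample(cells, spec, k)
    m1 <- community_matrix(r1, ids$ids1, "relative_abundance",
                           species = species)
    m2 <- community_matrix(r2, ids$ids2, "relative_abundance",
                           species = species)
    d <- hellinger_dist(rbind(m1, m2))
    grp <- factor(rep(c("T1", "T2"), times = c(nrow(m1), nrow(m2))))
    dt <- dispersion_test(d, grp, n_perm = n_perm,
                          seed = child_seed(spec$seed, 100000 + k))
    pm <- permanova(d, grp, n_perm = n_perm,
                    seed = child_seed(spec$seed, 200000 + k))
    p_disp[k] <- dt$p_perm
    p_perma[k] <- pm$p_perm
    dir_homog[k] <- dt$direction == "homogenization"
  }
  list(dispersion = list(mean_p = mean(p_disp), p_values = p_disp,
                         homogenization_share = mean(dir_homog)),
       permanova = list(mean_p = mean(p_perma), p_values = p_perma))
}

#' Run the full temporal beta-diversity and trait analysis
#'
#' Executes, for each cohort: community matrices for the three measures;
#' subsampled paired Wilcoxon tests of temporal change per species and
#' guild; the multivariate dispersion (homogenization) test and PERMANOVA on
#' Hellinger distances, both directly and under the subsampled protocol;
#' PCoA; LCBD/SCBD partitions per period with the temporal LCBD difference;
#' community-weighted mean traits with subsampled paired t tests and
#' trait-SCBD change; and the per-cell replacement/richness-difference
#' partition of temporal dissimilarity.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()], or a path to a YAML config file.
#' @return object of class `resurvey_report`.
#' @export
run_analysis <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  inp <- resolve_inputs(config)
  records <- pool_taxa(inp$records, config$pooling)
  periods <- sort(unique(records$period))
  if (length(periods) != 2)
    stop("stage survey_data: need exactly 2 survey periods, found ",
         length(periods))
  fn <- build_fishnet(inp$points, mesh_x = config$fishnet$mesh_x,
                      mesh_y = config$fishnet$mesh_y,
                      offsets = config$fishnet$offsets,
                      min_points = config$fishnet$min_points)
  by_cohort <- split_cohorts(records, config$cohort_threshold)

  cohorts <- list()
  for (cohort in config$cohorts) {
    rec <- by_cohort[[cohort]]
    retained <- as.vector(filter_rare(rec, inp$points, config$min_fraction))
    rec <- rec[rec$species %in% retained, ]
    r1 <- rec[rec$period == periods[1], ]
    r2 <- rec[rec$period == periods[2], ]
    spc <- subsample_spec(n = config$subsample$n, r = config$subsample$r,
                          seed = child_seed(config$seed,
                                            match(cohort, config$cohorts)),
                          pairing = config$subsample$pairing)

    matrices <- list()
    tests <- list()
    for (ms in config$measures) {
      matrices[[ms]] <- list()
      for (i in 1:2) {
        rr <- if (i == 1) r1 else r2
        matrices[[ms]][[periods[i]]] <-
          community_matrix(rr, fn, ms, species = retained,
                           period = periods[i], cohort = cohort)
      }
      tsp <- species_change_tests(r1, r2, fn, retained, measure = ms,
                                  spec = spc)
      tgl <- guild_change_tests(r1, r2, fn, retained, inp$guilds,
                                measure = ms, spec = spc)
      tests[[ms]] <- rbind(tsp, tgl)
    }
    test_table <- do.call(rbind, tests)
    test_table <- data.frame(cohort = cohort, test_table,
                             stringsAsFactors = FALSE, row.names = NULL)

    # beta-diversity and traits always work on relative abundance, whether
    # or not it is among the reported test measures
    if (is.null(matrices$relative_abundance)) {
      matrices$relative_abundance <- stats::setNames(list(
        community_matrix(r1, fn, "relative_abundance", species = retained,
                         period = periods[1], cohort = cohort),
        community_matrix(r2, fn, "relative_abundance", species = retained,
                         period = periods[2], cohort = cohort)), periods)
    }
    ra1 <- matrices$relative_abundance[[periods[1]]]
    ra2 <- matrices$relative_abundance[[periods[2]]]
    h <- hellinger(rbind(ra1, ra2))
    d <- stats::dist(h)
    grp <- factor(rep(periods, times = c(nrow(ra1), nrow(ra2))))
    disp_direct <- dispersion_test(d, grp, n_perm = config$n_perm,
                                   seed = child_seed(spc$seed, 91))
    perma_direct <- permanova(d, grp, n_perm = config$n_perm,
                              seed = child_seed(spc$seed, 92))
    multis <- subsampled_multivariate(r1, r2, fn, retained, spc,
                                      config$n_perm)
    ord <- pcoa(d)

    bp1 <- lcbd_scbd(hellinger(ra1))
    bp2 <- lcbd_scbd(hellinger(ra2))
    dl <- delta_lcbd(bp1, bp2, fn$cells)
    scbd <- data.frame(species = names(bp1$scbd),
                       scbd_t1 = unname(bp1$scbd),
                       scbd_t2 = unname(bp2$scbd),
                       change = unname(bp2$scbd - bp1$scbd),
                       stringsAsFactors = FALSE, row.names = NULL)

    trait_tests <- trait_change_tests(r1, r2, fn, retained, inp$traits,
                                      config$traits_tested, fn$cells, spc)
    tscbd <- lapply(config$traits_tested, function(tr)
      data.frame(trait = tr, trait_scbd(ra1, ra2, inp$traits, tr),
                 stringsAsFactors = FALSE))
    tscbd <- do.call(rbind, tscbd)

    comp_temporal <- temporal_components(ra1, ra2,
                                         family = config$beta_family)
    comp_spatial <- lapply(stats::setNames(periods, periods), function(per)
      beta_components(matrices$relative_abundance[[per]],
                      family = config$beta_family)$totals)

    cohorts[[cohort]] <- list(
      species = retained, tests = test_table, matrices = matrices,
      occupancy = lapply(matrices$occurrence, occupancy_summary),
      dispersion = list(direct = disp_direct,
                        subsampled = multis$dispersion),
      permanova = list(direct = perma_direct,
                       subsampled = multis$permanova),
      pcoa = ord, lcbd = list(bp1, bp2), delta_lcbd = dl, scbd = scbd,
      cwm = list(cwm_table(ra1, inp$traits, config$traits_tested),
                 cwm_table(ra2, inp$traits, config$traits_tested)),
      trait_tests = trait_tests, trait_scbd = tscbd,
      components = list(temporal = comp_temporal, spatial = comp_spatial))
    names(cohorts[[cohort]]$lcbd) <- periods
    names(cohorts[[cohort]]$cwm) <- periods
  }

  manifest <- list(
    package = "resurvey",
    version = as.character(utils::packageVersion("resurvey")),
    seed = config$seed,
    periods = periods,
    n_points = nrow(inp$points),
    n_cells = nrow(fn$cells),
    subsample = config$subsample,
    n_perm = config$n_perm,
    pooling = config$pooling,
    min_fraction = config$min_fraction,
    cohort_threshold = config$cohort_threshold,
    note = "PERMANOVA permutes labels freely; cells are paired across periods")

  report <- structure(list(cohorts = cohorts, fishnet = fn,
                           periods = periods, config = config,
                           manifest = manifest),
                      class = "resurvey_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.resurvey_report <- function(x, ...) {
  cat("Temporal resurvey analysis:", paste(x$periods, collapse = " vs "),
      "over", nrow(x$fishnet$cells), "cells\n")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat(sprintf(
      "  %s (%d species): dispersion mean p = %.3f (%s), PERMANOVA mean p = %.3f\n",
      nm, length(co$species), co$dispersion$subsampled$mean_p,
      co$dispersion$direct$direction, co$permanova$subsampled$mean_p))
  }
  invisible(x)
}

#' Write a report bundle to CSV and JSON files
#'
#' Serializes every table of a [run_analysis()] report plus a run manifest.
#'
#' @param report a `resurvey_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  for (nm in names(report$cohorts)) {
    co <- report$cohorts[[nm]]
    pre <- paste0(nm, "_")
    w(co$tests, paste0(pre, "tests.csv"))
    w(co$delta_lcbd, paste0(pre, "delta_lcbd.csv"))
    w(co$scbd, paste0(pre, "scbd.csv"))
    w(data.frame(cell_id = rownames(co$cwm[[1]]), co$cwm[[1]],
                 check.names = FALSE), paste0(pre, "cwm_t1.csv"))
    w(data.frame(cell_id = rownames(co$cwm[[2]]), co$cwm[[2]],
                 check.names = FALSE), paste0(pre, "cwm_t2.csv"))
    w(co$trait_tests, paste0(pre, "trait_tests.csv"))
    w(attr(co$trait_tests, "delta"), paste0(pre, "trait_delta.csv"))
    w(co$trait_scbd, paste0(pre, "trait_scbd.csv"))
    w(co$components$temporal, paste0(pre, "components.csv"))
    for (ms in names(co$matrices)) {
      for (per in names(co$matrices[[ms]])) {
        m <- co$matrices[[ms]][[per]]
        w(data.frame(cell_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE),
          paste0(pre, "matrix_", ms, "_", per, ".csv"))
        jsonlite::write_json(
          list(measure = ms, period = per, cohort = nm,
               n_points_per_cell = as.list(attr(m, "n_points"))),
          file.path(dir, paste0(pre, "matrix_", ms, "_", per, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
    pts <- co$pcoa$points
    w(data.frame(site = rownames(pts) %||% seq_len(nrow(pts)), pts,
                 check.names = FALSE), paste0(pre, "pcoa_coordinates.csv"))
    stats_json <- list(
      dispersion = list(
        F = co$dispersion$direct$F, p_perm = co$dispersion$direct$p_perm,
        direction = co$dispersion$direct$direction,
        mean_z = as.list(co$dispersion$direct$mean_z),
        subsampled_mean_p = co$dispersion$subsampled$mean_p),
      permanova = list(
        F = co$permanova$direct$F, R2 = co$permanova$direct$R2,
        p_perm = co$permanova$direct$p_perm,
        subsampled_mean_p = co$permanova$subsampled$mean_p,
        note = co$permanova$direct$note),
      beta_components = co$components$spatial)
    jsonlite::write_json(stats_json, file.path(dir, paste0(pre, "beta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  w(report$fishnet$cells, "fishnet_cells.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
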