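# Ingestion and aggregation of point-centred-quarter survey records.

SURVEY_COLUMNS <- c("point_id", "x", "y", "period", "quadrant", "species",
                    "dbh_cm", "distance_m")

#' Read and validate a point-quarter survey table
#'
#' Reads a delimited survey file (one row per sampled tree) and validates it
#' against the point-quarter protocol: positive dbh, nonnegative distance,
#' quadrant in 1..4, and at most one tree per (grid point, period, quadrant,
#' cohort). Grid points are derived from the unique `point_id`/`x`/`y`
#' combinations together with the set of periods in which each was sampled.
#'
#' @param path path to a CSV file with columns `point_id`, `x`, `y`, `period`,
#'   `quadrant`, `species`, `dbh_cm`, `distance_m` (UTF-8, header required).
#' @param cohort_threshold dbh (cm) at and above which a stem is counted as a
#'   mature tree when checking per-quadrant uniqueness. Default 10.
#' @param known_species optional character vector; species codes outside it
#'   are reported in the returned object's `unknown_species` field.
#' @return an object of class `pq_survey`: a list with `points` (data frame
#'   `point_id`, `x`, `y`, `sampled_in`), `records` (validated tree records)
#'   and `unknown_species`.
#' @export
read_survey <- function(path, cohort_threshold = 10, known_species = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SURVEY_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("survey schema error: missing column(s) ", paste(missing, collapse = ", "))
  df <- df[SURVEY_COLUMNS]
  validate_survey(df, cohort_threshold = cohort_threshold,
                  known_species = known_species)
}

# Validation shared by read_survey and in-memory record sets.
validate_survey <- function(df, cohort_threshold = 10, known_species = NULL) {
  for (col in c("x", "y", "dbh_cm", "distance_m")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0)
      stop("row-level validation error: non-numeric or missing ", col,
           " in row(s) ", paste(utils::head(bad, 10), collapse = ", "))
    df[[col]] <- v
  }
  df$quadrant <- suppressWarnings(as.integer(df$quadrant))
  bad <- which(is.na(df$quadrant) | !(df$quadrant %in% 1:4))
  if (length(bad) > 0)
    stop("row-level validation error: quadrant outside 1..4 in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(df$dbh_cm <= 0)
  if (length(bad) > 0)
    stop("row-level validation error: nonpositive dbh in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(df$distance_m < 0)
  if (length(bad) > 0)
    stop("row-level validation error: negative distance in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$point_id <- as.character(df$point_id)
  df$period <- as.character(df$period)
  df$species <- as.character(df$species)

  cohort <- ifelse(df$dbh_cm >= cohort_threshold, "mature", "sapling")
  key <- paste(df$point_id, df$period, df$quadrant, cohort, sep = "\r")
  if (anyDuplicated(key))
    stop("row-level validation error: duplicate (point, period, quadrant, cohort) ",
         "record(s), e.g. row ", which(duplicated(key))[1])

  pt_key <- !duplicated(df$point_id)
  points <- data.frame(point_id = df$point_id[pt_key],
                       x = df$x[pt_key], y = df$y[pt_key],
                       stringsAsFactors = FALSE)
  xy_bad <- tapply(paste(df$x, df$y), df$point_id,
                   function(v) length(unique(v)) > 1)
  if (any(xy_bad))
    stop("validation error: point(s) with inconsistent coordinates: ",
         paste(names(xy_bad)[xy_bad][1:min(5, sum(xy_bad))], collapse = ", "))
  sampled_in <- tapply(df$period, df$point_id,
                       function(p) paste(sort(unique(p)), collapse = ","))
  points$sampled_in <- unname(sampled_in[points$point_id])
  points <- points[order(points$point_id), ]
  rownames(points) <- NULL

  unknown <- character(0)
  if (!is.null(known_species))
    unknown <- sort(setdiff(df$species, known_species))

  completeness <- stats::aggregate(
    list(n_quadrants = df$quadrant),
    by = list(point_id = df$point_id, period = df$period),
    FUN = function(q) length(unique(q)))

  structure(list(points = points, records = df, unknown_species = unknown,
                 completeness = completeness),
            class = "pq_survey")
}

#' @export
print.pq_survey <- function(x, ...) {
  cat("Point-quarter survey:", nrow(x$records), "tree records at",
      nrow(x$points), "grid points;",
      "periods:", paste(sort(unique(x$records$period)), collapse = ", "), "\n")
  if (length(x$unknown_species) > 0)
    cat("Unknown species codes:", paste(x$unknown_species, collapse = ", "), "\n")
  invisible(x)
}

#' Write survey records to a CSV file
#'
#' Inverse of [read_survey()]; full numeric precision is retained.
#' @param records record data frame (columns as in [read_survey()]).
#' @param path output file path.
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records[SURVEY_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split records into mature and sapling cohorts
#'
#' Stems with dbh at or above the threshold are mature; the rest are
#' saplings. The two subsets partition the input for every positive dbh
#' (a dbh of exactly 10 cm is mature).
#'
#' @param records record data frame.
#' @param threshold cohort boundary in cm, default 10.
#' @return named list with elements `mature` and `sapling`.
#' @export
split_cohorts <- function(records, threshold = 10) {
  mature <- records$dbh_cm >= threshold
  list(mature = records[mature, , drop = FALSE],
       sapling = records[!mature, , drop = FALSE])
}

#' Pool taxa under a relabelling map
#'
#' Relabels species codes according to `pooling` (names are source codes,
#' values target codes), e.g. folding a hybrid into its parent species.
#' Record counts are conserved; chained or cyclic maps are rejected.
#'
#' @param records record data frame.
#' @param pooling named character vector, source -> target.
#' @return the records with species codes relabelled.
#' @export
pool_taxa <- function(records, pooling = character(0)) {
  if (length(pooling) == 0) return(records)
  if (is.null(names(pooling)) || any(names(pooling) == ""))
    stop("pooling config error: map must be a named character vector")
  if (any(pooling %in% names(pooling)))
    stop("pooling config error: chained or cyclic map (a target is also a source)")
  hit <- records$species %in% names(pooling)
  records$species[hit] <- unname(pooling[records$species[hit]])
  records
}

#' Drop species occurring at too few grid points
#'
#' A species' occupancy is the fraction of all surveyed grid points (both
#' periods pooled) at which it was recorded at least once. Species below
#' `min_fraction` are removed so the retained set is identical in both
#' periods.
#'
#' @param records record data frame (cohort-specific, pooling applied).
#' @param points grid-point data frame (all surveyed points).
#' @param min_fraction minimum occupied-point fraction, default 0.01.
#' @return character vector of retained species codes; species removed and
#'   their occupancy fractions are attached as attributes `removed` and
#'   `fraction`.
#' @export
filter_rare <- function(records, points, min_fraction = 0.01) {
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("config error: min_fraction must lie in [0, 1]")
  n_points <- nrow(points)
  occ <- tapply(records$point_id, records$species,
                function(p) length(unique(p)))
  frac <- occ / n_points
  keep <- names(frac)[frac >= min_fraction]
  removed <- setdiff(names(frac), keep)
  structure(sort(keep), removed = sort(removed), fraction = frac)
}

#' Build an optimized fishnet of grid-point cells
#'
#' Overlays a rectangular mesh on the grid points and returns, among all
#' candidate (mesh size, origin offset) combinations, the fishnet with the
#' most cells meeting the minimum point count; ties are broken by larger
#' mean points per qualifying cell, then smaller mesh area. Cell membership
#' uses half-open boxes `[min, max)` so every point belongs to exactly one
#' cell. Only qualifying cells are returned; the same fishnet is meant to be
#' reused for every period.
#'
#' @param points grid-point data frame with `point_id`, `x`, `y`.
#' @param mesh_x,mesh_y candidate mesh sizes (m) along x and y.
#' @param offsets candidate origin offsets as fractions of the mesh size.
#' @param min_points minimum grid points per qualifying cell, default 10.
#' @return object of class `fishnet`: list with `cells` (data frame of
#'   bounding boxes, centroids and counts) and `members` (named list of
#'   point ids per cell).
#' @export
build_fishnet <- function(points, mesh_x, mesh_y = mesh_x,
                          offsets = c(0, 0.25, 0.5, 0.75), min_points = 10) {
  if (nrow(points) < min_points)
    stop("fewer grid points than min_points")
  cand <- expand.grid(mx = mesh_x, my = mesh_y, fx = offsets, fy = offsets,
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_score <- c(-Inf, -Inf, Inf)
  for (i in seq_len(nrow(cand))) {
    mx <- cand$mx[i]; my <- cand$my[i]
    ox <- min(points$x) - cand$fx[i] * mx
    oy <- min(points$y) - cand$fy[i] * my
    ix <- floor((points$x - ox) / mx)
    iy <- floor((points$y - oy) / my)
    cell <- paste(ix, iy, sep = ":")
    cnt <- table(cell)
    qual <- names(cnt)[cnt >= min_points]
    score <- c(length(qual),
               if (length(qual) > 0) mean(cnt[qual]) else 0,
               -mx * my)
    better <- (score[1] > best_score[1]) ||
      (score[1] == best_score[1] && score[2] > best_score[2]) ||
      (score[1] == best_score[1] && score[2] == best_score[2] &&
         score[3] > best_score[3])
    if (better) {
      best_score <- score
      best <- list(mx = mx, my = my, ox = ox, oy = oy, ix = ix, iy = iy,
                   cell = cell, qual = qual)
    }
  }
  if (is.null(best) || length(best$qual) == 0)
    stop("fishnet search failed: no candidate yields a cell with ",
         min_points, " grid points")
  qual <- best$qual
  keep <- best$cell %in% qual
  members <- split(points$point_id[keep], best$cell[keep])
  idx <- do.call(rbind, strsplit(names(members), ":", fixed = TRUE))
  ix <- as.numeric(idx[, 1]); iy <- as.numeric(idx[, 2])
  ord <- order(iy, ix)
  members <- members[ord]
  ix <- ix[ord]; iy <- iy[ord]
  cell_id <- sprintf("C%02d", seq_along(members))
  names(members) <- cell_id
  cells <- data.frame(
    cell_id = cell_id,
    xmin = best$ox + ix * best$mx, xmax = best$ox + (ix + 1) * best$mx,
    ymin = best$oy + iy * best$my, ymax = best$oy + (iy + 1) * best$my,
    n_points = lengths(members), stringsAsFactors = FALSE)
  cells$cx <- (cells$xmin + cells$xmax) / 2
  cells$cy <- (cells$ymin + cells$ymax) / 2
  rownames(cells) <- NULL
  structure(list(cells = cells, members = members,
                 mesh = c(x = best$mx, y = best$my),
                 origin = c(x = best$ox, y = best$oy),
                 min_points = min_points),
            class = "fishnet")
}

#' Assign points to the cells of an existing fishnet
#'
#' Maps coordinates to the fishnet's half-open cell boxes `[min, max)`;
#' points falling outside every qualifying cell get `NA`. Because the boxes
#' are half-open, every point belongs to at most one cell, and jittering a
#' point within its box never changes its assignment.
#'
#' @param fishnet a [build_fishnet()] result.
#' @param points data frame with `x`, `y`.
#' @return character vector of cell ids (NA outside the fishnet).
#' @export
assign_cells <- function(fishnet, points) {
  cells <- fishnet$cells
  out <- rep(NA_character_, nrow(points))
  for (i in seq_len(nrow(cells))) {
    inside <- points$x >= cells$xmin[i] & points$x < cells$xmax[i] &
      points$y >= cells$ymin[i] & points$y < cells$ymax[i]
    out[inside] <- cells$cell_id[i]
  }
  out
}

#' @export
print.fishnet <- function(x, ...) {
  cat("Fishnet:", nrow(x$cells), "cells of", x$mesh["x"], "x", x$mesh["y"],
      "m;", min(x$cells$n_points), "-", max(x$cells$n_points),
      "grid points per cell\n")
  invisible(x)
}

# Normalize a fishnet or a named list of point-id vectors to the list form.
as_cells <- function(cells) {
  if (inherits(cells, "fishnet")) return(cells$members)
  if (is.list(cells) && !is.null(names(cells))) return(cells)
  stop("cells must be a fishnet or a named list of point-id vectors")
}

#' Build a cells-by-species community matrix
#'
#' Aggregates tree records into one of three per-cell measures:
#' \describe{
#'   \item{occurrence}{fraction of the cell's sampled grid points at which
#'     the species is present;}
#'   \item{relative_abundance}{individuals of the species divided by all
#'     individuals recorded in the cell;}
#'   \item{basal_area}{summed stem basal area pi*(dbh/2)^2 divided by the
#'     number of sampled grid points in the cell (cm^2 per point).}
#' }
#'
#' @param records record data frame, already restricted to one cohort and
#'   period (and to the retained species).
#' @param cells a `fishnet` or named list mapping cell id to the point ids
#'   sampled in this period.
#' @param measure one of `"occurrence"`, `"relative_abundance"`,
#'   `"basal_area"`.
#' @param species column order; defaults to the sorted species present.
#' @param period,cohort optional labels stored as attributes.
#' @return numeric matrix (cells x species) of class `community_matrix`,
#'   with attributes `measure`, `period`, `cohort`, `n_points`.
#' @export
community_matrix <- function(records, cells,
                             measure = c("occurrence", "relative_abundance",
                                         "basal_area"),
                             species = NULL, period = NULL, cohort = NULL) {
  measure <- match.arg(measure)
  cells <- as_cells(cells)
  n_pts <- lengths(cells)
  if (any(n_pts == 0))
    stop("cell with zero sampled points: ", names(cells)[n_pts == 0][1])
  if (is.null(species)) species <- sort(unique(records$species))
  records <- records[records$species %in% species, , drop = FALSE]

  pt2cell <- rep(names(cells), lengths(cells))
  names(pt2cell) <- unlist(cells, use.names = FALSE)
  rec_cell <- pt2cell[records$point_id]
  inside <- !is.na(rec_cell)
  records <- records[inside, , drop = FALSE]
  rec_cell <- rec_cell[inside]

  cf <- factor(rec_cell, levels = names(cells))
  sf <- factor(records$species, levels = species)
  m <- if (nrow(records) == 0) {
    matrix(0, length(cells), length(species))
  } else switch(measure,
    occurrence = {
      dup <- duplicated(paste(rec_cell, records$point_id, records$species,
                              sep = "\r"))
      counts <- table(cf[!dup], sf[!dup])
      unclass(counts) / n_pts
    },
    relative_abundance = {
      counts <- unclass(table(cf, sf))
      tot <- rowSums(counts)
      out <- counts
      nz <- tot > 0
      out[nz, ] <- counts[nz, , drop = FALSE] / tot[nz]
      out
    },
    basal_area = {
      ba <- tapply(basal_area_cm2(records$dbh_cm), list(cf, sf), sum,
                   default = 0)
      ba / n_pts
    })
  m <- matrix(as.numeric(m), nrow = length(cells), ncol = length(species),
              dimnames = list(names(cells), species))
  structure(m, measure = measure, period = period, cohort = cohort,
            n_points = n_pts, class = c("community_matrix", "matrix", "array"))
}

#' Percentage of cells occupied by each species
#'
#' Reporting summary for occurrence displays: the share of cells (in
#' percent) with a nonzero value per species.
#'
#' @param m a community matrix.
#' @return named numeric vector of percentages.
#' @export
occupancy_summary <- function(m) {
  100 * colMeans(as.matrix(m) > 0)
}
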