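# Trait tables, community-weighted means, temperature preference index,
# guild aggregation and trait-change inference.

TRAIT_NAMES <- c("shade", "drought", "waterlogging", "seed_mass", "temp_pref")

#' Read a species trait table
#'
#' Expects CSV columns `species`, `shade`, `drought`, `waterlogging`,
#' `seed_mass_mg` and optionally `temp_pref_c`. Tolerance scores must lie in
#' `[1, 5]` (1 = very intolerant, 5 = very tolerant); seed mass is in mg.
#' Missing values are allowed and flagged.
#'
#' @param path CSV file path.
#' @return validated trait data frame.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "shade", "drought", "waterlogging", "seed_mass_mg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("trait schema error: missing column(s) ", paste(missing, collapse = ", "))
  validate_traits(df)
}

validate_traits <- function(df) {
  for (col in c("shade", "drought", "waterlogging")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 1 | v > 5)))
      stop("trait validation error: ", col, " outside [1, 5]")
  }
  if (any(!is.na(df$seed_mass_mg) & df$seed_mass_mg <= 0))
    stop("trait validation error: nonpositive seed mass")
  df$species <- as.character(df$species)
  if (anyDuplicated(df$species)) stop("trait validation error: duplicate species")
  df
}

#' Read a species-to-guild table
#'
#' CSV with columns `species` and `guild`; guilds must be one of
#' `northern`, `central`, `carolinian`.
#'
#' @param path CSV file path.
#' @return data frame `species`, `guild`.
#' @export
read_guilds <- function(path) {
  if (!file.exists(path)) stop("guild file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "guild") %in% names(df)))
    stop("guild schema error: need columns species, guild")
  bad <- setdiff(unique(df$guild), c("northern", "central", "carolinian"))
  if (length(bad) > 0)
    stop("guild validation error: unknown guild(s) ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("guild validation error: species assigned to more than one guild")
  df
}

# Named per-species values for one trait. Seed mass enters analyses on the
# natural-log scale.
trait_values <- function(traits, trait) {
  trait <- match.arg(trait, TRAIT_NAMES)
  col <- switch(trait, seed_mass = "seed_mass_mg", temp_pref = "temp_pref_c",
                trait)
  if (!col %in% names(traits))
    stop("trait table lacks column ", col)
  v <- traits[[col]]
  if (trait == "seed_mass") v <- log(v)
  stats::setNames(v, traits$species)
}

#' Community-weighted mean of a trait
#'
#' `CWM_i = sum_j p_ij t_j / sum_j p_ij` over species with a non-missing
#' trait value (weights renormalized; no imputation). Seed mass is
#' log-transformed (natural log) before weighting.
#'
#' @param m relative-abundance community matrix (rows sum to 1 where
#'   nonempty).
#' @param traits trait data frame (see [read_traits()]).
#' @param trait one of `"shade"`, `"drought"`, `"waterlogging"`,
#'   `"seed_mass"`, `"temp_pref"`.
#' @return named numeric vector of per-cell CWM values; attribute
#'   `contributing` holds the per-cell abundance share carried by species
#'   with a non-missing trait.
#' @export
cwm <- function(m, traits, trait) {
  m <- as.matrix(m)
  tv <- trait_values(traits, trait)
  sp <- colnames(m)
  unknown <- setdiff(sp, names(tv))
  if (length(unknown) > 0)
    stop("species missing from trait table: ", paste(utils::head(unknown, 5),
                                                     collapse = ", "))
  t_j <- tv[sp]
  ok <- !is.na(t_j)
  w <- m[, ok, drop = FALSE]
  ws <- rowSums(w)
  tot <- rowSums(m)
  starved <- ws == 0 & tot > 0
  if (any(starved))
    stop("cell(s) whose entire abundance lies on trait-missing species: ",
         paste(utils::head(rownames(m)[starved], 5), collapse = ", "))
  vals <- as.numeric(w %*% t_j[ok]) / ws
  vals[tot == 0] <- NA_real_
  structure(stats::setNames(vals, rownames(m)), contributing = ws / pmax(tot, 1e-300))
}

#' Community-weighted means for several traits
#'
#' @inheritParams cwm
#' @param trait_names traits to include (default all five).
#' @return cells x traits matrix of CWM values.
#' @export
cwm_table <- function(m, traits, trait_names = TRAIT_NAMES) {
  out <- vapply(trait_names, function(tr) cwm(m, traits, tr),
                numeric(nrow(as.matrix(m))))
  matrix(out, nrow = nrow(as.matrix(m)),
         dimnames = list(rownames(m), trait_names))
}

#' Species temperature preference index
#'
#' Mean of a gridded mean-annual-temperature surface sampled at a species'
#' occurrence points (nearest-cell lookup, no interpolation). Points outside
#' the raster extent (or over no-data cells) are dropped and counted.
#'
#' @param occurrences data frame with columns `x`, `y`.
#' @param raster an `ascii_grid` object, see [read_ascii_grid()].
#' @return mean temperature (same units as the raster); attribute
#'   `n_dropped` counts discarded points.
#' @export
temperature_index <- function(occurrences, raster) {
  v <- raster_lookup(raster, occurrences$x, occurrences$y)
  dropped <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no usable occurrences inside the raster extent")
  structure(mean(v), n_dropped = dropped)
}

#' Read an ESRI ASCII grid raster
#'
#' Minimal reader for the plain-text ASCII grid format: header lines
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional
#' `NODATA_value`, then `nrows` rows of values, northernmost row first.
#'
#' @param path file path.
#' @return object of class `ascii_grid`: list with `ncols`, `nrows`, `xll`,
#'   `yll`, `cellsize`, `nodata`, and `values` (nrows x ncols matrix, row 1
#'   = north).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("raster schema error: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("raster validation error: expected ", nr * nc, " values, got ",
         length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  structure(list(ncols = nc, nrows = nr, xll = hdr$xllcorner,
                 yll = hdr$yllcorner, cellsize = hdr$cellsize,
                 nodata = nodata, values = m),
            class = "ascii_grid")
}

#' Write an ESRI ASCII grid raster
#'
#' @param grid an `ascii_grid` object (see [read_ascii_grid()]).
#' @param path output file path.
#' @export
write_ascii_grid <- function(grid, path) {
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize))
  vals <- grid$values
  if (!is.null(grid$nodata)) {
    hdr <- c(hdr, sprintf("NODATA_value %.10g", grid$nodata))
    vals[is.na(vals)] <- grid$nodata
  }
  rows <- apply(vals, 1, function(r) paste(format(r, trim = TRUE),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Nearest-cell raster lookup; NA outside the extent or over no-data cells.
raster_lookup <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row_s <- floor((y - grid$yll) / grid$cellsize) + 1   # from the south
  row <- grid$nrows - row_s + 1                        # matrix row, north first
  ok <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Subsampled change tests for species guilds
#'
#' Pools member species (values summed before normalization for relative
#' abundance) and runs the subsampled paired Wilcoxon protocol per guild.
#' Guilds with no retained species are skipped with a warning.
#'
#' @inheritParams species_change_tests
#' @param guilds guild data frame (`species`, `guild`).
#' @return data frame as in [species_change_tests()], one row per guild.
#' @export
guild_change_tests <- function(records_t1, records_t2, cells, species, guilds,
                               measure = "relative_abundance",
                               test = "paired_wilcoxon",
                               spec = subsample_spec()) {
  members <- split(guilds$species, guilds$guild)
  members <- lapply(members, intersect, x = species)
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning("guild(s) with no retained species skipped: ",
            paste(names(members)[empty], collapse = ", "))
    members <- members[!empty]
  }
  sf <- stat_species(members, measure)
  out <- subsample_engine(records_t1, records_t2, cells, sf, test, spec)
  summarize_pmatrix(out, names(members), measure, spec)
}

# Per-cell CWM statistic recomputed inside each subsample replicate.
stat_cwm <- function(species, traits, trait_names) {
  function(records, ids) {
    m <- community_matrix(records, ids, measure = "relative_abundance",
                          species = species)
    cwm_table(m, traits, trait_names)
  }
}

#' Subsampled paired t tests of community-weighted trait change
#'
#' Recomputes the CWM of each trait inside every subsample replicate and
#' tests the per-cell values between periods with a paired t test. The
#' full-data per-cell change `CWM_T2 - CWM_T1` is attached for mapping.
#'
#' @inheritParams species_change_tests
#' @param traits trait data frame.
#' @param trait_names traits to test (default all five).
#' @param coords optional cell centroid table (`cell_id`, `cx`, `cy`).
#' @return data frame of test summaries (one row per trait) with the
#'   per-cell delta table attached as attribute `delta`.
#' @export
trait_change_tests <- function(records_t1, records_t2, cells, species, traits,
                               trait_names = TRAIT_NAMES, coords = NULL,
                               spec = subsample_spec()) {
  sf <- stat_cwm(species, traits, trait_names)
  out <- subsample_engine(records_t1, records_t2, cells, sf, "paired_t", spec)
  res <- summarize_pmatrix(out, trait_names, "cwm", spec)

  cl <- as_cells(cells)
  m1 <- community_matrix(records_t1, cl, "relative_abundance",
                         species = species)
  m2 <- community_matrix(records_t2, cl, "relative_abundance",
                         species = species)
  c1 <- cwm_table(m1, traits, trait_names)
  c2 <- cwm_table(m2, traits, trait_names)
  delta <- data.frame(cell_id = rownames(c1), c2 - c1, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(coords)) {
    i <- match(delta$cell_id, coords$cell_id)
    delta$cx <- coords$cx[i]; delta$cy <- coords$cy[i]
  }
  attr(res, "delta") <- delta
  res
}

#' Species contributions to community-trait variation
#'
#' SCBD-style column shares of the abundance-by-trait contribution matrix
#' `x_ij = p_ij * t_j` (weights renormalized over species with non-missing
#' trait): `share_j = sum_i (x_ij - mean_i x_ij)^2 / SS_total` per period,
#' and their temporal change. Shares sum to 1 within each period.
#'
#' @param m_t1,m_t2 relative-abundance community matrices, identical species.
#' @param traits trait data frame.
#' @param trait trait name.
#' @return data frame `species`, `share_t1`, `share_t2`, `change`.
#' @export
trait_scbd <- function(m_t1, m_t2, traits, trait) {
  share <- function(m) {
    m <- as.matrix(m)
    t_j <- trait_values(traits, trait)[colnames(m)]
    ok <- !is.na(t_j)
    w <- m[, ok, drop = FALSE]
    ws <- rowSums(w)
    if (any(ws == 0))
      stop("cell(s) whose entire abundance lies on trait-missing species: ",
           paste(utils::head(rownames(m)[ws == 0], 5), collapse = ", "))
    w <- w / ws
    xm <- sweep(w, 2, t_j[ok], "*")
    s <- sweep(xm, 2, colMeans(xm))^2
    out <- rep(NA_real_, ncol(m))
    names(out) <- colnames(m)
    # no variation (e.g. a single species): contributions are uniform
    out[ok] <- if (sum(s) == 0) 1 / sum(ok) else colSums(s) / sum(s)
    out
  }
  s1 <- share(m_t1); s2 <- share(m_t2)
  data.frame(species = names(s1), share_t1 = unname(s1),
             share_t2 = unname(s2), change = unname(s2 - s1),
             stringsAsFactors = FALSE, row.names = NULL)
}
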