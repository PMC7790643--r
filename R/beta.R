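# Hellinger-distance beta-diversity machinery: dispersion (homogenization)
# test, PERMANOVA, PCoA, LCBD/SCBD partition, replacement vs richness
# difference components.

#' Hellinger transformation
#'
#' Row-wise square-root of relative abundances: `y'_ij = sqrt(y_ij / sum_j
#' y_ij)`. Each transformed row has unit Euclidean norm, and Euclidean
#' distance between transformed rows is the Hellinger distance (bounded by
#' sqrt(2)).
#'
#' @param x nonnegative matrix (cells x species) with positive row sums.
#' @return transformed numeric matrix.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    bad <- rownames(x)[rs <= 0] %||% which(rs <= 0)
    stop("zero-sum row (empty cell): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  sqrt(sweep(x, 1, rs, "/"))
}

#' Hellinger distance matrix
#'
#' Euclidean distances between Hellinger-transformed rows.
#'
#' @param x abundance matrix, or an already transformed matrix with
#'   `transformed = TRUE`.
#' @param transformed set TRUE if `x` is already Hellinger-transformed.
#' @return a `dist` object.
#' @export
hellinger_dist <- function(x, transformed = FALSE) {
  y <- if (transformed) as.matrix(x) else hellinger(x)
  stats::dist(y)
}

#' Principal coordinates analysis
#'
#' Metric embedding of a dissimilarity matrix by eigendecomposition of the
#' Gower-centred matrix -1/2 J D^2 J. Axes with positive eigenvalue are
#' scaled by the square root of the eigenvalue; negative eigenvalues are
#' reported but their axes are excluded from the coordinates.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @return object of class `pcoa`: `values` (all eigenvalues, descending),
#'   `vectors` (unit eigenvectors), `points` (site coordinates on positive
#'   axes), `prop_explained` (per positive axis), `labels`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-8
  pos <- e$values > tol
  pts <- sweep(e$vectors[, pos, drop = FALSE], 2, sqrt(e$values[pos]), "*")
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(values = e$values, vectors = e$vectors, points = pts,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 tol = tol, labels = rownames(d)),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  k <- min(3, ncol(x$points))
  cat("PCoA of", length(x$labels), "sites;",
      sum(x$values > x$tol), "positive axes; first",
      k, "explain", sprintf("%.1f%%", 100 * sum(x$prop_explained[seq_len(k)])),
      "\n")
  invisible(x)
}

# One-way ANOVA F statistic (no p-value) on a vector given a grouping
# factor. Sums of squares below machine-level noise (relative to the data
# scale) are treated as zero so congruent groups give F = 0 exactly.
anova_F <- function(z, g) {
  N <- length(z)
  a <- nlevels(g)
  m <- tapply(z, g, mean)
  n_g <- tabulate(g)
  ssb <- sum(n_g * (m - mean(z))^2)
  ssw <- sum((z - m[as.integer(g)])^2)
  eps <- 1e-12 * max(sum(z^2), .Machine$double.xmin)
  if (ssb + ssw <= eps) return(0)
  if (ssw <= 1e-12 * (ssb + ssw)) return(Inf)
  (ssb / (a - 1)) / (ssw / (N - a))
}

# All 2-group label assignments of N sites with n1 in the first group.
enumerate_splits <- function(g) {
  if (nlevels(g) != 2)
    stop("enumeration mode supports exactly 2 groups")
  N <- length(g)
  n1 <- sum(as.integer(g) == 1)
  combs <- utils::combn(N, n1)
  lapply(seq_len(ncol(combs)), function(j) {
    gl <- rep(levels(g)[2], N)
    gl[combs[, j]] <- levels(g)[1]
    factor(gl, levels = levels(g))
  })
}

#' Test for homogeneity of multivariate dispersions
#'
#' Permutation test on site distances to their group (period) centroid in
#' principal-coordinate space: a significant decrease in dispersion from the
#' first to the second period is interpreted as biotic homogenization, an
#' increase as differentiation. Distances handle negative eigenvalue axes by
#' subtracting their squared contribution (clamped at zero). The observed F
#' is the one-way ANOVA F on the distances; the permutation distribution is
#' obtained by permuting group labels of the distances, with
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`. With `enumerate = TRUE` all
#' distinct two-group label assignments are evaluated instead and
#' `p = #{F* >= F} / n_assignments`.
#'
#' @param d dissimilarity matrix (`dist` or square matrix).
#' @param groups period labels, one per site (2 or more levels; direction is
#'   reported for 2 levels, first level = historical).
#' @param n_perm number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param enumerate evaluate all label assignments exactly (2 groups only).
#' @return object of class `dispersion_test`: `z` (distances to centroids),
#'   `F`, `p_perm`, `n_perm`, `mean_z` per group, and `direction`
#'   (`"homogenization"`, `"differentiation"` or `"none"`).
#' @export
dispersion_test <- function(d, groups, n_perm = 9999, seed = NULL,
                            enumerate = FALSE) {
  if (!enumerate && (!is.numeric(n_perm) || n_perm < 1))
    stop("config error: n_perm must be >= 1")
  d <- as.matrix(d)
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (any(tabulate(g) < 2)) stop("each group needs at least 2 sites")
  pc <- pcoa(d)
  vals <- pc$values
  posax <- vals > pc$tol
  negax <- vals < -pc$tol
  Cpos <- sweep(pc$vectors[, posax, drop = FALSE], 2, sqrt(vals[posax]), "*")
  Cneg <- sweep(pc$vectors[, negax, drop = FALSE], 2, sqrt(-vals[negax]), "*")
  z2 <- numeric(nrow(d))
  for (lev in levels(g)) {
    i <- which(g == lev)
    cp <- colMeans(Cpos[i, , drop = FALSE])
    cn <- colMeans(Cneg[i, , drop = FALSE])
    z2[i] <- rowSums(sweep(Cpos[i, , drop = FALSE], 2, cp)^2) -
      rowSums(sweep(Cneg[i, , drop = FALSE], 2, cn)^2)
  }
  z <- sqrt(pmax(z2, 0))
  F_obs <- anova_F(z, g)
  if (enumerate) {
    Fs <- vapply(enumerate_splits(g), function(gl) anova_F(z, gl), 0)
    p <- mean(Fs >= F_obs - 1e-12)
    n_perm <- length(Fs)
  } else {
    Fs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      anova_F(z, g[sample.int(length(g))]), 0))
    p <- (1 + sum(Fs >= F_obs - 1e-12)) / (1 + n_perm)
  }
  mean_z <- tapply(z, g, mean)
  direction <- "none"
  if (nlevels(g) == 2) {
    tol <- 1e-12 * max(mean_z, .Machine$double.xmin)
    if (mean_z[2] < mean_z[1] - tol) direction <- "homogenization"
    else if (mean_z[2] > mean_z[1] + tol) direction <- "differentiation"
  }
  structure(list(z = stats::setNames(z, rownames(d)), F = F_obs, p_perm = p,
                 n_perm = n_perm, mean_z = mean_z, direction = direction,
                 groups = g, enumerated = enumerate, seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Multivariate dispersion test: F = %.4g, p = %.4g (%s)\n",
              x$F, x$p_perm,
              if (x$enumerated) paste(x$n_perm, "enumerated assignments")
              else paste(x$n_perm, "permutations")))
  cat("Mean distance to centroid:",
      paste(sprintf("%s = %.4f", names(x$mean_z), x$mean_z), collapse = ", "),
      "->", x$direction, "\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a dissimilarity matrix. Sums of squares follow
#' the distance-based decomposition `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, with pseudo-F
#' `(SS_B/(a-1)) / (SS_W/(N-a))` and `R^2 = SS_B/SS_total`. Labels are
#' permuted freely; `p = (1 + #{F* >= F}) / (1 + n_perm)`, or exact
#' enumeration of two-group assignments with `enumerate = TRUE`.
#'
#' @inheritParams dispersion_test
#' @return object of class `permanova` with `F`, `R2`, `p_perm`, `n_perm`,
#'   `SS_between`, `SS_within`, `SS_total`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL,
                      enumerate = FALSE) {
  if (!enumerate && (!is.numeric(n_perm) || n_perm < 1))
    stop("config error: n_perm must be >= 1")
  D2 <- as.matrix(d)^2
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  N <- nrow(D2)
  a <- nlevels(g)
  if (a < 2) stop("need at least 2 groups")
  if (any(tabulate(g) < 1)) stop("empty group")
  sst <- sum(D2[upper.tri(D2)]) / N
  ssw_of <- function(gl) {
    s <- 0
    for (lev in levels(gl)) {
      i <- which(gl == lev)
      s <- s + sum(D2[i, i]) / (2 * length(i))
    }
    s
  }
  F_of <- function(gl) {
    ssw <- ssw_of(gl)
    ((sst - ssw) / (a - 1)) / (ssw / (N - a))
  }
  F_obs <- F_of(g)
  if (enumerate) {
    Fs <- vapply(enumerate_splits(g), F_of, 0)
    p <- mean(Fs >= F_obs - 1e-12)
    n_perm <- length(Fs)
  } else {
    Fs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      F_of(g[sample.int(N)]), 0))
    p <- (1 + sum(Fs >= F_obs - 1e-12)) / (1 + n_perm)
  }
  ssw <- ssw_of(g)
  structure(list(F = F_obs, R2 = (sst - ssw) / sst, p_perm = p,
                 n_perm = n_perm, SS_between = sst - ssw, SS_within = ssw,
                 SS_total = sst, df = c(between = a - 1, within = N - a),
                 groups = g, enumerated = enumerate, seed = seed,
                 note = paste("labels permuted freely; paired structure of",
                              "cells across periods is not used as strata")),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4f, p = %.4g\n",
              x$F, x$df[1], x$df[2], x$R2, x$p_perm))
  invisible(x)
}

#' Partition total beta diversity into site and species contributions
#'
#' Decomposes the total community sum of squares of a (typically
#' Hellinger-transformed) matrix: with `s_ij = (y_ij - mean_i y_ij)^2`,
#' `SS_total = sum s_ij`; LCBD_i (local contribution, site uniqueness) is the
#' row share and SCBD_j (species contribution) the column share, each summing
#' to 1. `BD_total = SS_total / (n - 1)`. The identity `SS_total = (1/n)
#' sum_{i<j} d_ij^2` is verified internally and both values stored.
#'
#' @param y numeric matrix (cells x species), typically from [hellinger()].
#' @return object of class `beta_partition` with `SS_total`, `SS_total_d`
#'   (from the distance identity), `BD_total`, `lcbd`, `scbd`.
#' @export
lcbd_scbd <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 2) stop("need at least 2 cells")
  s <- sweep(y, 2, colMeans(y))^2
  sst <- sum(s)
  if (sst <= .Machine$double.eps * n * ncol(y))
    stop("beta partition undefined: all cells have identical composition")
  sst_d <- sum(stats::dist(y)^2) / n
  structure(list(SS_total = sst, SS_total_d = sst_d,
                 BD_total = sst / (n - 1),
                 lcbd = rowSums(s) / sst,
                 scbd = colSums(s) / sst),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("Beta-diversity partition: SS_total = %.5g, BD_total = %.5g\n",
              x$SS_total, x$BD_total))
  top <- utils::head(sort(x$scbd, decreasing = TRUE), 3)
  cat("Top SCBD:", paste(sprintf("%s %.3f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Temporal change in local contributions to beta diversity
#'
#' Per-cell difference of LCBD between a contemporary and a historical
#' partition (`LCBD_T2 - LCBD_T1`), with cell centroid coordinates for
#' mapping. The differences always sum to zero.
#'
#' @param bp_t1,bp_t2 `beta_partition` objects over identical cell sets.
#' @param coords optional data frame with `cell_id`, `cx`, `cy` (e.g.
#'   `fishnet$cells`).
#' @return data frame `cell_id`, `lcbd_t1`, `lcbd_t2`, `delta`, `sign`, and
#'   coordinates when supplied.
#' @export
delta_lcbd <- function(bp_t1, bp_t2, coords = NULL) {
  l1 <- bp_t1$lcbd; l2 <- bp_t2$lcbd
  if (length(l1) != length(l2) || !identical(names(l1), names(l2)))
    stop("mismatched cells between the two partitions")
  out <- data.frame(cell_id = names(l1) %||% seq_along(l1),
                    lcbd_t1 = unname(l1), lcbd_t2 = unname(l2),
                    delta = unname(l2 - l1), stringsAsFactors = FALSE)
  out$sign <- sign(out$delta)
  if (!is.null(coords)) {
    i <- match(out$cell_id, coords$cell_id)
    out$cx <- coords$cx[i]
    out$cy <- coords$cy[i]
  }
  out
}

#' Replacement and richness-difference components of dissimilarity
#'
#' Pairwise percentage-difference dissimilarity and its additive
#' decomposition. For sites i, k with `A = sum_j min(y_ij, y_kj)`,
#' `B = sum_j max(y_ij - y_kj, 0)`, `C = sum_j max(y_kj - y_ij, 0)`:
#' `D = (B + C) / (2A + B + C)`. The Podani-family decomposition (default)
#' uses `Repl = 2 min(B, C) / (2A + B + C)` and
#' `RichDiff = |B - C| / (2A + B + C)`; the Baselga-family variant uses
#' balanced variation `Repl = min(B, C) / (A + min(B, C))` and
#' `RichDiff = D - Repl`. In both, `D = Repl + RichDiff` elementwise.
#'
#' @param x abundance (or presence-absence) matrix, cells x species.
#' @param quantitative if FALSE, `x` is reduced to presence-absence first.
#' @param family `"podani"` (default) or `"baselga"`.
#' @return object of class `beta_components`: matrices `D`, `repl`, `rich`
#'   and `totals` (means over pairs).
#' @export
beta_components <- function(x, quantitative = TRUE,
                            family = c("podani", "baselga")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (!quantitative) x <- (x > 0) * 1
  n <- nrow(x)
  lab <- rownames(x) %||% as.character(seq_len(n))
  D <- R <- S <- matrix(0, n, n, dimnames = list(lab, lab))
  for (i in seq_len(n - 1)) {
    for (k in seq(i + 1, n)) {
      abc <- pair_abc(x[i, ], x[k, ])
      cmp <- decompose_pair(abc, family)
      D[i, k] <- D[k, i] <- cmp["D"]
      R[i, k] <- R[k, i] <- cmp["repl"]
      S[i, k] <- S[k, i] <- cmp["rich"]
    }
  }
  lt <- lower.tri(D)
  structure(list(D = D, repl = R, rich = S,
                 totals = c(D = mean(D[lt]), repl = mean(R[lt]),
                            rich = mean(S[lt])),
                 family = family, quantitative = quantitative),
            class = "beta_components")
}

pair_abc <- function(yi, yk) {
  c(A = sum(pmin(yi, yk)),
    B = sum(pmax(yi - yk, 0)),
    C = sum(pmax(yk - yi, 0)))
}

decompose_pair <- function(abc, family) {
  A <- abc[["A"]]; B <- abc[["B"]]; C <- abc[["C"]]
  den <- 2 * A + B + C
  if (den == 0) stop("pair of two all-zero rows: dissimilarity undefined")
  D <- (B + C) / den
  if (family == "podani") {
    repl <- 2 * min(B, C) / den
    rich <- abs(B - C) / den
  } else {
    repl <- if (A + min(B, C) == 0) 0 else min(B, C) / (A + min(B, C))
    rich <- D - repl
  }
  c(D = D, repl = repl, rich = rich)
}

#' @export
print.beta_components <- function(x, ...) {
  cat(sprintf(
    "%s decomposition (%s): mean D = %.4f = replacement %.4f + richness diff %.4f\n",
    if (x$family == "podani") "Podani-family" else "Baselga-family",
    if (x$quantitative) "quantitative" else "presence-absence",
    x$totals["D"], x$totals["repl"], x$totals["rich"]))
  invisible(x)
}

#' Temporal replacement/richness partition per cell
#'
#' For matched community matrices of two periods, decomposes each cell's
#' temporal dissimilarity (its period-1 vs period-2 profile) into
#' replacement and richness-difference components.
#'
#' @param m_t1,m_t2 community matrices with identical cells and species.
#' @inheritParams beta_components
#' @return data frame `cell_id`, `D`, `repl`, `rich`.
#' @export
temporal_components <- function(m_t1, m_t2, quantitative = TRUE,
                                family = c("podani", "baselga")) {
  family <- match.arg(family)
  m_t1 <- as.matrix(m_t1); m_t2 <- as.matrix(m_t2)
  stopifnot(identical(dimnames(m_t1), dimnames(m_t2)))
  if (!quantitative) { m_t1 <- (m_t1 > 0) * 1; m_t2 <- (m_t2 > 0) * 1 }
  res <- t(vapply(seq_len(nrow(m_t1)), function(i)
    decompose_pair(pair_abc(m_t1[i, ], m_t2[i, ]), family), numeric(3)))
  data.frame(cell_id = rownames(m_t1) %||% seq_len(nrow(m_t1)),
             D = res[, "D"], repl = res[, "repl"], rich = res[, "rich"],
             stringsAsFactors = FALSE, row.names = NULL)
}
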