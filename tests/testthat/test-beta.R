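# Hellinger machinery, PCoA, dispersion test, PERMANOVA, LCBD/SCBD,
# replacement/richness components.

test_that("Hellinger transform and distance obey their identities", {
  expect_equal(unname(hellinger(matrix(c(4, 0, 0), 1))[1, ]), c(1, 0, 0))
  expect_equal(unname(hellinger(matrix(c(1, 1, 2), 1))[1, ]),
               c(0.5, 0.5, 0.70710678), tolerance = 1e-8)
  expect_error(hellinger(rbind(A = c(1, 2), B = c(0, 0))), "B")

  # Euclidean distance on transformed rows equals the direct formula
  set.seed(2)
  x <- matrix(rpois(60, 4) + 1, 10, 6)
  d <- as.matrix(hellinger_dist(x))
  p <- x / rowSums(x)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(d[i, j], sqrt(sum((sqrt(p[i, ]) - sqrt(p[j, ]))^2)),
                 tolerance = 1e-12)

  # identical rows -> 0; disjoint compositions -> sqrt(2)
  expect_equal(as.numeric(hellinger_dist(rbind(c(2, 1), c(2, 1)))), 0)
  expect_equal(as.numeric(hellinger_dist(rbind(c(1, 0), c(0, 1)))), sqrt(2))

  # bound and triangle inequality on random 6-site fixtures
  for (s in 1:5) {
    set.seed(s)
    d6 <- as.matrix(hellinger_dist(matrix(runif(6 * 4), 6)))
    expect_true(all(d6 <= sqrt(2) + 1e-12))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d6[i, j], d6[i, k] + d6[k, j] + 1e-12)
  }
})

test_that("PCoA reconstructs distances and matches cmdscale", {
  # 2 sites at distance d -> coordinates +/- d/2
  d2 <- as.dist(matrix(c(0, 3, 3, 0), 2))
  pc2 <- pcoa(d2)
  expect_equal(sort(unname(pc2$points[, 1])), c(-1.5, 1.5))

  set.seed(5)
  x <- matrix(rpois(48, 5) + 1, 8, 6)
  d <- hellinger_dist(x)
  pc <- pcoa(d)
  expect_true(all(pc$values >= -1e-9))
  expect_equal(as.matrix(dist(pc$points)), as.matrix(d), tolerance = 1e-6,
               ignore_attr = TRUE)

  # independent oracle: classical MDS from stats
  cm <- cmdscale(d, k = ncol(pc$points), eig = TRUE)
  expect_equal(abs(pc$points), abs(cm$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pc$values[seq_along(cm$eig)], cm$eig, tolerance = 1e-8)
})

test_that("dispersion test: mirrored clouds give F = 0 and p = 1", {
  a <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, byrow = TRUE)
  b <- -a   # congruent mirrored cloud
  d <- dist(rbind(a, b))
  dt <- dispersion_test(d, rep(c("T1", "T2"), each = 4), n_perm = 99,
                        seed = 1)
  expect_equal(dt$F, 0, tolerance = 1e-20)
  expect_equal(dt$p_perm, 1)
  expect_equal(dt$direction, "none")
})

test_that("dispersion F equals the one-way ANOVA F on the z vector", {
  set.seed(9)
  x <- matrix(rpois(60, 5) + 1, 10, 6)
  g <- rep(c("T1", "T2"), each = 5)
  dt <- dispersion_test(hellinger_dist(x), g, n_perm = 19, seed = 1)
  fit <- stats::anova(stats::lm(dt$z ~ factor(g)))
  expect_equal(dt$F, fit$`F value`[1], tolerance = 1e-10)
})

test_that("dispersion distances agree with vegan::betadisper", {
  skip_if_not_installed("vegan")
  set.seed(10)
  x <- matrix(rpois(60, 5) + 1, 10, 6)
  g <- factor(rep(c("T1", "T2"), each = 5))
  d <- hellinger_dist(x)
  dt <- dispersion_test(d, g, n_perm = 19, seed = 1)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(dt$z), unname(bd$distances), tolerance = 1e-8)
})

test_that("permutation p-values match exhaustive enumeration on 3+3 sites", {
  skip_if_not_installed("vegan")
  set.seed(11)
  x <- matrix(rpois(36, 4) + 1, 6, 6)
  d <- hellinger_dist(x)
  g <- factor(rep(c("T1", "T2"), each = 3))

  # PERMANOVA: oracle F per assignment from vegan::adonis2
  pm <- permanova(d, g, enumerate = TRUE)
  expect_equal(pm$n_perm, 20)
  splits <- combn(6, 3)
  F_or <- apply(splits, 2, function(s) {
    gl <- factor(ifelse(seq_len(6) %in% s, "A", "B"))
    as.data.frame(vegan::adonis2(d ~ gl, permutations = 2))$F[1]
  })
  F_obs <- as.data.frame(vegan::adonis2(d ~ g, permutations = 2))$F[1]
  expect_equal(pm$F, F_obs, tolerance = 1e-10)
  expect_equal(pm$p_perm, mean(F_or >= F_obs - 1e-12))

  # dispersion: z fixed at observed groups, F enumerated over label splits
  dt <- dispersion_test(d, g, enumerate = TRUE)
  z <- vegan::betadisper(d, g, type = "centroid")$distances
  F_or2 <- apply(splits, 2, function(s) {
    gl <- factor(ifelse(seq_len(6) %in% s, "A", "B"))
    stats::anova(stats::lm(z ~ gl))$`F value`[1]
  })
  F_obs2 <- stats::anova(stats::lm(z ~ g))$`F value`[1]
  expect_equal(dt$F, F_obs2, tolerance = 1e-10)
  expect_equal(dt$p_perm, mean(F_or2 >= F_obs2 - 1e-12))

  # sampled permutation p is consistent with the enumerated value
  pm_s <- permanova(d, g, n_perm = 999, seed = 3)
  expect_lt(abs(pm_s$p_perm - pm$p_perm), 0.08)
})

test_that("PERMANOVA statistics match vegan::adonis2 and its identities", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rpois(120, 5) + 1, 20, 6)
  g <- factor(rep(c("T1", "T2"), each = 10))
  d <- hellinger_dist(x)
  pm <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- as.data.frame(vegan::adonis2(d ~ g, permutations = 2))
  expect_equal(pm$F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(pm$SS_between + pm$SS_within, pm$SS_total, tolerance = 1e-9)
  expect_gte(pm$R2, 0)
  expect_lte(pm$R2, 1)

  # SS_total is label-free
  pm2 <- permanova(d, sample(g), n_perm = 19, seed = 1)
  expect_equal(pm2$SS_total, pm$SS_total)

  # two groups with identical compositions: p near 1
  xx <- rbind(x[1:10, ], x[1:10, ])
  pm3 <- permanova(dist(hellinger(xx)), g, n_perm = 199, seed = 1)
  expect_gt(pm3$p_perm, 0.5)
})

test_that("LCBD/SCBD partition sums to one and matches the distance identity", {
  # two cells symmetric about their mean
  bp2 <- lcbd_scbd(hellinger(rbind(A = c(3, 1), B = c(1, 3))))
  expect_equal(unname(bp2$lcbd), c(0.5, 0.5))

  expect_error(lcbd_scbd(rbind(c(1, 2), c(1, 2))), "identical")

  set.seed(13)
  y <- hellinger(matrix(rpois(20, 4) + 1, 5, 4))
  bp <- lcbd_scbd(y)
  expect_equal(sum(bp$lcbd), 1, tolerance = 1e-12)
  expect_equal(sum(bp$scbd), 1, tolerance = 1e-12)
  expect_true(all(bp$lcbd >= 0) && all(bp$scbd >= 0))
  expect_equal(bp$SS_total, bp$SS_total_d, tolerance = 1e-9)
  expect_equal(bp$BD_total, bp$SS_total / 4)
})

test_that("LCBD matches a hand-computed 3-cell fixture and deltas sum to zero", {
  # cells (1,0), (0,1), (1,1): s_ij from column means (2/3, 2/3)
  y1 <- rbind(C1 = c(1, 0), C2 = c(0, 1), C3 = c(1, 1))
  bp1 <- lcbd_scbd(y1)
  expect_equal(unname(bp1$lcbd), c(5, 5, 2) / 12, tolerance = 1e-12)
  expect_equal(unname(bp1$scbd), c(0.5, 0.5), tolerance = 1e-12)

  y2 <- rbind(C1 = c(1, 1), C2 = c(0, 1), C3 = c(1, 0))
  bp2 <- lcbd_scbd(y2)
  dl <- delta_lcbd(bp1, bp2,
                   data.frame(cell_id = c("C1", "C2", "C3"), cx = 1:3,
                              cy = 0))
  expect_equal(dl$delta, c(-0.25, 0, 0.25), tolerance = 1e-12)
  expect_equal(sum(dl$delta), 0, tolerance = 1e-15)
  expect_equal(dl$cx, 1:3)

  bp_bad <- bp2
  names(bp_bad$lcbd) <- c("C1", "C2", "X")
  expect_error(delta_lcbd(bp1, bp_bad), "mismatch")
})

test_that("replacement/richness components decompose percentage difference", {
  x <- rbind(s1 = c(3, 1, 0), s2 = c(1, 1, 2), s3 = c(0, 2, 1))
  bc <- beta_components(x)
  # hand computation: pair(1,2) A=2 B=2 C=2; pair(1,3) A=1 B=3 C=2;
  # pair(2,3) A=2 B=2 C=1
  expect_equal(bc$D["s1", "s2"], 0.5)
  expect_equal(bc$repl["s1", "s2"], 0.5)
  expect_equal(bc$rich["s1", "s2"], 0)
  expect_equal(bc$D["s1", "s3"], 5 / 7)
  expect_equal(bc$repl["s1", "s3"], 4 / 7)
  expect_equal(bc$rich["s1", "s3"], 1 / 7)
  expect_equal(bc$D["s2", "s3"], 3 / 7)
  expect_equal(bc$repl["s2", "s3"], 2 / 7)
  expect_equal(bc$rich["s2", "s3"], 1 / 7)

  # identical sites -> all zero; D = repl + rich elementwise, both families
  expect_equal(beta_components(rbind(a = 1:3, b = 1:3))$totals,
               c(D = 0, repl = 0, rich = 0))
  set.seed(14)
  m <- matrix(rpois(40, 3), 8, 5)
  m[rowSums(m) == 0, 1] <- 1
  for (fam in c("podani", "baselga")) {
    bc2 <- beta_components(m, family = fam)
    expect_equal(bc2$D, bc2$repl + bc2$rich, tolerance = 1e-12)
    expect_true(all(bc2$D >= 0 & bc2$D <= 1))
    expect_true(all(bc2$repl >= -1e-15 & bc2$rich >= -1e-15))
  }

  # nested presence-absence sites: pure richness difference
  nest <- rbind(big = c(1, 1, 1, 1), small = c(1, 1, 0, 0))
  bn <- beta_components(nest, quantitative = FALSE)
  expect_equal(bn$repl["big", "small"], 0)
  expect_equal(bn$D["big", "small"], bn$rich["big", "small"])

  expect_error(beta_components(rbind(c(0, 0), c(0, 0))), "all-zero")
})

test_that("temporal components partition per-cell temporal dissimilarity", {
  m1 <- rbind(C1 = c(3, 1, 0), C2 = c(1, 1, 2))
  m2 <- rbind(C1 = c(1, 1, 2), C2 = c(1, 1, 2))
  tc <- temporal_components(m1, m2)
  expect_equal(tc$D, c(0.5, 0))
  expect_equal(tc$D, tc$repl + tc$rich, tolerance = 1e-12)
})

test_that("PERMANOVA SS_total equals the LCBD sum of squares", {
  set.seed(15)
  y <- hellinger(matrix(rpois(60, 5) + 1, 10, 6))
  bp <- lcbd_scbd(y)
  pm <- permanova(dist(y), rep(c("a", "b"), 5), n_perm = 19, seed = 1)
  expect_equal(pm$SS_total, bp$SS_total, tolerance = 1e-9)
})
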