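# CWM, temperature index, guild aggregation, trait-change inference.

mk_traits <- function(sp, shade = NULL, seed_mass = NULL) {
  n <- length(sp)
  data.frame(species = sp,
             shade = shade %||% rep(3, n),
             drought = rep(2, n), waterlogging = rep(2, n),
             seed_mass_mg = seed_mass %||% rep(50, n),
             temp_pref_c = rep(7, n), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CWM is the renormalized abundance-weighted trait mean", {
  m <- rbind(C1 = c(1, 0), C2 = c(0.5, 0.5))
  tr <- mk_traits(c("A", "B"), shade = c(1, 5))
  colnames(m) <- c("A", "B")
  v <- cwm(m, tr, "shade")
  expect_equal(as.numeric(v), c(1, 3))

  # seed mass enters as natural log
  vs <- cwm(m, mk_traits(c("A", "B"), seed_mass = c(10, 1000)), "seed_mass")
  expect_equal(unname(vs[1]), log(10))
  expect_equal(unname(vs[2]), mean(log(c(10, 1000))))

  # direct-formula oracle on a random fixture
  set.seed(20)
  mm <- matrix(runif(40), 8, 5)
  mm <- mm / rowSums(mm)
  colnames(mm) <- sprintf("S%d", 1:5)
  t_j <- runif(5, 1, 5)
  tr2 <- mk_traits(colnames(mm), shade = t_j)
  expect_equal(as.numeric(cwm(mm, tr2, "shade")),
               as.numeric(mm %*% t_j / rowSums(mm)), tolerance = 1e-12)

  # bounded by contributing trait extremes
  v2 <- cwm(mm, tr2, "shade")
  expect_true(all(v2 >= min(t_j) - 1e-12 & v2 <= max(t_j) + 1e-12))
})

test_that("missing traits are renormalized away, starved cells error", {
  tr <- mk_traits(c("A", "B", "C"), shade = c(2, NA, 4))
  m <- rbind(C1 = c(0.6, 0.4, 0), C2 = c(0.25, 0.25, 0.5))
  colnames(m) <- c("A", "B", "C")
  v <- cwm(m, tr, "shade")
  expect_equal(unname(v[1]), 2)                       # B's weight dropped
  expect_equal(unname(v[2]), (0.25 * 2 + 0.5 * 4) / 0.75)
  expect_equal(unname(attr(v, "contributing")), c(0.6, 0.75))

  m2 <- rbind(C1 = c(0.5, 0.5, 0), C2 = c(0, 1, 0))
  colnames(m2) <- c("A", "B", "C")
  expect_error(cwm(m2, tr, "shade"), "C2")
})

test_that("temperature index samples the raster at occurrence points", {
  grid <- structure(list(ncols = 4, nrows = 3, xll = 0, yll = 0,
                         cellsize = 10, nodata = -9999,
                         values = matrix(7, 3, 4)), class = "ascii_grid")
  occ <- data.frame(x = c(5, 15, 35), y = c(5, 25, 12))
  expect_equal(as.numeric(temperature_index(occ, grid)), 7)

  # two points over cells at 5 and 15 degrees -> 10
  g2 <- structure(list(ncols = 2, nrows = 1, xll = 0, yll = 0,
                       cellsize = 10, nodata = NULL,
                       values = matrix(c(5, 15), 1, 2)),
                  class = "ascii_grid")
  expect_equal(as.numeric(temperature_index(
    data.frame(x = c(5, 15), y = c(5, 5)), g2)), 10)

  # row orientation: matrix row 1 is the northernmost row
  grid$values <- matrix(rep(1:3, 4), 3, 4)   # row i has value i
  occ2 <- data.frame(x = c(5, 5), y = c(25, 5))  # north row, south row
  v2 <- temperature_index(occ2, grid)
  expect_equal(as.numeric(v2), mean(c(1, 3)))

  # translation equivariance
  gridc <- grid
  gridc$values <- gridc$values + 3
  expect_equal(as.numeric(temperature_index(occ2, gridc)),
               as.numeric(temperature_index(occ2, grid)) + 3)

  # out-of-extent points dropped with a count; all-out errors
  occ3 <- data.frame(x = c(5, -100), y = c(5, 5))
  v3 <- temperature_index(occ3, grid)
  expect_equal(attr(v3, "n_dropped"), 1)
  expect_error(temperature_index(data.frame(x = -1, y = -1), grid),
               "no usable occurrences")
})

test_that("linear-gradient raster matches a brute-force per-point mean", {
  nr <- 6; nc <- 8; cs <- 10
  vals <- outer(seq_len(nr), seq_len(nc), function(r, co) 2 * co + 0.5 * r)
  grid <- structure(list(ncols = nc, nrows = nr, xll = 0, yll = 0,
                         cellsize = cs, nodata = NULL, values = vals),
                    class = "ascii_grid")
  set.seed(21)
  occ <- data.frame(x = runif(40, 0, nc * cs), y = runif(40, 0, nr * cs))
  brute <- mean(sapply(seq_len(40), function(i) {
    col <- floor(occ$x[i] / cs) + 1
    row <- nr - floor(occ$y[i] / cs)
    vals[row, col]
  }))
  expect_equal(as.numeric(temperature_index(occ, grid)), brute)
})

test_that("ASCII grids round-trip through write and read", {
  grid <- structure(list(ncols = 5, nrows = 4, xll = -10, yll = 20,
                         cellsize = 2.5, nodata = -9999,
                         values = matrix(round(rnorm(20), 4), 4, 5)),
                    class = "ascii_grid")
  grid$values[2, 3] <- NA
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(grid, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, grid$values)
  expect_equal(back$cellsize, 2.5)
  expect_equal(back$xll, -10)
})

test_that("guild values are sums of member-species statistics", {
  sim <- small_sim(seed = 31)
  fn <- small_fishnet(sim)
  rr <- sim_records(sim)
  guilds <- pool_guilds(sim$pool)
  members <- split(guilds$species, guilds$guild)
  members <- lapply(members, intersect, x = rr$species)
  ids <- lapply(fn$members, function(p) p[1:10])
  for (ms in c("occurrence", "relative_abundance", "basal_area")) {
    gl <- stat_species(members, ms)(rr$t1, ids)
    sp <- stat_species(rr$species, ms)(rr$t1, ids)
    for (g in names(members))
      expect_equal(gl[, g],
                   rowSums(sp[, members[[g]], drop = FALSE]),
                   tolerance = 1e-12)
  }
  # single-guild community has relative abundance 1 everywhere
  one <- stat_species(list(all = rr$species), "relative_abundance")(rr$t1, ids)
  expect_true(all(abs(one - 1) < 1e-12))
})

test_that("guild tests flag inflated guilds under an abundance shift", {
  null_p <- numeric(50)
  shift_p <- numeric(50)
  for (k in 1:50) {
    cfgs <- list(
      scenario_config(seed = 5000 + k),
      scenario_config("abundance_shift", target_guild = "northern",
                      multiplier = 2, seed = 5000 + k))
    ps <- sapply(cfgs, function(cf) {
      sim <- simulate_resurvey(cf)
      fn <- small_fishnet(sim)
      rr <- sim_records(sim)
      res <- guild_change_tests(rr$t1, rr$t2, fn, rr$species,
                                pool_guilds(sim$pool),
                                spec = subsample_spec(n = 10, r = 10,
                                                      seed = 5000 + k))
      res$mean_p[res$species_or_group == "northern"]
    })
    null_p[k] <- ps[1]
    shift_p[k] <- ps[2]
  }
  expect_lt(median(shift_p), median(null_p))
})

test_that("trait change tests recover identical periods and ignore species order", {
  sim <- small_sim(seed = 33)
  fn <- small_fishnet(sim)
  rr <- sim_records(sim)
  tr <- pool_traits(sim$pool)
  r2same <- rr$t1
  r2same$period <- "T2"
  res <- trait_change_tests(rr$t1, rr$t2, fn, rr$species, tr,
                            spec = subsample_spec(n = 10, r = 3, seed = 1))
  res_same <- trait_change_tests(rr$t1, r2same, fn, rr$species, tr,
                                 spec = subsample_spec(n = 10, r = 3,
                                                       seed = 1))
  expect_true(all(res_same$mean_p == 1))
  d0 <- attr(res_same, "delta")
  expect_true(all(abs(as.matrix(d0[, TRAIT_NAMES <- c("shade", "drought",
                                                      "waterlogging",
                                                      "seed_mass",
                                                      "temp_pref")])) < 1e-12))

  # delta is invariant to species ordering
  res_rev <- trait_change_tests(rr$t1, rr$t2, fn, rev(rr$species), tr,
                                spec = subsample_spec(n = 10, r = 3,
                                                      seed = 1))
  expect_equal(attr(res, "delta")$shade, attr(res_rev, "delta")$shade,
               tolerance = 1e-12)
  expect_true(all(res$mean_p >= 0 & res$mean_p <= 1))
})

test_that("trait SCBD shares sum to one and match a hand-computed fixture", {
  m <- rbind(C1 = c(1, 0), C2 = c(0, 1), C3 = c(0.5, 0.5))
  colnames(m) <- c("A", "B")
  tr <- mk_traits(c("A", "B"), shade = c(2, 4))
  # x = p * t: rows (2,0), (0,4), (1,2); column SS: 2 and 8
  out <- trait_scbd(m, m, tr, "shade")
  expect_equal(out$share_t1, c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(sum(out$share_t1), 1)
  expect_equal(out$change, c(0, 0))

  # single species: its share is 1
  m1 <- matrix(1, 3, 1, dimnames = list(NULL, "A"))
  out1 <- trait_scbd(m1, m1, mk_traits("A", shade = 3), "shade")
  expect_equal(out1$share_t1, 1)
})
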