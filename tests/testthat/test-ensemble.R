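# RMSF/B-factor, RMSD/Rg series, gromos clustering, DCCM, region blocks.

test_that("RMSF is zero for static ensembles and d/2 for two-pose flipping", {
  base <- matrix(rnorm(30, sd = 5), 10)
  static <- toy_ensemble(rep(list(base), 5))
  prof <- rmsf_profile(static)
  expect_true(all(prof$rmsf == 0))
  expect_true(all(prof$b_pred == 0))

  flip <- list(base, base, base, base)
  flip[[2]][3, ] <- flip[[2]][3, ] + c(2, 0, 0)
  flip[[4]][3, ] <- flip[[4]][3, ] + c(2, 0, 0)
  prof2 <- rmsf_profile(toy_ensemble(flip), superpose = FALSE)
  expect_equal(prof2$rmsf[3], 1)  # alternates between poses 2 A apart
  expect_equal(prof2$rmsf[-3], rep(0, 9))
  expect_error(rmsf_profile(toy_ensemble(list(base))), "at least 2")
})

test_that("B-factor conversion is exactly (8 pi^2 / 3) rmsf^2", {
  set.seed(3)
  frames <- lapply(1:6, function(k) matrix(rnorm(30, sd = 5), 10))
  prof <- rmsf_profile(toy_ensemble(frames), superpose = FALSE)
  expect_equal(prof$b_pred, 8 * pi^2 / 3 * prof$rmsf^2, tolerance = 1e-12)
})

test_that("Gaussian jitter gives rmsf = sigma * sqrt(3)", {
  set.seed(17)
  base <- matrix(rnorm(90, sd = 10), 30)
  m <- 3000L
  arr <- array(rep(base, each = m), c(m, 30, 3)) +
    array(rnorm(m * 90, sd = 0.5), c(m, 30, 3))
  topo <- toy_ensemble(list(base))$topology
  prof <- rmsf_profile(conformer_ensemble(topo, arr), superpose = FALSE)
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.02)
})

test_that("RMSF agrees with bio3d on a shared pre-superposed ensemble", {
  skip_if_not_installed("bio3d")
  set.seed(23)
  frames <- lapply(1:8, function(k)
    matrix(rnorm(24, sd = 3), 8) * 0.2 + matrix(1:24, 8))
  ens <- toy_ensemble(frames)
  prof <- rmsf_profile(ens, superpose = FALSE)
  xyz <- t(vapply(1:8, function(k) as.numeric(t(ens$frames[k, , ])),
                  numeric(24)))
  # bio3d::rmsf uses the n-1 (sample) variance; this package uses the mean
  # square deviation, so rescale by sqrt((m-1)/m) before comparing
  expect_equal(prof$rmsf, as.numeric(bio3d::rmsf(xyz)) * sqrt(7 / 8),
               tolerance = 1e-6)
})

test_that("per-frame series compose superposition and gyration correctly", {
  set.seed(9)
  base <- matrix(rnorm(36, sd = 6), 12)
  shifts <- list(c(0, 0, 0), c(10, 0, 0), c(0, -5, 3))
  rigid <- toy_ensemble(lapply(shifts, function(s) sweep(base, 2, s, `+`)))
  ser <- ensemble_series(rigid)
  expect_equal(ser$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_equal(ser$rg, rep(radius_of_gyration(base), 3), tolerance = 1e-9)

  centered <- sweep(base, 2, colMeans(base))
  scaled <- toy_ensemble(list(centered, centered * 2))
  expect_equal(ensemble_series(scaled)$rg[2],
               2 * ensemble_series(scaled)$rg[1], tolerance = 1e-9)

  rnd <- toy_ensemble(lapply(1:5, function(k) matrix(rnorm(36, sd = 4), 12)))
  ser2 <- ensemble_series(rnd)
  for (k in 1:5) {
    expect_equal(ser2$rmsd[k],
                 kabsch_superpose(rnd$frames[k, , ], rnd$frames[1, , ])$rmsd)
    expect_equal(ser2$rg[k], radius_of_gyration(rnd$frames[k, , ]))
  }
})

test_that("gromos clustering matches construction and the reference sweep", {
  set.seed(31)
  center1 <- matrix(rnorm(30, sd = 8), 10)
  center2 <- matrix(rnorm(30, sd = 8), 10)  # a genuinely different shape
  grp <- c(lapply(1:5, function(k) center1 + rnorm(30, sd = 0.2)),
           lapply(1:5, function(k) center2 + rnorm(30, sd = 0.2)))
  ens <- toy_ensemble(grp)
  cl <- gromos_cluster(ens, cutoff = 5)
  expect_equal(length(cl$centers), 2L)
  expect_equal(cl$assignments[1:5], rep(1L, 5))
  expect_equal(cl$assignments[6:10], rep(2L, 5))
  ref <- gromos_reference(dimerhinge:::pairwise_rmsd(ens), 5)
  expect_equal(cl$assignments, ref$assignments)
  expect_equal(cl$centers, ref$centers)

  # everything within cutoff: one cluster
  one <- gromos_cluster(ens, cutoff = 1e4)
  expect_equal(length(one$centers), 1L)
  # vanishing cutoff with distinct frames: all singletons
  tiny <- gromos_cluster(ens, cutoff = 1e-9)
  expect_equal(length(tiny$centers), 10L)
  expect_error(gromos_cluster(ens, cutoff = -1), "positive")
})

test_that("gromos clustering equals the reference on random small ensembles", {
  for (seed in 1:15) {
    set.seed(seed)
    m <- sample(2:8, 1)
    ens <- toy_ensemble(lapply(seq_len(m), function(k)
      matrix(rnorm(18, sd = sample(c(0.5, 3, 8), 1)), 6)))
    D <- dimerhinge:::pairwise_rmsd(ens)
    cutoff <- stats::quantile(D[upper.tri(D)], runif(1))
    if (cutoff <= 0) cutoff <- 0.1
    got <- gromos_cluster(ens, cutoff = cutoff)
    ref <- gromos_reference(D, cutoff)
    expect_equal(got$assignments, ref$assignments)
    expect_equal(got$centers, ref$centers)
  }
})

test_that("cluster count is non-increasing in the cutoff", {
  set.seed(40)
  ens <- toy_ensemble(lapply(1:12, function(k) matrix(rnorm(24, sd = 5), 8)))
  counts <- vapply(c(1, 5, 20), function(ct)
    length(gromos_cluster(ens, cutoff = ct)$centers), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DCCM is +1/-1 for in/anti-phase motion and bounded everywhere", {
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE)
  drift <- seq(-1, 1, length.out = 8)
  inphase <- lapply(drift, function(d) base + rbind(c(d, 0, 0), c(d, 0, 0), 0))
  cc <- suppressWarnings(dccm(toy_ensemble(inphase), superpose = FALSE))
  expect_equal(cc$matrix[1, 2], 1, tolerance = 1e-12)

  anti <- lapply(drift, function(d) base + rbind(c(d, 0, 0), c(-d, 0, 0), 0))
  cc2 <- suppressWarnings(dccm(toy_ensemble(anti), superpose = FALSE))
  expect_equal(cc2$matrix[1, 2], -1, tolerance = 1e-12)
  # static third atom: zero row with unit diagonal, and a warning
  expect_warning(dccm(toy_ensemble(anti), superpose = FALSE), "zero-variance")
  expect_equal(cc2$matrix[3, 1], 0)
  expect_equal(cc2$matrix[3, 3], 1)

  set.seed(55)
  rnd <- toy_ensemble(lapply(1:10, function(k) matrix(rnorm(36, sd = 2), 12)))
  M <- dccm(rnd)$matrix
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(diag(M), rep(1, 12))
  expect_true(all(M >= -1 & M <= 1))
})

test_that("independent atoms decorrelate at the null bound", {
  set.seed(61)
  m <- 2000L
  base <- matrix(c(0, 0, 0, 20, 0, 0, 0, 20, 0, 20, 20, 0), 4, byrow = TRUE)
  arr <- array(rep(base, each = m), c(m, 4, 3)) +
    array(rnorm(m * 12, sd = 0.5), c(m, 4, 3))
  cc <- dccm(conformer_ensemble(toy_ensemble(list(base))$topology, arr),
             superpose = FALSE)
  off <- cc$matrix[upper.tri(cc$matrix)]
  expect_true(all(abs(off) < 3 / sqrt(m)))
})

test_that("DCCM with superposition is rigid-motion invariant and matches bio3d", {
  set.seed(71)
  frames <- lapply(1:12, function(k)
    matrix(rnorm(30, sd = 4), 10) * 0.3 + matrix(seq(0, 45, 5), 10, 3))
  ens <- toy_ensemble(frames)
  M1 <- dccm(ens)$matrix
  R <- random_rotation(72)
  moved <- lapply(frames, function(x) sweep(x %*% t(R), 2, c(7, -2, 1), `+`))
  M2 <- dccm(toy_ensemble(moved))$matrix
  expect_equal(M1, M2, tolerance = 1e-6)

  skip_if_not_installed("bio3d")
  # compare on the package's superposed coordinates (bio3d's own fitting
  # differs slightly; the correlation formula is what is cross-checked)
  arr <- dimerhinge:::superpose_frames(ens$frames)
  xyz <- t(vapply(1:12, function(k) as.numeric(t(arr[k, , ])), numeric(30)))
  ref <- bio3d::dccm.xyz(xyz)
  expect_equal(M1, unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("region blocks summarize coupled and independent motion", {
  set.seed(81)
  n <- 12; m <- 400
  base <- matrix(rnorm(3 * n, sd = 10), n)
  drive <- rnorm(m)
  arr <- array(rep(base, each = m), c(m, n, 3))
  arr[, 1:4, 1] <- arr[, 1:4, 1] + drive          # "loop" block
  arr[, 5:8, 1] <- arr[, 5:8, 1] - drive          # "helix" block, anti-phase
  arr[, 9:12, ] <- arr[, 9:12, ] +
    array(rnorm(m * 12, sd = 1), c(m, 4, 3))       # independent block
  ens <- conformer_ensemble(toy_ensemble(list(base))$topology, arr)
  cc <- dccm(ens, superpose = FALSE)
  anti <- region_cross_correlation(cc, 1:4, 5:8)
  expect_lt(anti$mean, -0.9)
  self <- region_cross_correlation(cc, 1:4, 1:4)
  expect_equal(self$max, 1)
  nullb <- region_cross_correlation(cc, 1:4, 9:12)
  expect_lt(abs(nullb$mean), 0.2)
  expect_error(region_cross_correlation(cc, 1:4, 10:15), "absent")
})
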