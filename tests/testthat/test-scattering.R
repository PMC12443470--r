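# Debye profiles, Guinier analysis, chi-square fitting, ensemble screening.

test_that("Debye profile reproduces analytic limits and the brute-force sum", {
  one <- debye_profile(matrix(c(0, 0, 0), 1), q_grid = c(0, 0.1, 0.3))
  expect_equal(one$I, rep(1, 3))

  two <- debye_profile(rbind(c(0, 0, 0), c(7.3, 0, 0)), q_grid = c(0, 0.05))
  expect_equal(two$I[1], 4)  # (sum f)^2 at q = 0

  set.seed(11)
  pts <- matrix(rnorm(15, sd = 5), 5)
  f <- c(1, 1, 1, 1, 1)
  prof <- debye_profile(pts, f, q_grid = c(0, 0.1))
  expect_equal(prof$I[2], debye_brute(pts, f, 0.1), tolerance = 1e-12)

  # weighted beads against the same oracle
  fw <- c(2, 0.5, 1, 3, 1.2)
  pw <- debye_profile(pts, fw, q_grid = c(0, 0.07, 0.2))
  for (k in 1:3)
    expect_equal(pw$I[k], debye_brute(pts, fw, pw$q[k]), tolerance = 1e-12)
  expect_equal(pw$I[1], sum(fw)^2)
})

test_that("Debye profile is invariant under rigid motion", {
  set.seed(4)
  pts <- matrix(rnorm(60, sd = 8), 20)
  R <- random_rotation(9)
  moved <- sweep(pts %*% t(R), 2, c(12, -3, 40), `+`)
  q <- seq(0, 0.4, length.out = 21)
  expect_equal(debye_profile(moved, q_grid = q)$I,
               debye_profile(pts, q_grid = q)$I, tolerance = 1e-10)
})

test_that("radius of gyration matches closed forms and direct evaluation", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(6, 0, 0))), 3)
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0)

  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  direct <- sqrt(mean(rowSums(sweep(tetra, 2, colMeans(tetra))^2)))
  expect_equal(radius_of_gyration(tetra), direct, tolerance = 1e-12)
  expect_equal(direct, sqrt(3 / 8), tolerance = 1e-12)  # edge-1 tetrahedron

  expect_error(radius_of_gyration(tetra, weights = rep(0, 4)), "zero")
})

test_that("Guinier fit recovers exact Gaussian curves and coordinate Rg", {
  q <- seq(0.001, 0.2, length.out = 120)
  exact <- saxs_curve(q, 100 * exp(-q^2 * 20^2 / 3))
  g <- guinier_fit(exact)
  expect_equal(g$I0, 100, tolerance = 1e-9)
  expect_equal(g$rg, 20, tolerance = 1e-9)

  set.seed(21)
  beads <- matrix(rnorm(150, sd = 6), 50)
  rg_coord <- radius_of_gyration(beads)
  prof <- debye_profile(beads, q_grid = seq(0.001, 0.3, length.out = 200))
  g2 <- guinier_fit(prof)
  expect_lt(abs(g2$rg - rg_coord) / rg_coord, 0.02)

  # error decreases as the window tightens (slope-limit property)
  errs <- vapply(c(1.3, 0.8, 0.5), function(lim)
    abs(guinier_fit(prof, qRg_limit = lim)$rg - rg_coord), numeric(1))
  expect_true(all(diff(errs) < 0))

  far <- saxs_curve(seq(0.2, 0.4, 0.01), 100 * exp(-seq(0.2, 0.4, 0.01)^2 * 400 / 3))
  expect_error(guinier_fit(far), "Guinier window")
})

test_that("profile fitting matches the grid-search oracle", {
  q <- c(0.01, 0.02, 0.03)
  calc <- saxs_curve(q, c(4, 3, 2))
  expc <- saxs_curve(q, 3 * c(4, 3, 2), rep(1, 3))
  fit <- fit_profile(calc, expc)
  expect_equal(fit$scale_c, 3)
  expect_equal(fit$chi2, 0)

  q4 <- c(0.01, 0.02, 0.03, 0.04)
  calc4 <- saxs_curve(q4, c(4, 3, 2, 1))
  exp4 <- saxs_curve(q4, c(8.2, 6.1, 3.9, 2.1), rep(0.2, 4))
  fit4 <- fit_profile(calc4, exp4)
  oracle <- grid_fit_oracle(c(4, 3, 2, 1), c(8.2, 6.1, 3.9, 2.1),
                            rep(0.2, 4), dof = 3)
  expect_equal(fit4$scale_c, oracle$scale, tolerance = 1e-6)
  expect_equal(fit4$chi2, oracle$chi2, tolerance = 1e-6)

  wide <- saxs_curve(c(0.005, 0.02, 0.05), c(1, 1, 1), rep(1, 3))
  expect_error(fit_profile(calc, wide), "extends beyond")
})

test_that("chi-square is invariant under joint rescaling of I_exp and sigma", {
  set.seed(5)
  q <- seq(0.01, 0.2, length.out = 30)
  calc <- saxs_curve(q, 50 * exp(-q^2 * 100))
  expc <- saxs_curve(q, 2.4 * calc$I * (1 + rnorm(30, sd = 0.03)),
                     0.05 * calc$I)
  base <- fit_profile(calc, expc)
  for (k in c(0.2, 5, 1000)) {
    scaled <- saxs_curve(q, k * expc$I, k * expc$sigma)
    expect_equal(fit_profile(calc, scaled)$chi2, base$chi2, tolerance = 1e-10)
  }
  # normalization conventions divide the same RSS differently
  rss <- base$chi2 * (30 - 1)
  expect_equal(fit_profile(calc, expc, normalization = "n")$chi2, rss / 30)
  expect_equal(fit_profile(calc, expc, normalization = "n-1")$chi2, rss / 29)
})

test_that("background fitting recovers an added constant offset", {
  q <- seq(0.01, 0.2, length.out = 25)
  calc <- saxs_curve(q, 80 * exp(-q^2 * 150))
  expc <- saxs_curve(q, 1.7 * calc$I + 4.2, 0.1 * calc$I + 0.5)
  fit <- fit_profile(calc, expc, fit_background = TRUE)
  expect_equal(fit$scale_c, 1.7, tolerance = 1e-9)
  expect_equal(fit$offset_b, 4.2, tolerance = 1e-9)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
})

test_that("ensemble screening selects the generating frame", {
  spec <- small_spec(theta_list = seq(0, 36, by = 4), sigma_thermal = 0.4,
                     seed = 13)
  ens <- generate_hinge_ensemble(spec)
  qg <- seq(0.01, 0.3, length.out = 50)
  exact <- synth_saxs_experiment(ensemble_frame(ens, 7), noise_frac = 0,
                                 floor_frac = 0, q_grid = qg)
  exact_sigma <- saxs_curve(exact$q, exact$I, 0.01 * exact$I)
  scr <- screen_ensemble(ens, exact_sigma)
  expect_equal(scr$best_frame, 7L)
  expect_lt(scr$chi2_per_frame[7], 1e-10)
  expect_true(all(scr$chi2_per_frame[-7] > scr$chi2_per_frame[7]))
  expect_equal(scr$table$chi2, scr$chi2_per_frame)

  # all frames identical: every chi2 equal, tie broken to the first frame
  tie <- toy_ensemble(rep(list(matrix(rnorm(30, sd = 5), 10)), 4))
  prof <- debye_profile(tie$frames[1, , ], q_grid = qg)
  scr_tie <- screen_ensemble(tie, saxs_curve(qg, 2 * prof$I, 0.02 * prof$I))
  expect_equal(scr_tie$best_frame, 1L)
  expect_equal(max(scr_tie$chi2_per_frame) - min(scr_tie$chi2_per_frame), 0)
})

test_that("best-frame recovery degrades monotonically with noise", {
  spec <- small_spec(theta_list = seq(0, 38, by = 2), sigma_thermal = 0.5,
                     seed = 42)
  ens <- generate_hinge_ensemble(spec)
  qg <- seq(0.01, 0.35, length.out = 70)
  idx <- which(ens$topology$atoms$atom_name == "CA")
  profs <- lapply(seq_len(n_frames(ens)), function(k)
    debye_profile(ens$frames[k, idx, ], q_grid = qg))
  jstar <- 8L
  truth <- profs[[jstar]]$I
  recover_rate <- function(noise, n_rep = 30) {
    hits <- 0L
    for (s in seq_len(n_rep)) {
      set.seed(1000 + s)
      expc <- saxs_curve(qg, truth * (1 + rnorm(length(qg), sd = noise)),
                         noise * truth)
      chi2 <- vapply(profs, function(p) fit_profile(p, expc)$chi2, numeric(1))
      hits <- hits + (abs(which.min(chi2) - jstar) <= 1L)
    }
    hits / n_rep
  }
  rates <- vapply(c(0.02, 0.10, 0.30), recover_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gte(rates[1], rates[3])
})
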