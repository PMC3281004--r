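# Inverse-estimation tests. The full noisy deep-dip parameter-recovery
# study lives in the acceptance suite; here the estimator is exercised
# on small, fast cases.

test_that("shape mismatch matches a hand-written reference", {
  ct <- resample_to_s_grid(hemisphere_contour(n = 101), 50)
  obs <- observation_from_contour(ct)
  expect_equal(shape_mismatch(ct, obs), 0, tolerance = 1e-20)

  shifted <- ct
  shifted$r <- ct$r + 0.03
  expect_equal(shape_mismatch(shifted, obs), 0.03^2, tolerance = 1e-12)

  db <- resample_to_s_grid(dumbbell_contour(), 50)
  ref <- mean((db$r - obs$r_mean)^2 +
    ((db$z - db$z[1]) - (obs$z_mean - obs$z_mean[1]))^2)
  expect_equal(shape_mismatch(db, obs), ref, tolerance = 1e-12)

  # SD weighting floors tiny variances at the 10th percentile
  obs2 <- obs
  obs2$r_sd <- seq(0.01, 0.1, length.out = 50)
  obs2$z_sd <- rep(0.05, 50)
  vr <- pmax(obs2$r_sd^2, stats::quantile(obs2$r_sd^2, 0.1))
  refw <- mean((shifted$r - obs2$r_mean)^2 / vr)
  expect_equal(shape_mismatch(shifted, obs2, sd_weighting = TRUE), refw,
    tolerance = 1e-12
  )

  bad <- resample_to_s_grid(ct, 30)
  expect_error(shape_mismatch(bad, obs), NA) # resampled internally, no error
})

test_that("a spherical observation yields a constant profile under the gauge", {
  eq <- solve_equilibrium(4 * pi / 3, 4 * pi, n_nodes = 80)
  obs <- observation_from_contour(eq$contour)
  cfg <- inverse_config("nodal", n_basis = 6, omega1 = 1e-6, gamma = 0,
    n_nodes = 80, maxit = 40)
  res <- estimate_kc(obs, cfg, init_profile = stiffness_profile("constant", 0))
  lk <- log_kc(res$profile, seq(0, 1, length.out = 101))
  expect_lt(max(abs(lk)), 0.05)
  expect_equal(res$total_cost,
    res$mismatch_cost + cfg$omega1 * res$smoothness_cost,
    tolerance = 1e-10
  )
})

test_that("a moderate equatorial dip is recovered noiselessly (Method 2)", {
  va <- va_for_v(0.88)
  depth <- log(10)
  truth <- stiffness_profile("cosine_basis", c(-depth / 2, depth / 2))
  eq <- solve_equilibrium(va$V, va$A, stiffness_profile("constant", 0), 5,
    n_nodes = 120)
  for (frac in c(0.5, 1)) {
    eq <- solve_equilibrium(va$V, va$A, profile_log_scale(truth, frac), 5,
      n_nodes = 120, init = eq$contour)
  }
  obs <- observation_from_contour(eq$contour)
  cfg <- inverse_config("cosine_basis", n_basis = 3, omega1 = 1e-8,
    gamma = 5, n_nodes = 100, maxit = 100)
  res <- estimate_kc(obs, cfg,
    init_profile = stiffness_profile("cosine_basis", c(-0.75, 0.75)))
  sg <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(log_kc(res$profile, sg) - log_kc(truth, sg))), 0.15)
  expect_lt(res$mismatch_cost, 1e-6)
})

test_that("gauge invariance at gamma = 0: scaled initializations agree after normalization", {
  va <- va_for_v(0.95)
  prof <- stiffness_profile("cosine_basis", c(-0.4, 0.4))
  eq <- solve_equilibrium(va$V, va$A, prof, 0, n_nodes = 100)
  obs <- observation_from_contour(eq$contour)
  # the shape itself is scale-invariant at gamma = 0, so the mismatch is too
  eq2 <- solve_equilibrium(va$V, va$A, scale_profile(prof, 5), 0,
    n_nodes = 100, init = eq$contour)
  expect_lt(contour_rmsd(eq$contour, eq2$contour), 1e-4)

  # rescaled initializations map to the same starting parameters in the
  # normalized gauge ...
  cfg <- inverse_config("nodal", n_basis = 5, omega1 = 1e-6, gamma = 0,
    n_nodes = 80, maxit = 80)
  p1 <- furrowbend:::par_from_profile(prof, cfg, obs)
  p2 <- furrowbend:::par_from_profile(scale_profile(prof, 10), cfg, obs)
  expect_equal(p1, p2, tolerance = 1e-12)

  # ... and the estimator returns the same normalized profile from both
  # (agreement up to optimizer tolerance; the trajectories are identical
  # apart from floating-point rounding of the rescaled input)
  r1 <- estimate_kc(obs, cfg, init_profile = prof)
  r2 <- estimate_kc(obs, cfg, init_profile = scale_profile(prof, 10))
  sg <- seq(0, 1, length.out = 51)
  expect_lt(max(abs(log_kc(r1$profile, sg) - log_kc(r2$profile, sg))), 0.2)
})

test_that("smoothness weight drives the estimate towards constancy monotonically", {
  va <- va_for_v(0.9)
  truth <- stiffness_profile("cosine_basis", c(-0.6, 0.6))
  eq <- solve_equilibrium(va$V, va$A, truth, 5, n_nodes = 100)
  obs <- observation_from_contour(eq$contour)
  sm <- vapply(c(1e-8, 1e-4, 1), function(om) {
    cfg <- inverse_config("cosine_basis", n_basis = 3, omega1 = om,
      gamma = 5, n_nodes = 80, maxit = 40)
    estimate_kc(obs, cfg, init_profile = truth)$smoothness_cost
  }, numeric(1))
  expect_true(all(diff(sm) <= 1e-8))
  # omega1 -> infinity limit: essentially constant profile
  expect_lt(sm[3], 1e-2)
})

test_that("timecourse estimation runs sequentially with warm starts", {
  va1 <- va_for_v(0.95)
  va2 <- va_for_v(0.90)
  prof <- stiffness_profile("cosine_basis", c(-0.5, 0.5))
  o1 <- observation_from_contour(
    solve_equilibrium(va1$V, va1$A, prof, 5, n_nodes = 100)$contour, "0.8-0.7"
  )
  o2 <- observation_from_contour(
    solve_equilibrium(va2$V, va2$A, prof, 5, n_nodes = 100)$contour, "0.7-0.6"
  )
  cfg <- inverse_config("cosine_basis", n_basis = 2, omega1 = 1e-8,
    gamma = 5, n_nodes = 80, maxit = 40)
  res <- estimate_timecourse(list(o1, o2), cfg)
  expect_length(res, 2)
  mat <- attr(res, "kc_matrix")
  expect_equal(dim(mat), c(2, 101))
  sg <- seq(0, 1, length.out = 101)
  for (r in res) {
    expect_lt(max(abs(log_kc(r$profile, sg) - log_kc(prof, sg))), 0.2)
  }
})

test_that("the L-curve utility maps the smoothness trade-off and suggests a corner", {
  va <- va_for_v(0.92)
  truth <- stiffness_profile("cosine_basis", c(-0.5, 0.5))
  eq <- solve_equilibrium(va$V, va$A, truth, 5, n_nodes = 90)
  obs <- observation_from_contour(eq$contour)
  cfg <- inverse_config("cosine_basis", n_basis = 2, gamma = 5,
    n_nodes = 80, maxit = 25)
  lc <- omega1_lcurve(obs, cfg, omegas = c(1e-8, 1e-4, 1e-1))
  expect_equal(nrow(lc), 3)
  expect_true(all(diff(lc$smoothness) <= 1e-8)) # smoother as omega1 grows
  expect_true(attr(lc, "suggested_omega1") %in% lc$omega1)
})
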