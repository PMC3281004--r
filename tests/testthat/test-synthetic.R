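test_that("scenario profiles implement the wild-type dip and mutant constancy", {
  sc <- synthetic_scenario("wildtype_like")
  sz <- synthetic_scenario("zen4_like")
  expect_length(sz$bins, 4) # arrest at the 0.6-0.5 bin
  expect_equal(sz$bins[4], "0.6-0.5")

  pz <- make_profile(sz, "0.7-0.6")
  expect_equal(kc_eval(pz, c(0, 0.5, 1)), rep(1, 3))

  pw <- make_profile(sc, "0.1-0.0")
  # final-bin pole/furrow stiffness ratio: two orders of magnitude
  expect_equal(kc_eval(pw, 0) / kc_eval(pw, 1), 100, tolerance = 1e-6)
  # the dip closed form: -depth*(1+cos(pi*(1-s)))/2
  d <- -2 * pw$coefficients[1]
  s <- seq(0, 1, 0.1)
  expect_equal(log_kc(pw, s), -d * (1 + cos(pi * (1 - s))) / 2, tolerance = 1e-10)

  sc0 <- synthetic_scenario("wildtype_like", depth_max = 0)
  p0 <- make_profile(sc0, "0.1-0.0")
  expect_equal(log_kc(p0, s), rep(0, length(s)), tolerance = 1e-12)
})

test_that("noise-free single-cell observation reproduces the clean equilibrium", {
  sc <- synthetic_scenario("wildtype_like", noise_sd = 0, n_cells = 1)
  go <- generate_observation(sc, "0.6-0.5", seed = 4, n_nodes = 100)
  obs <- go$observation
  clean <- go$truth$contour
  expect_equal(obs$r_mean, clean$r, tolerance = 1e-12)
  expect_equal(obs$z_mean, clean$z - clean$z[1], tolerance = 1e-12)
  expect_true(all(obs$r_sd == 0))
  # the furrow lands at the bin centre
  expect_equal(obs$furrow_radius, 0.55, tolerance = 0.03)
  expect_true(go$truth$equilibrium$converged)
})

test_that("noisy observations are seeded, reproducible, and unbiased", {
  sc <- synthetic_scenario("wildtype_like", noise_sd = 0.01, n_cells = 40)
  go1 <- generate_observation(sc, "0.6-0.5", seed = 7, n_nodes = 100)
  go2 <- generate_observation(sc, "0.6-0.5", seed = 7, n_nodes = 100)
  expect_identical(go1$observation$r_mean, go2$observation$r_mean)

  clean <- go1$truth$contour
  dev <- abs(go1$observation$r_mean[-1] - clean$r[-1])
  expect_true(all(dev < 3 * 0.01 / sqrt(40) + 1e-9 | dev < 3 * go1$observation$r_sd[-1] / sqrt(40)))
  expect_gt(mean(go1$observation$r_sd[-1]), 0.005)
  expect_lt(mean(go1$observation$r_sd[-1]), 0.02)
})

test_that("ingressing wild-type shapes develop the meridional-curvature shoulder next to the furrow", {
  sc <- synthetic_scenario("wildtype_like", noise_sd = 0, n_cells = 1)
  for (b in c("0.6-0.5", "0.5-0.4")) {
    go <- suppressWarnings(generate_observation(sc, b, seed = 1, n_nodes = 120))
    cm <- go$observation$Cm_mean
    s <- go$observation$s
    win <- s >= 0.55 & s <= 0.8
    # C_m is locally elevated in the region neighbouring the furrow,
    # relative to mid-cell and to the concave furrow itself
    expect_gt(max(cm[win]), cm[which.min(abs(s - 0.45))])
    expect_gt(max(cm[win]), cm[which.min(abs(s - 0.9))])
  }
})

test_that("rendered images are deterministic with a flat degenerate limit", {
  ct <- hemisphere_contour(R = 1, n = 101)
  r1 <- render_image(ct, 14.5 / 40, noise = 0.3, seed = 9)
  r2 <- render_image(ct, 14.5 / 40, noise = 0.3, seed = 9)
  expect_identical(r1$image, r2$image)
  r3 <- render_image(ct, 14.5 / 40, noise = 0.3, seed = 10)
  expect_false(identical(r1$image, r3$image))

  flat <- render_image(ct, 14.5 / 40, contrast = 0)
  expect_lt(diff(range(flat$image)), 1e-12)
  expect_error(binarize_local_threshold(flat$image), "no membrane")
})

test_that("round trip: rendered sphere re-quantified within 2%", {
  ren <- render_image(hemisphere_contour(R = 1, n = 151),
    scale_um_per_px = 14.5 / 100, membrane_width_px = 3, contrast = 5
  )
  quads <- quantify_cell(ren$image, ren$scale_um_per_px)
  fr <- vapply(quads, `[[`, numeric(1), "furrow_radius")
  expect_true(all(abs(fr - 1) < 0.02))
})
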