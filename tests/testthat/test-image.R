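# Image-quantification pipeline tests; all fixtures rendered in code.

test_that("ridge binarization recovers a rendered membrane annulus", {
  ct <- hemisphere_contour(R = 40 / model_units()$unit_length_um * 14.5 / 14.5, n = 101)
  # sphere of radius 40 px at 1 um/px scale with unit length = 14.5 um:
  ren <- render_image(hemisphere_contour(R = 1, n = 101),
    scale_um_per_px = 14.5 / 40, membrane_width_px = 3, contrast = 5
  )
  mask <- binarize_local_threshold(ren$image, offset_d = 4, ratio_f = 1.5)
  jac <- sum(mask & ren$mask) / sum(mask | ren$mask)
  expect_gt(jac, 0.8)

  expect_error(
    binarize_local_threshold(matrix(1, 32, 32)),
    "no membrane"
  )

  ren_noisy <- render_image(hemisphere_contour(R = 1, n = 101),
    scale_um_per_px = 14.5 / 40, membrane_width_px = 3, contrast = 5,
    noise = 0.5, seed = 1
  )
  mask_n <- binarize_local_threshold(ren_noisy$image, offset_d = 4, ratio_f = 1.5)
  jac_n <- sum(mask_n & ren_noisy$mask) / sum(mask_n | ren_noisy$mask)
  expect_gt(jac_n, 0.7)
})

test_that("boundary following returns the closed inner cycle", {
  m <- annulus_mask(m = 64, rin = 20, rout = 26)
  bp1 <- trace_bp1(m)
  ctr <- c((64 + 1) / 2, (64 + 1) / 2) - 1 # 0-based centre
  d <- sqrt((bp1[, 1] - ctr[1])^2 + (bp1[, 2] - ctr[2])^2)
  expect_true(all(d >= 19 & d <= 21))
  expect_gt(nrow(bp1), 0.9 * 2 * pi * 20)
  expect_lt(nrow(bp1), 1.25 * 2 * pi * 20)
  # closed: consecutive pixels (and wrap) are 8-neighbours
  steps <- rbind(diff(bp1), bp1[1, ] - bp1[nrow(bp1), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))

  # one-pixel pit on the inner boundary stays part of the cycle
  m2 <- annulus_mask(m = 31, rin = 9, rout = 13)
  pit <- c(16, 16 + 9) # just inside the inner radius on the +x axis
  m2[pit[1], pit[2] - 1] <- TRUE
  bp1b <- trace_bp1(m2)
  expect_true(any(bp1b[, 1] == pit[1] - 1 & bp1b[, 2] == pit[2] - 2))
  steps <- rbind(diff(bp1b), bp1b[1, ] - bp1b[nrow(bp1b), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))

  # two disjoint annuli: not a single component
  m3 <- matrix(FALSE, 64, 130)
  m3[, 1:64] <- annulus_mask(64, 12, 16)
  m3[, 65:128] <- annulus_mask(64, 12, 16)
  expect_error(trace_bp1(m3), "single component|multiple")
})

test_that("adaptive subsampling spaces points by line deviation", {
  m <- annulus_mask(m = 128, rin = 50, rout = 56)
  bp2 <- subsample_bp2(trace_bp1(m))
  expect_gte(nrow(bp2), 5)
  # roughly uniform spacing on a circle; no sharp turns (interior angles
  # stay obtuse)
  j <- nrow(bp2)
  for (i in seq_len(j)) {
    a <- bp2[(i - 2) %% j + 1, ]
    b <- bp2[i, ]
    cc <- bp2[i %% j + 1, ]
    v1 <- a - b
    v2 <- cc - b
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    expect_gt(ang, pi / 2)
  }
  # chord lengths: on a digital circle the acceptance rule gives chords
  # near 2*sqrt(2*R*dist) = 28 px for R = 50, dist = 2
  ch <- sqrt(rowSums((bp2 - bp2[c(2:j, 1), ])^2))
  expect_gt(mean(ch), 10)
  expect_lt(mean(ch), 45)
})

test_that("circumcircle-normal curvature is exact on circles, signed, and safe on collinear points", {
  for (R in c(10, 50, 200, 500)) {
    pts <- circle_points(R, n = 60)
    cvn <- curvature_from_normals(pts)
    expect_lt(max(abs(cvn$C_m * R - 1)), 1e-6)
  }
  # physical scale conversion
  cvn <- curvature_from_normals(circle_points(50), scale = 0.2)
  expect_equal(mean(cvn$C_m), 1 / (50 * 0.2), tolerance = 1e-6)

  # parabola apex: y = x^2/2 has curvature 1 at the apex; close the
  # polygon far away so the apex arcs are interior
  x <- seq(-3, 3, by = 0.1)
  poly <- rbind(cbind(x, x^2 / 2), c(0, 40))
  cvn2 <- curvature_from_normals(poly)
  apex_arc <- which.min(abs(cvn2$arc_mid[, 1]) + abs(cvn2$arc_mid[, 2]))
  expect_equal(abs(cvn2$C_m[apex_arc]), 1, tolerance = 0.02)

  # three collinear points inside an otherwise curved cycle: flat arc
  poly3 <- rbind(
    c(0, 0), c(1, 0), c(2, 0), c(3, 0),
    c(3, 3), c(0, 3)
  )
  cvn3 <- curvature_from_normals(poly3)
  expect_equal(cvn3$C_m[2], 0)
})

test_that("quantify_cell recovers a rendered sphere and respects symmetry", {
  ren <- render_image(hemisphere_contour(R = 1, n = 151),
    scale_um_per_px = 14.5 / 100, membrane_width_px = 3, contrast = 5,
    noise = 0.15, seed = 3
  )
  quads <- quantify_cell(ren$image, ren$scale_um_per_px)
  expect_length(quads, 4)
  for (q in quads) {
    expect_equal(q$furrow_radius, 1, tolerance = 0.05)
    mid <- q$s >= 0.1 & q$s <= 0.9
    expect_lt(max(abs(q$C_m[mid] - 1)), 0.05 * 1 + 0.05)
    expect_equal(q$volume, 4 * pi / 3, tolerance = 0.1)
    expect_equal(q$area, 4 * pi, tolerance = 0.1)
    expect_true(all(q$cp_flag_pole == (q$s < 0.2)))
  }
  # mirrored image gives the same quadrant statistics up to ordering
  quads_m <- quantify_cell(ren$image[, rev(seq_len(ncol(ren$image)))],
    ren$scale_um_per_px)
  fr <- sort(vapply(quads, `[[`, numeric(1), "furrow_radius"))
  fr_m <- sort(vapply(quads_m, `[[`, numeric(1), "furrow_radius"))
  expect_equal(fr, fr_m, tolerance = 0.02)
})

test_that("quantify_cell places a rendered dumbbell in the right furrow bin", {
  db <- dumbbell_contour(300, amp = 0.9)
  # rescale to cell-like size, then render at ~0.15 um/px
  lam <- (from_cell_volume_units(1) / enclosed_volume(db))^(1 / 3)
  db <- contour_from_theta(db$theta, db$t1 * lam)
  fr_true <- shape_descriptors(db)$furrow_radius
  ren <- render_image(db, scale_um_per_px = 14.5 / 70,
    membrane_width_px = 3, contrast = 5)
  quads <- quantify_cell(ren$image, ren$scale_um_per_px)
  for (q in quads) expect_equal(q$furrow_radius, fr_true, tolerance = 0.06)
})

test_that("bin_and_average computes correct statistics", {
  mk <- function(rshift) {
    ct <- resample_to_s_grid(hemisphere_contour(n = 101), 40)
    cv <- curvatures_of(ct)
    list(
      s = ct$s, r = ct$r + rshift, z = ct$z, C_m = cv$C_m, C_p = cv$C_p,
      furrow_radius = 0.85, volume = enclosed_volume(ct),
      area = surface_area(ct)
    )
  }
  ident <- replicate(10, mk(0), simplify = FALSE)
  obs <- bin_and_average(ident, m = 30)
  expect_length(obs, 1)
  expect_equal(obs[[1]]$bin_label, "0.9-0.8")
  expect_true(all(obs[[1]]$r_sd == 0))
  expect_equal(obs[[1]]$n_samples, 10)

  two <- list(mk(0), mk(0.1))
  obs2 <- bin_and_average(two, m = 30)[[1]]
  expect_equal(mean(obs2$r_sd), sd(c(0, 0.1)), tolerance = 1e-10)
  ref <- resample_to_s_grid(hemisphere_contour(n = 101), 40)
  expect_equal(obs2$r_mean,
    stats::approx(ref$s, ref$r + 0.05, xout = obs2$s)$y,
    tolerance = 1e-8
  )

  # empty bins yield no observation
  expect_length(bin_and_average(ident, bin_edges = c(0.5, 0.4)), 0)
})
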