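test_that("sphere and cylinder curvatures match closed forms", {
  hemi <- hemisphere_contour(R = 2, n = 201)
  cv <- curvatures_of(hemi)
  expect_equal(cv$C_m, rep(0.5, 201), tolerance = 1e-10)
  expect_equal(cv$C_p, rep(0.5, 201), tolerance = 1e-5)

  # straight cylinder segment (no pole): theta = pi/2, r = R constant
  n <- 50
  cyl <- structure(
    list(
      n = n, t = seq(0, 1, length.out = n), t1 = 1,
      theta = rep(pi / 2, n), r = rep(2, n),
      z = -seq(0, 1, length.out = n), s = seq(0, 1, length.out = n)
    ),
    class = "axisym_contour"
  )
  cvc <- curvatures_of(cyl)
  expect_equal(cvc$C_m, rep(0, n))
  expect_equal(cvc$C_p, rep(0.5, n))
})

test_that("half-ellipse curvatures match the analytic ellipsoid formulas", {
  b <- 1
  cc <- 1.5
  ct <- ellipse_contour(b = b, c = cc, n = 400)
  cv <- curvatures_of(ct)
  # recover phi from r = b sin(phi), z = c (cos(phi) - 1) (pole at origin)
  phi <- atan2(ct$r / b, (ct$z + cc) / cc)
  ref <- ellipsoid_curvatures(phi, b = b, c = cc)
  interior <- 6:395
  expect_lt(max(abs(cv$C_m[interior] / ref$C_m[interior] - 1)), 0.005)
  expect_lt(max(abs(cv$C_p[interior] / ref$C_p[interior] - 1)), 0.005)
})

test_that("area and volume quadrature are exact for the sphere and stable under refinement", {
  hemi <- hemisphere_contour(R = 1, n = 201)
  expect_equal(surface_area(hemi), 4 * pi, tolerance = 1e-4)
  expect_equal(enclosed_volume(hemi), 4 * pi / 3, tolerance = 1e-4)

  # printed unit system: a sphere holding 1.27e4 um^3 has area 2.63e3 um^2
  # and radius 14.5 um
  R_um <- (3 * 1.27e4 / (4 * pi))^(1 / 3)
  expect_equal(R_um, 14.5, tolerance = 2e-3)
  expect_equal(4 * pi * R_um^2, 2.63e3, tolerance = 2e-3)
  expect_equal(1 / R_um, 0.0691, tolerance = 2e-3)
  u <- model_units()
  expect_equal(u$unit_curvature_per_um * u$unit_length_um, 1)
  expect_equal(u$unit_area_um2, 4 * pi * (3 * u$unit_volume_um3 / (4 * pi))^(2 / 3),
    tolerance = 1e-10
  )

  # grid-refinement oracle on a dumbbell
  d100 <- resample_to_s_grid(dumbbell_contour(400), 100)
  d10k <- resample_to_s_grid(dumbbell_contour(400), 10000)
  expect_equal(surface_area(d100), surface_area(d10k), tolerance = 1e-4)
  expect_equal(enclosed_volume(d100), enclosed_volume(d10k), tolerance = 1e-4)
})

test_that("shape descriptors are correct and scale-invariant after normalization", {
  hemi <- hemisphere_contour()
  d <- shape_descriptors(hemi)
  expect_equal(d$furrow_radius, 1, tolerance = 1e-4)
  expect_equal(d$pole_to_furrow, 1, tolerance = 1e-4)

  db <- dumbbell_contour()
  lam <- 1.7
  scaled <- contour_from_theta(db$theta, db$t1 * lam)
  d1 <- shape_descriptors(db)
  d2 <- shape_descriptors(scaled)
  expect_equal(d2$volume, d1$volume * lam^3, tolerance = 1e-10)
  expect_equal(d2$area, d1$area * lam^2, tolerance = 1e-10)
  expect_equal(d2$furrow_radius_norm, d1$furrow_radius_norm, tolerance = 1e-10)
  expect_equal(d2$pole_to_furrow_norm, d1$pole_to_furrow_norm, tolerance = 1e-10)
})

test_that("resampling preserves curvature, endpoints, and integrals", {
  hemi <- hemisphere_contour(R = 1, n = 100)
  r50 <- resample_to_s_grid(hemi, 50)
  cv <- curvatures_of(r50)
  expect_lt(max(abs(cv$C_m - 1)), 1e-3)
  expect_equal(r50$theta[1], 0)
  expect_equal(r50$theta[50], pi / 2)

  db <- dumbbell_contour(400)
  back <- resample_to_s_grid(resample_to_s_grid(db, 400), 400)
  expect_lt(contour_rmsd(db, back), 1e-6)

  d100 <- resample_to_s_grid(db, 100)
  expect_lt(abs(surface_area(d100) / surface_area(db) - 1), 1e-3)
  expect_lt(abs(enclosed_volume(d100) / enclosed_volume(db) - 1), 1e-3)
})

test_that("isoperimetric bound and pole regularity hold on generated contours", {
  shapes <- list(
    hemisphere_contour(), ellipse_contour(), dumbbell_contour(),
    dumbbell_contour(amp = 0.4), ellipse_contour(b = 1, c = 3)
  )
  for (ct in shapes) {
    V <- enclosed_volume(ct)
    A <- surface_area(ct)
    expect_gte(A, sphere_area_for_volume(V) * (1 - 1e-4))
    cv <- curvatures_of(ct)
    gap <- abs(cv$C_p - cv$C_m)
    # umbilic pole: C_p - C_m -> 0 roughly linearly in t
    expect_lt(gap[2], 5 * abs(cv$C_m[1]) * ct$t[2] + 1e-6)
  }
  expect_equal(surface_area(hemisphere_contour(n = 400)),
    sphere_area_for_volume(enclosed_volume(hemisphere_contour(n = 400))),
    tolerance = 1e-6
  )
})

test_that("contour validation catches broken inputs and CSV round-trips", {
  hemi <- hemisphere_contour(n = 60)
  expect_true(validate_contour(hemi))
  bad <- hemi
  bad$r[1] <- 0.5
  expect_error(validate_contour(bad), "pole")
  tmp <- tempfile(fileext = ".csv")
  write_contour_csv(hemi, tmp)
  back <- read_contour_csv(tmp)
  expect_equal(back$r, hemi$r, tolerance = 1e-12)
  expect_equal(back$theta, hemi$theta, tolerance = 1e-12)
  unlink(tmp)
  tmpj <- tempfile(fileext = ".json")
  write_contour_json(hemi, tmpj)
  backj <- read_contour_json(tmpj)
  expect_equal(backj$r, hemi$r, tolerance = 1e-12)
  expect_equal(backj$t1, hemi$t1, tolerance = 1e-12)
  unlink(tmpj)
})
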