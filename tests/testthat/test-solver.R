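# Forward-model tests. Solver sizes are kept moderate (60-160 nodes);
# the dedicated acceptance suite exercises the full 200-node settings.

test_that("bending energy of a sphere is 8*pi, for any radius and grid", {
  for (R in c(0.5, 1, 14.5)) {
    hemi <- hemisphere_contour(R = R, n = 200)
    expect_equal(bending_energy(hemi), 8 * pi, tolerance = 1e-3)
  }
  # scale invariance is exact in the discretization, not just approximate
  db <- dumbbell_contour(300)
  scaled <- contour_from_theta(db$theta, db$t1 * 3.7)
  expect_equal(bending_energy(db), bending_energy(scaled), tolerance = 1e-12)

  # spatially varying profile against a fine-grid quadrature oracle
  prof <- stiffness_profile("cosine_basis", c(-0.8, 0.8))
  E_fine <- bending_energy(resample_to_s_grid(db, 20000), prof)
  E_400 <- bending_energy(resample_to_s_grid(db, 400), prof)
  expect_equal(E_400, E_fine, tolerance = 1e-4)
})

test_that("the sphere is recovered at reduced volume 1", {
  eq <- solve_equilibrium(4 * pi / 3, 4 * pi, n_nodes = 100)
  expect_equal(eq$energy, 8 * pi, tolerance = 1e-3)
  d <- shape_descriptors(eq$contour)
  expect_equal(d$furrow_radius, 1, tolerance = 0.02)
  expect_lt(max(abs(eq$residuals)), 1e-4)
})

test_that("direct minimizer matches the Euler-Lagrange shooting oracle", {
  va <- va_for_v(0.90)
  eq <- solve_equilibrium(va$V, va$A, n_nodes = 200)
  sh <- shooting_equilibrium(va$V, va$A)
  expect_true(sh$converged)
  expect_lt(contour_rmsd(eq$contour, sh$contour), 1e-3)
  expect_equal(eq$energy, sh$energy, tolerance = 1e-4)
})

test_that("constraints are met and energy descends on varied problems", {
  cases <- list(
    list(v = 0.95, gamma = 0), list(v = 0.85, gamma = 0),
    list(v = 0.85, gamma = 5), list(v = 0.78, gamma = 2)
  )
  for (cs in cases) {
    va <- va_for_v(cs$v)
    eq <- solve_equilibrium(va$V, va$A, gamma = cs$gamma, n_nodes = 120)
    expect_true(eq$converged)
    expect_lt(abs(enclosed_volume(eq$contour) / va$V - 1), 1e-4)
    expect_lt(abs(surface_area(eq$contour) / va$A - 1), 1e-4)
    expect_lte(eq$energy, eq$initial_energy + 1e-8)
  }
})

test_that("jointly rescaling Kc and gamma leaves the shape unchanged", {
  va <- va_for_v(0.85)
  prof <- stiffness_profile("cosine_basis", c(-0.5, 0.5))
  eq1 <- solve_equilibrium(va$V, va$A, prof, gamma = 3, n_nodes = 100)
  eq2 <- solve_equilibrium(va$V, va$A, scale_profile(prof, 4),
    gamma = 12,
    n_nodes = 100, init = eq1$contour
  )
  expect_lt(contour_rmsd(eq1$contour, eq2$contour), 1e-4)
  expect_equal(eq2$energy, 4 * eq1$energy, tolerance = 1e-5)
})

test_that("force sweep is consistent and monotone, ending closed at gamma = Inf", {
  va <- va_for_v(0.70) # below 2^(-1/2): full closure feasible
  sw <- force_sweep(va$V, va$A, gamma_list = c(0, 2, 5, Inf), n_nodes = 120)
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$furrow_radius) < 0))
  expect_equal(sw$furrow_radius[4], 0, tolerance = 1e-4)
  eq0 <- solve_equilibrium(va$V, va$A, gamma = 0, n_nodes = 120)
  expect_lt(contour_rmsd(attr(sw, "shapes")[[1]]$contour, eq0$contour), 1e-5)
})

test_that("pinned furrow radius reports the ring force that would hold it", {
  va <- va_for_v(0.9)
  eq5 <- solve_equilibrium(va$V, va$A, gamma = 5, n_nodes = 150)
  fr5 <- eq5$contour$r[150]
  pin <- solve_equilibrium(va$V, va$A, r_eq = fr5, n_nodes = 150)
  expect_true(pin$converged)
  expect_equal(pin$ring_force_equiv, 5, tolerance = 0.05)
  expect_lt(contour_rmsd(pin$contour, eq5$contour), 1e-3)
})

test_that("required force brackets and diverges sensibly", {
  va <- va_for_v(0.9)
  eq0 <- solve_equilibrium(va$V, va$A, gamma = 0, n_nodes = 120)
  fr0 <- eq0$contour$r[120]
  expect_equal(required_force(va$V, va$A, 1, fr0, n_nodes = 120), 0, tolerance = 0.02)
  expect_error(
    required_force(va$V, va$A, 1, fr0 + 0.1, n_nodes = 120),
    "attainable"
  )
  expect_warning(
    g <- required_force(va$V, va$A, 1, 0.001,
      n_nodes = 120, gamma_cap = 100
    ),
    "cap"
  )
  expect_identical(g, Inf)
})

test_that("multi-start finds a single sphere minimum at v = 1 and collapses duplicates", {
  mins <- find_local_minima(4 * pi / 3, 4 * pi,
    stiffness_profile("constant", 0),
    n_starts = 5, seed = 2, n_nodes = 80
  )
  expect_equal(length(mins), 1)
  expect_equal(mins[[1]]$energy, 8 * pi, tolerance = 1e-3)
  expect_gte(mins[[1]]$basin_count, 3)
})

test_that("infeasible targets error clearly", {
  expect_error(solve_equilibrium(4 * pi / 3, 0.9 * 4 * pi), "reduced volume")
  va <- va_for_v(0.9)
  expect_error(solve_equilibrium(va$V, va$A, gamma = Inf), "closure")
})
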