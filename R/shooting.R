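#' Euler-Lagrange shooting solver for constant bending modulus
#'
#' Independent reference solver for the axisymmetric shape equations with
#' spatially constant Kc. The stationarity conditions of
#' H = E + P V + T A + gamma * 2*pi*r(equator) are integrated as a
#' first-order ODE system in arclength t from the pole, with state
#' (theta, r, z, w, lr, Vh, Ah): w = C_m + C_p is the total curvature and
#' lr the multiplier function enforcing dr/dt = cos(theta). The free
#' parameters (pole curvature u0, total arclength t1, pressure P, tension
#' T) are found by Levenberg-Marquardt shooting on the boundary residuals
#' theta(t1) = pi/2, lr(t1) = -2*pi*gamma, V = V_target, A = A_target.
#' The pole start uses series expansions at t0 << t1; Hamiltonian
#' conservation fixes lr(0) = 0.
#'
#' Continuation: the solve walks the reduced volume down from near 1
#' (where the prolate spheroid provides good starting guesses) to the
#' requested value, warm-starting the shooting parameters.
#'
#' This solver exists as a cross-check for the direct minimizer; it only
#' covers constant Kc, where the classic shooting formulation applies.
#'
#' @param V,A targets (length-unit integrals).
#' @param Kc constant bending modulus.
#' @param gamma ring line tension (finite, >= 0).
#' @param n_out nodes of the returned contour.
#' @param v_step continuation step in reduced volume.
#' @return list with `contour` (an `axisym_contour`), `P`, `T`, `u0`,
#'   `energy`, `residuals`, `converged`.
#' @export
shooting_equilibrium <- function(V, A, Kc = 1, gamma = 0, n_out = 400,
                                 v_step = 0.015) {
  stopifnot(is.finite(gamma), gamma >= 0, Kc > 0)
  v_target <- reduced_volume(V, A)
  if (v_target > 1 - 1e-6) stop("shooting oracle needs v < 1 (non-spherical)")
  v_seq <- unique(c(seq(0.995, v_target, by = -abs(v_step)), v_target))

  p <- NULL
  for (v in v_seq) {
    Av <- 4 * pi * (3 * V / (4 * pi * v))^(2 / 3)
    if (is.null(p)) {
      p <- shoot_first_guess(V, Av, Kc, gamma)
    } else {
      fit <- minpack.lm::nls.lm(
        par = p, fn = shoot_residuals, V = V, A = Av, Kc = Kc, gamma = gamma,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)
      )
      p <- fit$par
    }
  }
  fit <- minpack.lm::nls.lm(
    par = p, fn = shoot_residuals, V = V, A = A, Kc = Kc, gamma = gamma,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15)
  )
  p <- fit$par
  res <- shoot_residuals(p, V, A, Kc, gamma)
  sol <- shoot_integrate(p, Kc, dense = TRUE)
  tt <- sol[, "time"]
  th <- sol[, "theta"]
  f <- stats::splinefun(c(0, tt), c(0, th), method = "monoH.FC")
  tg <- seq(0, exp(p[2]), length.out = n_out)
  thg <- f(tg)
  thg[1] <- 0
  thg[n_out] <- pi / 2
  ct <- contour_from_theta(thg, exp(p[2]))
  list(
    contour = ct, P = p[3], T = p[4], u0 = p[1],
    energy = bending_energy(ct, stiffness_profile("constant", log(Kc))),
    residuals = res, converged = max(abs(res)) < 1e-7
  )
}

shoot_first_guess <- function(V, A, Kc, gamma) {
  v <- reduced_volume(V, A)
  alpha <- stats::uniroot(function(al) spheroid_reduced_volume(al) - v,
    c(1 + 1e-9, 60), tol = 1e-12
  )$root
  lam <- (V / (4 / 3 * pi * alpha))^(1 / 3) # equatorial semi-axis
  a <- lam
  cc <- alpha * lam
  u0 <- cc / a^2
  phi <- seq(0, pi / 2, length.out = 2000)
  t1 <- sum(sqrt((a * diff(sin(phi)))^2 + (cc * diff(cos(phi)))^2))
  R <- (3 * V / (4 * pi))^(1 / 3)
  best <- NULL
  for (P0 in c(0, -2, 2, -8, 8, -20)) {
    par0 <- c(u0, log(t1), P0, -P0 * R / 2)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = shoot_residuals, V = V, A = A, Kc = Kc, gamma = gamma,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$deviance < 1e-16) break
  }
  if (is.null(best)) stop("shooting start failed")
  best$par
}

shoot_rhs <- function(t, y, parms) {
  K <- parms$K
  P <- parms$P
  TT <- parms$TT
  th <- y[1]; r <- y[2]; w <- y[4]; lr <- y[5]
  sth <- sin(th)
  list(c(
    w - sth / r,
    cos(th),
    -sth,
    P * r * cos(th) / (2 * K) + lr * sth / (2 * pi * K * r),
    pi * K * w^2 - 2 * pi * K * w * sth / r + 2 * pi * TT + 2 * pi * P * r * sth,
    pi * r^2 * sth,
    2 * pi * r
  ))
}

shoot_integrate <- function(p, Kc, dense = FALSE) {
  u0 <- p[1]
  t1 <- exp(p[2])
  P <- p[3]
  TT <- p[4]
  t0 <- 1e-6 * t1
  y0 <- c(
    theta = u0 * t0,
    r = t0 - u0^2 * t0^3 / 6,
    z = -u0 * t0^2 / 2,
    w = 2 * u0 + (P / (2 * Kc) + TT * u0 / Kc) * t0^2 / 2,
    lr = 2 * pi * TT * t0,
    Vh = pi * u0 * t0^4 / 4,
    Ah = pi * t0^2
  )
  times <- if (dense) seq(t0, t1, length.out = 800) else c(t0, t1)
  deSolve::lsoda(y0, times, shoot_rhs, parms = list(K = Kc, P = P, TT = TT),
    rtol = 1e-11, atol = 1e-12
  )
}

shoot_residuals <- function(p, V, A, Kc, gamma) {
  sol <- tryCatch(shoot_integrate(p, Kc), error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), ]))) {
    return(rep(10, 4))
  }
  yf <- sol[nrow(sol), ]
  c(
    yf[["theta"]] - pi / 2,
    yf[["lr"]] / (2 * pi) + gamma,
    (2 * yf[["Vh"]] - V) / V,
    (2 * yf[["Ah"]] - A) / A
  )
}
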