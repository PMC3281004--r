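#' Helfrich-type bending energy of a contour
#'
#' E = 2 * integral over the half-contour of (Kc(s)/2) (C_m + C_p)^2 dA,
#' dA = 2*pi*r dt, with zero spontaneous curvature; the factor 2 accounts
#' for the mirror half. Discretized with interval-midpoint curvatures,
#' which is regular at the pole and second-order accurate. For a sphere
#' with Kc = 1 the energy is 8*pi independent of radius (the energy is
#' scale invariant).
#'
#' @param contour an `axisym_contour`.
#' @param profile a `stiffness_profile` (default: constant Kc = 1).
#' @return energy in units of the reference bending modulus.
#' @export
bending_energy <- function(contour, profile = stiffness_profile("constant", 0)) {
  n <- contour$n
  h <- contour$t1 / (n - 1)
  th <- contour$theta
  r <- contour$r
  thm <- (th[-n] + th[-1]) / 2
  rm <- (r[-n] + r[-1]) / 2
  # same softplus radius floor as the solver: regular at the pole and at a
  # fully closed furrow, negligible (<1e-6 relative) on ordinary contours
  eps <- 0.01 * h
  rme <- 0.5 * (rm + sqrt(rm^2 + eps^2))
  Cm <- diff(th) / h
  Cp <- sin(thm) / rme
  sm <- (contour$s[-n] + contour$s[-1]) / 2
  K <- kc_eval(profile, sm)
  2 * pi * h * sum(K * (Cm + Cp)^2 * rme)
}

# ---------------------------------------------------------------------------
# Augmented-Lagrangian direct minimization over (theta at interior nodes,
# log t1). Objective value and analytic gradient in one pass.
#
# x = c(theta[2..n-1], log t1); lam = c(lam_V, lam_A[, lam_R]); mu penalty.
# gamma = Inf is handled as the hard constraint r(t1) = 0 (index 3).
al_objective <- function(x, fixed) {
  n <- fixed$n
  if (any(!is.finite(x)) || abs(x[n - 1]) > 20) {
    return(list(value = 1e10, gradient = rep(0, n - 1)))
  }
  th <- c(0, x[seq_len(n - 2)], pi / 2)
  t1 <- exp(x[n - 1])
  h <- t1 / (n - 1)
  cth <- cos(th)
  sth <- sin(th)
  r <- c(0, cumsum((cth[-n] + cth[-1]) / 2 * h))

  thm <- (th[-n] + th[-1]) / 2
  rm <- (r[-n] + r[-1]) / 2
  # softplus floor: a smooth barrier keeping the effective midpoint radius
  # positive (energy diverges if rm crosses 0); scales with h so the
  # discrete energy stays exactly invariant under rescaling t1.
  eps <- 0.01 * h
  sq <- sqrt(rm^2 + eps^2)
  rme <- 0.5 * (rm + sq)
  drme <- 0.5 * (1 + rm / sq)
  Cm <- diff(th) / h
  Cp <- sin(thm) / rme
  w <- Cm + Cp
  K <- fixed$K_mid
  E <- 2 * pi * h * sum(K * w^2 * rme)

  wt <- c(0.5, rep(1, n - 2), 0.5)
  fV <- r^2 * sth
  V <- 2 * pi * h * sum(wt * fV)
  A <- 4 * pi * h * sum(wt * r)
  rN <- r[n]

  gV <- V / fixed$V_target - 1
  gA <- A / fixed$A_target - 1
  g <- c(gV, gA)
  lam <- fixed$lam
  mu <- fixed$mu
  gamma <- fixed$gamma
  Lref <- fixed$Lref
  ring <- if (is.finite(gamma)) gamma * 2 * pi * rN else 0
  if (fixed$has_req) g <- c(g, (rN - fixed$r_target) / Lref)
  # keep the meridian on the physical side of the axis: the ring term is
  # linear in r(t1) and would otherwise pay out for axis crossings
  cneg <- 1e6
  rneg <- pmin(r, 0)
  Pneg <- cneg * sum(rneg^2)
  val <- E + ring + Pneg + sum(-lam * g + (mu / 2) * g^2)

  # gradient -------------------------------------------------------------
  cV <- (-lam[1] + mu * g[1]) / fixed$V_target
  cA <- (-lam[2] + mu * g[2]) / fixed$A_target
  cR <- if (fixed$has_req) (-lam[3] + mu * g[3]) / Lref else 0

  dE_dCm <- 4 * pi * h * K * w * rme        # per interval; * dCm/dth = +-1/h
  dE_dthm <- 4 * pi * h * K * w * cos(thm)  # per interval; half to each node
  dE_drm <- 2 * pi * h * K * (w^2 - 2 * w * Cp) * drme

  gth <- numeric(n)                          # direct dL/dth at nodes
  gth[-n] <- gth[-n] - dE_dCm / h + dE_dthm / 2
  gth[-1] <- gth[-1] + dE_dCm / h + dE_dthm / 2
  gth <- gth + cV * 2 * pi * h * wt * r^2 * cth

  rho <- numeric(n)                          # dL/dr at nodes
  rho[-n] <- rho[-n] + dE_drm / 2
  rho[-1] <- rho[-1] + dE_drm / 2
  rho <- rho + cV * 2 * pi * h * wt * 2 * r * sth + cA * 4 * pi * h * wt +
    2 * cneg * rneg
  rho[n] <- rho[n] + (if (is.finite(gamma)) gamma * 2 * pi else 0) + cR

  # chain rule through r_j = h * cumtrapz(cos th): dr_j/dth_k = -h sin(th_k)
  # * (1 if k < j, 0.5 if k == j). Reverse-accumulate.
  Srev <- rev(cumsum(rev(rho)))              # sum_{j >= k} rho_j
  tail_sum <- c(Srev[-1], 0)                 # sum_{j > k} rho_j
  gth <- gth - h * sth * (0.5 * rho + tail_sum)

  dtau <- cV * 3 * V + cA * 2 * A +
    (if (is.finite(gamma)) gamma * 2 * pi else 0) * rN + cR * rN + 2 * Pneg

  grad <- c(gth[2:(n - 1)], dtau)
  if (!is.finite(val) || any(!is.finite(grad))) {
    return(list(value = 1e10, gradient = rep(0, n - 1)))
  }
  list(value = val, gradient = grad)
}

#' Seed contour matched to target volume and area
#'
#' A prolate spheroid with the requested reduced volume, rescaled to the
#' exact target volume, optionally perturbed with a neck mode
#' theta += neck * sin(pi*s) (neck > 0 narrows the equator, neck < 0
#' widens it) used for multi-start exploration.
#'
#' @param V,A target volume and area (length-unit integrals).
#' @param n number of contour nodes.
#' @param neck amplitude of the sin(pi*s) tangent-angle perturbation.
#' @return an `axisym_contour`.
#' @export
seed_contour <- function(V, A, n = 200, neck = 0) {
  v <- reduced_volume(V, A)
  if (v > 1 + 1e-9) stop("infeasible targets: reduced volume > 1")
  v <- min(v, 1)
  # aspect ratio c/a of the prolate spheroid with reduced volume v
  alpha <- if (v >= 1 - 1e-12) 1 else {
    stats::uniroot(function(al) spheroid_reduced_volume(al) - v,
      c(1, 60), tol = 1e-12
    )$root
  }
  phi <- seq(0, pi / 2, length.out = 4 * n)
  a <- 1
  cc <- alpha
  tarc <- c(0, cumsum(sqrt((a * diff(sin(phi)))^2 + (cc * diff(cos(phi)))^2)))
  th <- atan2(cc * sin(phi), a * cos(phi))
  f <- stats::splinefun(tarc, th, method = "monoH.FC")
  tt <- seq(0, tarc[length(tarc)], length.out = n)
  th_u <- f(tt)
  th_u[1] <- 0
  th_u[n] <- pi / 2
  if (neck != 0) th_u <- th_u + neck * sin(pi * seq(0, 1, length.out = n))
  ct <- contour_from_theta(th_u, tt[n])
  lam <- (V / enclosed_volume(ct))^(1 / 3)
  contour_from_theta(ct$theta, ct$t1 * lam)
}

spheroid_reduced_volume <- function(alpha) {
  # prolate spheroid, equatorial semi-axis 1, polar semi-axis alpha >= 1
  V <- 4 / 3 * pi * alpha
  e <- sqrt(max(0, 1 - 1 / alpha^2))
  A <- if (e < 1e-8) 4 * pi else 2 * pi * (1 + alpha * asin(e) / e)
  reduced_volume(V, A)
}

#' Minimum-bending-energy shape under volume/area constraints
#'
#' Minimizes E + gamma * 2*pi*r(equator) over discretized tangent angles
#' and total arclength, subject to enclosed volume and surface area
#' equality constraints, by an augmented-Lagrangian outer loop around
#' L-BFGS-B with analytic gradients. `gamma = Inf` replaces the ring term
#' with the hard constraint r(equator) = 0 (fully ingressed furrow).
#' Supplying `r_eq` pins the furrow radius at an arbitrary value instead;
#' the constraint's converged dual value is reported as
#' `ring_force_equiv`, the ring line tension that would hold the furrow
#' there (negative when the surface would constrict further on its own).
#'
#' @param V,A target volume and area (length-unit integrals; the unit
#'   sphere has V = 4*pi/3, A = 4*pi). Must satisfy reduced volume <= 1.
#' @param profile a `stiffness_profile`; default constant Kc = 1.
#' @param gamma contractile-ring line tension (>= 0) in reference-modulus
#'   per length units, or `Inf`.
#' @param n_nodes number of contour nodes.
#' @param init optional warm-start `axisym_contour`.
#' @param r_eq optional pinned furrow radius (length units).
#' @param constraint_tol relative constraint tolerance for convergence.
#' @param max_outer maximum augmented-Lagrangian outer iterations.
#' @param mu0 initial penalty parameter.
#' @return object of class `equilibrium_shape`: list with `contour`,
#'   `energy`, `P`, `T` (volume/area multipliers, reported from the
#'   converged dual values), `gamma`, `ring_force_equiv` (when the furrow
#'   is pinned), `converged`, `residuals`, `outer_iterations`.
#' @examples
#' eq <- solve_equilibrium(4 * pi / 3, 4 * pi, n_nodes = 60)
#' eq$energy / (8 * pi) # ~1: the sphere
#' @export
solve_equilibrium <- function(V, A, profile = stiffness_profile("constant", 0),
                              gamma = 0, n_nodes = 200, init = NULL,
                              r_eq = NULL, constraint_tol = 1e-6,
                              max_outer = 25, mu0 = 1e3) {
  stopifnot(V > 0, A > 0, gamma >= 0)
  v <- reduced_volume(V, A)
  if (v > 1 + 1e-3) {
    stop("infeasible: reduced volume v = ", signif(v, 6), " > 1")
  }
  if (v > 1) {
    # within discretization slack of a sphere: clamp to the isoperimetric
    # minimum area
    A <- sphere_area_for_volume(V)
    v <- 1
  }
  if ((!is.finite(gamma) || (!is.null(r_eq) && r_eq == 0)) &&
    v > 1 / sqrt(2) + 1e-9) {
    stop(
      "full furrow closure infeasible: it needs reduced volume <= 2^(-1/2) ",
      "(each mirror lobe must satisfy its own isoperimetric bound); v = ",
      signif(v, 6)
    )
  }
  has_req <- !is.finite(gamma) || !is.null(r_eq)
  r_target <- if (!is.finite(gamma)) 0 else if (!is.null(r_eq)) r_eq else NA
  # cold starts with a strongly varying profile ramp the stiffness
  # pattern in from constant, so the solve does not snap through the
  # softened equator on the way to the furrowed branch
  if (is.null(init) &&
    diff(range(log_kc(profile, seq(0, 1, length.out = 41)))) > 0.3) {
    warm <- NULL
    for (frac in c(0, 0.5)) {
      warm <- solve_equilibrium(V, A, profile_log_scale(profile, frac),
        gamma = if (is.finite(gamma)) gamma else 0, n_nodes = n_nodes,
        init = warm, constraint_tol = constraint_tol,
        max_outer = max_outer, mu0 = mu0
      )$contour
    }
    init <- warm
  }
  # cold starts under strong or full constriction walk in gradually so the
  # shape follows the constricting branch instead of folding across the axis
  if (is.null(init) && has_req) {
    eq0 <- solve_equilibrium(V, A, profile, if (is.finite(gamma)) gamma else 0,
      n_nodes = n_nodes, constraint_tol = constraint_tol,
      max_outer = max_outer, mu0 = mu0
    )
    fr0 <- eq0$contour$r[n_nodes]
    warm <- eq0$contour
    steps <- seq(fr0, r_target, length.out = max(2, ceiling(abs(fr0 - r_target) / 0.08) + 1))
    for (rt in steps[-1]) {
      warm <- solve_equilibrium(V, A, profile, if (is.finite(gamma)) gamma else 0,
        n_nodes = n_nodes, init = warm, r_eq = rt,
        constraint_tol = constraint_tol, max_outer = max_outer, mu0 = mu0
      )$contour
    }
    return(solve_equilibrium(V, A, profile, gamma,
      n_nodes = n_nodes, init = warm, r_eq = r_eq,
      constraint_tol = constraint_tol, max_outer = max_outer, mu0 = mu0
    ))
  }
  if (is.null(init) && is.finite(gamma) && gamma > 10) {
    g <- 5
    warm <- NULL
    while (g < min(gamma, 1e4)) {
      warm <- solve_equilibrium(V, A, profile, g,
        n_nodes = n_nodes, init = warm,
        constraint_tol = constraint_tol, max_outer = max_outer, mu0 = mu0
      )$contour
      g <- g * 2
    }
    return(solve_equilibrium(V, A, profile, gamma,
      n_nodes = n_nodes, init = warm,
      constraint_tol = constraint_tol, max_outer = max_outer, mu0 = mu0
    ))
  }
  n <- n_nodes
  ct0 <- if (is.null(init)) {
    seed_contour(V, A, n)
  } else if (init$n == n) init else resample_to_s_grid(init, n)
  x <- c(ct0$theta[2:(n - 1)], log(ct0$t1))
  sm <- (seq(0, 1, length.out = n)[-n] + seq(0, 1, length.out = n)[-1]) / 2
  fixed <- list(
    n = n, V_target = V, A_target = A,
    gamma = if (is.finite(gamma)) gamma else Inf,
    has_req = has_req, r_target = r_target,
    K_mid = kc_eval(profile, sm), Lref = sqrt(A / (4 * pi)),
    lam = if (has_req) c(0, 0, 0) else c(0, 0), mu = mu0
  )
  E0 <- bending_energy(ct0, profile)
  fixed$lam <- dual_estimate(x, fixed)

  gmax_prev <- Inf
  converged <- FALSE
  outer_done <- 0
  for (outer in seq_len(max_outer)) {
    opt <- stats::optim(x,
      fn = function(p) al_objective(p, fixed)$value,
      gr = function(p) al_objective(p, fixed)$gradient,
      method = "L-BFGS-B",
      control = list(maxit = 600, factr = 1e4)
    )
    x <- opt$par
    res <- constraint_residuals(x, fixed)
    gmax <- max(abs(res$g))
    outer_done <- outer
    if (gmax < constraint_tol) {
      fixed$lam <- fixed$lam - fixed$mu * res$g
      converged <- TRUE
      break
    }
    if (gmax < 0.25 * gmax_prev) {
      fixed$lam <- fixed$lam - fixed$mu * res$g
    } else {
      fixed$lam <- fixed$lam - fixed$mu * res$g
      fixed$mu <- fixed$mu * 10
    }
    gmax_prev <- gmax
  }

  th <- c(0, x[seq_len(n - 2)], pi / 2)
  ct <- contour_from_theta(th, exp(x[n - 1]))
  res <- constraint_residuals(x, fixed)
  if (min(ct$r) < -1e-4 * fixed$Lref) {
    converged <- FALSE # meridian crossed the rotation axis: nonphysical
  }
  E <- bending_energy(ct, profile)
  out <- structure(
    list(
      contour = ct, energy = E,
      P = -fixed$lam[1] / V, T = -fixed$lam[2] / A,
      gamma = gamma,
      ring_force_equiv = if (has_req) {
        (if (is.finite(gamma)) gamma else 0) -
          fixed$lam[3] / (2 * pi * fixed$Lref)
      } else {
        gamma
      },
      converged = converged,
      residuals = res$g, outer_iterations = outer_done,
      initial_energy = E0, profile = profile,
      V_target = V, A_target = A
    ),
    class = "equilibrium_shape"
  )
  if (!converged) {
    warning(
      "equilibrium solve did not reach constraint tolerance (max |g| = ",
      signif(max(abs(res$g)), 3), ")"
    )
  }
  out
}

# Least-squares multiplier estimate at a starting point: solve
# min || grad(E + ring) - sum_c lam_c grad(g_c) || over lam. Keeps the
# first inner solve from trading constraint violation for energy and
# thereby leaving the warm start's basin.
dual_estimate <- function(x, fixed) {
  m <- length(fixed$lam)
  f0 <- fixed
  f0$mu <- 0
  f0$lam <- rep(0, m)
  g0 <- al_objective(x, f0)$gradient
  Amat <- matrix(0, length(g0), m)
  for (j in seq_len(m)) {
    fj <- f0
    fj$lam <- replace(rep(0, m), j, 1)
    Amat[, j] <- g0 - al_objective(x, fj)$gradient
  }
  lam <- tryCatch(
    stats::lsfit(Amat, g0, intercept = FALSE)$coefficients,
    error = function(e) rep(0, m)
  )
  lam[!is.finite(lam)] <- 0
  unname(lam)
}

constraint_residuals <- function(x, fixed) {
  n <- fixed$n
  th <- c(0, x[seq_len(n - 2)], pi / 2)
  ct <- contour_from_theta(th, exp(x[n - 1]))
  g <- c(
    enclosed_volume(ct) / fixed$V_target - 1,
    surface_area(ct) / fixed$A_target - 1
  )
  if (fixed$has_req) g <- c(g, (ct$r[n] - fixed$r_target) / fixed$Lref)
  list(g = g, contour = ct)
}

#' @export
print.equilibrium_shape <- function(x, ...) {
  d <- shape_descriptors(x$contour)
  cat(sprintf(
    paste0(
      "equilibrium_shape: E = %.6f, furrow radius = %.4f, ",
      "pole-to-furrow = %.4f\n  gamma = %s, converged = %s, max |residual| = %.2e\n"
    ),
    x$energy, d$furrow_radius, d$pole_to_furrow,
    format(x$gamma), x$converged, max(abs(x$residuals))
  ))
  invisible(x)
}

#' RMS distance between two half-contours
#'
#' Both contours are resampled to a common uniform s grid with poles at
#' the origin; the RMSD combines r and z deviations.
#'
#' @param c1,c2 `axisym_contour` objects.
#' @param m number of comparison nodes.
#' @export
contour_rmsd <- function(c1, c2, m = 200) {
  a <- resample_to_s_grid(c1, m)
  b <- resample_to_s_grid(c2, m)
  sqrt(mean((a$r - b$r)^2 + (a$z - b$z)^2))
}

#' Sweep the contractile-ring force
#'
#' Solves the equilibrium sequentially over an ascending list of gamma
#' values (optionally ending with `Inf`), warm-starting each solve from
#' the previous solution.
#'
#' @param V,A targets (length-unit integrals).
#' @param profile a `stiffness_profile`.
#' @param gamma_list ascending numeric vector, `Inf` allowed last.
#' @param n_nodes contour nodes.
#' @return data.frame with columns gamma, furrow_radius, pole_to_furrow,
#'   energy, converged; attribute "shapes" holds the solution list.
#' @export
force_sweep <- function(V, A, profile = stiffness_profile("constant", 0),
                        gamma_list = c(0, 2, 5, 10, 20, 50), n_nodes = 200) {
  stopifnot(!is.unsorted(gamma_list))
  shapes <- vector("list", length(gamma_list))
  prev <- NULL
  rows <- lapply(seq_along(gamma_list), function(i) {
    eq <- solve_equilibrium(V, A, profile, gamma_list[i],
      n_nodes = n_nodes, init = prev
    )
    prev <<- eq$contour
    shapes[[i]] <<- eq
    d <- shape_descriptors(eq$contour)
    data.frame(
      gamma = gamma_list[i], furrow_radius = d$furrow_radius,
      pole_to_furrow = d$pole_to_furrow, energy = eq$energy,
      converged = eq$converged
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "shapes") <- shapes
  out
}

#' Ring force required to reach a target furrow radius
#'
#' The line tension in force balance with a spatially constant bending
#' modulus when the furrow is held at the target radius, computed as the
#' dual value of a pinned-furrow equilibrium solve. (Under strong
#' constriction the fixed-force furrow-radius map folds - the neck snaps
#' shut - so inverting it would report the snap threshold instead of the
#' holding force.) The attainable interval is bounded by the force-free
#' equilibrium radius above; targets below the geometric constriction
#' bound, or whose holding force exceeds `gamma_cap`, report `Inf` with
#' a warning.
#'
#' @param V,A targets (length-unit integrals).
#' @param Kc_const constant bending modulus.
#' @param target_furrow_radius target equatorial radius (length units).
#' @param tol tolerance on the achieved furrow radius.
#' @param gamma_cap largest force reported before declaring divergence.
#' @param n_nodes contour nodes.
#' @param clamp_above with TRUE, a target wider than the force-free
#'   equilibrium radius needs no constriction at all and reports 0;
#'   with the default FALSE it is an error naming the attainable
#'   interval.
#' @return gamma (scalar); `Inf` with a warning when the target needs a
#'   force beyond `gamma_cap` or is geometrically out of reach.
#' @export
required_force <- function(V, A, Kc_const = 1, target_furrow_radius,
                           tol = 1e-4, gamma_cap = 2000, n_nodes = 200,
                           clamp_above = FALSE) {
  prof <- stiffness_profile("constant", log(Kc_const))
  eq0 <- solve_equilibrium(V, A, prof, 0, n_nodes = n_nodes)
  fr0 <- eq0$contour$r[n_nodes]
  if (target_furrow_radius > fr0 + tol) {
    if (clamp_above) {
      return(0)
    }
    stop(sprintf(
      "target %.4f outside attainable interval [0, %.4f]",
      target_furrow_radius, fr0
    ))
  }
  if (target_furrow_radius >= fr0 - tol) {
    return(0)
  }
  # pinned-radius continuation from the force-free shape down to the
  # target; retried with finer steps if the path develops an axis
  # crossing or stalls
  acceptable <- function(eq) {
    !is.null(eq) && (eq$converged || max(abs(eq$residuals)) < 1e-4) &&
      min(eq$contour$r) > -1e-4
  }
  eq <- NULL
  for (step in c(0.08, 0.03)) {
    warm <- eq0$contour
    rts <- unique(c(seq(fr0, target_furrow_radius, by = -step),
      target_furrow_radius))
    good <- TRUE
    for (rt in rts[-1]) {
      cand <- tryCatch(
        suppressWarnings(solve_equilibrium(V, A, prof, 0,
          r_eq = rt, n_nodes = n_nodes, init = warm
        )),
        error = function(e) NULL
      )
      if (!acceptable(cand)) {
        good <- FALSE
        break
      }
      warm <- cand$contour
      eq <- cand
    }
    if (good) break
  }
  if (!acceptable(eq) ||
    abs(eq$contour$r[n_nodes] - target_furrow_radius) > 10 * tol ||
    eq$ring_force_equiv > gamma_cap) {
    warning("required force exceeds cap ", gamma_cap, "; reporting Inf")
    return(Inf)
  }
  max(0, eq$ring_force_equiv)
}

#' Multi-start search for distinct bending-energy minima
#'
#' Runs the equilibrium solver from diverse seed contours (varying the
#' neck perturbation amplitude, with seeded jitter), clusters converged
#' solutions (two are distinct when contour RMSD > 0.02 length units) and
#' returns them sorted by energy.
#'
#' @param V,A targets (length-unit integrals).
#' @param profile a `stiffness_profile`.
#' @param n_starts number of starts (>= 3).
#' @param seed RNG seed for the start jitter.
#' @param gamma ring force (default 0).
#' @param n_nodes contour nodes.
#' @param rmsd_tol clustering threshold (length units).
#' @return list of `equilibrium_shape`, energy-ascending; each carries a
#'   `basin_count` field (number of starts that reached it).
#' @export
find_local_minima <- function(V, A, profile, n_starts = 8, seed = 1,
                              gamma = 0, n_nodes = 200, rmsd_tol = 0.02) {
  stopifnot(n_starts >= 3)
  set.seed(seed)
  necks <- seq(-0.8, 2.4, length.out = n_starts) +
    stats::rnorm(n_starts, sd = 0.02)
  sols <- list()
  for (nk in necks) {
    eq <- tryCatch(
      suppressWarnings(solve_equilibrium(V, A, profile, gamma,
        n_nodes = n_nodes,
        init = seed_contour(V, A, n_nodes, neck = nk)
      )),
      error = function(e) NULL
    )
    if (is.null(eq) || !eq$converged || min(eq$contour$r) < -1e-6) next
    placed <- FALSE
    for (i in seq_along(sols)) {
      if (contour_rmsd(sols[[i]]$contour, eq$contour) <= rmsd_tol) {
        sols[[i]]$basin_count <- sols[[i]]$basin_count + 1
        if (eq$energy < sols[[i]]$energy) {
          bc <- sols[[i]]$basin_count
          sols[[i]] <- eq
          sols[[i]]$basin_count <- bc
        }
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      eq$basin_count <- 1
      sols[[length(sols) + 1]] <- eq
    }
  }
  # stability check: a genuine minimum must be recovered from a small
  # perturbation of itself; shallow kinked stationary artifacts drift
  keep <- vapply(sols, function(s0) {
    n <- s0$contour$n
    pert <- contour_from_theta(
      s0$contour$theta + 5e-3 * sin(7 * pi * seq(0, 1, length.out = n)),
      s0$contour$t1
    )
    re <- tryCatch(
      suppressWarnings(solve_equilibrium(V, A, profile, gamma,
        n_nodes = n_nodes, init = pert
      )),
      error = function(e) NULL
    )
    !is.null(re) && re$converged &&
      contour_rmsd(re$contour, s0$contour) <= rmsd_tol
  }, logical(1))
  sols <- sols[keep]
  sols[order(vapply(sols, function(s) s$energy, numeric(1)))]
}
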