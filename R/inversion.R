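#' Configuration for the inverse stiffness estimation
#'
#' @param method "cosine_basis" (fit log Kc in a truncated cosine series)
#'   or "nodal" (fit log Kc values at uniform s nodes with monotone
#'   Hermite interpolation).
#' @param n_basis number of cosine terms K (cosine_basis; coefficients
#'   a0..aK) or node count M (nodal).
#' @param omega1 weight of the smoothness cost (>= 0).
#' @param gamma assumed contractile-ring force during fitting (0, 5, 20,
#'   50 or any other finite value).
#' @param sd_weighting weight the shape mismatch by the observed per-s
#'   variances (floored at their 10th percentile).
#' @param n_nodes forward-solver contour nodes used during fitting.
#' @param maxit optimizer iteration cap (per Levenberg-Marquardt round).
#' @param reltol relative convergence tolerance.
#' @return object of class `inverse_config`.
#' @export
inverse_config <- function(method = c("cosine_basis", "nodal"),
                           n_basis = NULL, omega1 = 1e-6, gamma = 0,
                           sd_weighting = FALSE, n_nodes = 120,
                           maxit = 200, reltol = 1e-8) {
  method <- match.arg(method)
  if (is.null(n_basis)) n_basis <- if (method == "cosine_basis") 6L else 20L
  stopifnot(omega1 >= 0, n_basis >= 1, is.finite(gamma), gamma >= 0)
  structure(
    list(
      method = method, n_basis = as.integer(n_basis), omega1 = omega1,
      gamma = gamma, sd_weighting = sd_weighting, n_nodes = n_nodes,
      maxit = maxit, reltol = reltol
    ),
    class = "inverse_config"
  )
}

#' Shape mismatch between a model contour and an observation
#'
#' Mean over the common s grid of (r_model - r_obs)^2 + (z_model -
#' z_obs)^2, poles aligned at the origin. With `sd_weighting` each squared
#' deviation is divided by the observed variance at that s, floored at
#' the 10th-percentile variance so near-zero SDs cannot dominate.
#'
#' @param model an `axisym_contour`.
#' @param observed a `shape_observation`.
#' @param sd_weighting logical.
#' @return nonnegative scalar cost.
#' @export
shape_mismatch <- function(model, observed, sd_weighting = FALSE) {
  m <- length(observed$s)
  ct <- if (model$n == m) model else resample_to_s_grid(model, m)
  if (max(abs(ct$s - observed$s)) > 1e-8) {
    stop("model and observation must share the uniform s grid")
  }
  dr2 <- (ct$r - observed$r_mean)^2
  dz2 <- ((ct$z - ct$z[1]) - (observed$z_mean - observed$z_mean[1]))^2
  if (sd_weighting) {
    vr <- floor_var(observed$r_sd^2)
    vz <- floor_var(observed$z_sd^2)
    mean(dr2 / vr + dz2 / vz)
  } else {
    mean(dr2 + dz2)
  }
}

floor_var <- function(v) {
  fl <- stats::quantile(v, 0.1, names = FALSE)
  if (fl <= 0) fl <- max(v[v > 0], 1e-12)[1]
  pmax(v, fl)
}

# area-weighted mean of log Kc over the observation's s grid (weights
# proportional to r(s), the area element on a uniform arclength grid)
weighted_mean_log_kc <- function(profile, observed) {
  w <- pmax(observed$r_mean, 0)
  if (sum(w) <= 0) w <- rep(1, length(observed$s))
  sum(w * log_kc(profile, observed$s)) / sum(w)
}

normalize_profile <- function(profile, observed) {
  scale_profile(profile, exp(-weighted_mean_log_kc(profile, observed)))
}

profile_from_par <- function(par, config, observed) {
  if (config$method == "cosine_basis") {
    if (config$gamma == 0) {
      # a0 recomputed from the gauge condition: area-weighted mean log Kc = 0
      pr <- stiffness_profile("cosine_basis", c(0, par))
      stiffness_profile(
        "cosine_basis", c(-weighted_mean_log_kc(pr, observed), par),
        normalization = "area_weighted_mean_log_zero"
      )
    } else {
      stiffness_profile("cosine_basis", par)
    }
  } else {
    pr <- stiffness_profile("nodal", par)
    if (config$gamma == 0) {
      pr <- normalize_profile(pr, observed)
      pr$normalization <- "area_weighted_mean_log_zero"
    }
    pr
  }
}

par_from_profile <- function(profile, config, observed) {
  s_nodes <- seq(0, 1, length.out = config$n_basis)
  if (config$method == "cosine_basis") {
    # project log Kc onto the cosine basis by least squares on a fine grid
    sg <- seq(0, 1, length.out = 201)
    y <- log_kc(profile, sg)
    X <- cbind(1, vapply(
      seq_len(config$n_basis),
      function(k) cos(k * pi * sg), numeric(201)
    ))
    a <- stats::lsfit(X, y, intercept = FALSE)$coefficients
    if (config$gamma == 0) unname(a[-1]) else unname(a)
  } else {
    lk <- log_kc(profile, s_nodes)
    # at gamma = 0 the overall scale is a gauge direction: start in the
    # normalized gauge so rescaled initializations are exactly equivalent
    if (config$gamma == 0) {
      lk <- lk - weighted_mean_log_kc(profile, observed)
    }
    lk
  }
}

#' Estimate the spatial bending-modulus profile from an observed shape
#'
#' Iteratively improves the log-stiffness coefficients so the forward
#' model's equilibrium matches the observed contour: each evaluation
#' solves the forward problem at the observation's volume and area and
#' the configured ring force, warm-started from the best solution so
#' far, and scores shape mismatch plus omega1 times the smoothness
#' cost. The optimizer is Levenberg-Marquardt on the stacked residuals
#' (restarted once with a fresh trust region), with finite-difference
#' Jacobian steps widened above the forward solver's numerical noise.
#' With gamma = 0 the mismatch is invariant under rescaling Kc, so the
#' profile is pinned by the gauge condition that the area-weighted mean
#' of log Kc is zero; with gamma > 0 the force sets the absolute scale
#' and no renormalization is applied.
#'
#' The cost surface can hold spurious local minima (notably a uniform
#' softening that mimics an equatorial dip when gamma > 0), so with no
#' starting profile the estimator multi-starts from a spatially constant
#' profile and two generic equatorial dips and keeps the best fit.
#'
#' @param observed a `shape_observation`.
#' @param config an `inverse_config`.
#' @param init_profile optional starting `stiffness_profile`; when
#'   supplied, a single quasi-Newton run starts there.
#' @return object of class `inverse_result`: `profile`, `mismatch_cost`,
#'   `smoothness_cost`, `total_cost`, `iterations`, `converged`,
#'   `fitted` (the final `equilibrium_shape`), `n_forward_solves`.
#' @export
estimate_kc <- function(observed, config = inverse_config(),
                        init_profile = NULL) {
  if (!is.null(init_profile)) {
    return(estimate_kc_single(observed, config, init_profile))
  }
  inits <- list(
    stiffness_profile("constant", 0),
    stiffness_profile("cosine_basis", c(-0.75, 0.75)),
    stiffness_profile("cosine_basis", c(-1.75, 1.75))
  )
  best <- NULL
  for (ip in inits) {
    res <- tryCatch(estimate_kc_single(observed, config, ip),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$total_cost < best$total_cost) best <- res
  }
  if (is.null(best)) stop("stiffness estimation failed from every start")
  best
}

estimate_kc_single <- function(observed, config, init_profile) {
  stopifnot(inherits(observed, "shape_observation"))
  V <- observed$volume
  A <- observed$area
  par0 <- par_from_profile(init_profile, config, observed)

  state <- new.env(parent = emptyenv())
  state$warm <- NULL
  state$nsolve <- 0L
  state$nfail <- 0L
  # prime the warm start by ramping the initial profile in from constant,
  # so the first forward solve tracks the furrowed branch; keep the last
  # physical shape even if later ramp steps fail
  ramp_to <- function(target_profile, from = NULL) {
    last <- from
    for (frac in c(0, 0.25, 0.5, 0.75, 1)) {
      step <- tryCatch(
        solve_equilibrium(V, A, profile_log_scale(target_profile, frac),
          config$gamma,
          n_nodes = config$n_nodes, init = last,
          constraint_tol = 1e-6
        ),
        error = function(e) NULL
      )
      if (!is.null(step) &&
        (step$converged || max(abs(step$residuals)) < 1e-4) &&
        min(step$contour$r) > -1e-6) {
        last <- step$contour
      }
    }
    last
  }
  # ramp the *normalized* initial profile so the whole run is a function
  # of the starting parameters alone (a rescaled but gauge-equivalent
  # initialization yields a bitwise-identical trajectory)
  state$warm <- ramp_to(profile_from_par(par0, config, observed))

  # every evaluation warm-starts from the best solution found so far and
  # only improvements replace it: line-search probes far from the current
  # iterate then cannot hop the forward problem onto another shape branch
  # and poison later evaluations
  state$best <- Inf
  evalcost <- function(par) {
    pr <- profile_from_par(par, config, observed)
    eq <- tryCatch(
      solve_equilibrium(V, A, pr, config$gamma,
        n_nodes = config$n_nodes, init = state$warm,
        constraint_tol = 1e-6
      ),
      error = function(e) NULL
    )
    state$nsolve <- state$nsolve + 1L
    if (is.null(eq) || !(eq$converged || max(abs(eq$residuals)) < 1e-4)) {
      state$nfail <- state$nfail + 1L
      return(1e6)
    }
    cost <- shape_mismatch(eq$contour, observed, config$sd_weighting) +
      config$omega1 * smoothness_penalty(pr)
    if (cost < state$best) {
      state$best <- cost
      state$warm <- eq$contour
    }
    cost
  }
  # stacked least-squares residuals for the Gauss-Newton polish: shape
  # deviations scaled so their sum of squares equals the mismatch, plus
  # second-difference residuals carrying omega1 * smoothness
  m <- length(observed$s)
  sg101 <- seq(0, 1, length.out = 101)
  vr <- if (config$sd_weighting) floor_var(observed$r_sd^2) else rep(1, m)
  vz <- if (config$sd_weighting) floor_var(observed$z_sd^2) else rep(1, m)
  residfn <- function(par) {
    pr <- profile_from_par(par, config, observed)
    eq <- tryCatch(
      solve_equilibrium(V, A, pr, config$gamma,
        n_nodes = config$n_nodes, init = state$warm,
        constraint_tol = 1e-6
      ),
      error = function(e) NULL
    )
    state$nsolve <- state$nsolve + 1L
    if (is.null(eq) || !(eq$converged || max(abs(eq$residuals)) < 1e-4)) {
      state$nfail <- state$nfail + 1L
      return(rep(10, 2 * m + 99 + (config$gamma == 0)))
    }
    ct <- resample_to_s_grid(eq$contour, m)
    rr <- c(
      (ct$r - observed$r_mean) / sqrt(vr),
      ((ct$z - ct$z[1]) - (observed$z_mean - observed$z_mean[1])) / sqrt(vz)
    ) / sqrt(m)
    f <- log_kc(pr, sg101)
    d2 <- (f[-c(1, 2)] - 2 * f[-c(1, 101)] + f[-c(100, 101)]) / 0.01^2
    out <- c(rr, sqrt(config$omega1 / 99) * d2)
    if (config$gamma == 0) {
      # the overall scale of the parameters is a gauge direction (the
      # profile is re-normalized every evaluation): tether it so the
      # optimizer cannot drift along it
      out <- c(out, 0.01 * mean(par))
    }
    cost <- sum(out^2)
    if (cost < state$best) {
      state$best <- cost
      state$warm <- eq$contour
    }
    out
  }

  # Levenberg-Marquardt on the stacked residuals (restarted once with a
  # fresh trust region): the mismatch valley is shallow and curved near
  # the optimum, where a Gauss-Newton model converges far better than
  # quasi-Newton line searches; the finite-difference step is widened
  # above the forward solver's numerical noise
  evalcost(par0)
  par <- par0
  lmctl <- minpack.lm::nls.lm.control(
    maxiter = config$maxit, ftol = 1e-13, ptol = 1e-11, epsfcn = 1e-6
  )
  niter_lm <- 0L
  best_cost <- sum(residfn(par0)^2) # a diverged round must not beat the start
  for (round in 1:2) {
    lm <- tryCatch(minpack.lm::nls.lm(par, fn = residfn, control = lmctl),
      error = function(e) NULL
    )
    if (is.null(lm)) break
    cost <- sum(residfn(lm$par)^2)
    if (cost <= best_cost) {
      best_cost <- cost
      par <- lm$par
    }
    niter_lm <- niter_lm + lm$niter
  }

  profile <- profile_from_par(par, config, observed)
  fitted <- tryCatch(
    solve_equilibrium(V, A, profile, config$gamma,
      n_nodes = config$n_nodes, init = state$warm, constraint_tol = 1e-6
    ),
    error = function(e) NULL
  )
  mm <- if (is.null(fitted)) {
    Inf
  } else {
    shape_mismatch(fitted$contour, observed, config$sd_weighting)
  }
  if (!is.finite(mm) || mm > 2 * state$best + 1e-9) {
    # the direct refit left the fitted branch: rebuild it by ramping the
    # final profile in from constant
    warm2 <- ramp_to(profile)
    if (!is.null(warm2)) {
      fit2 <- tryCatch(
        solve_equilibrium(V, A, profile, config$gamma,
          n_nodes = config$n_nodes, init = warm2, constraint_tol = 1e-6
        ),
        error = function(e) NULL
      )
      if (!is.null(fit2)) {
        mm2 <- shape_mismatch(fit2$contour, observed, config$sd_weighting)
        if (mm2 < mm || is.null(fitted)) {
          fitted <- fit2
          mm <- mm2
        }
      }
    }
  }
  if (is.null(fitted)) stop("final forward solve failed")
  sm <- smoothness_penalty(profile)
  structure(
    list(
      profile = profile, mismatch_cost = mm, smoothness_cost = sm,
      total_cost = mm + config$omega1 * sm,
      iterations = niter_lm,
      converged = state$nfail == 0 || mm < 1e5,
      fitted = fitted, n_forward_solves = state$nsolve,
      n_failed_solves = state$nfail, config = config
    ),
    class = "inverse_result"
  )
}

#' @export
print.inverse_result <- function(x, ...) {
  rng <- range(kc_eval(x$profile, seq(0, 1, length.out = 101)))
  cat(sprintf(
    paste0(
      "inverse_result (%s, omega1 = %g, gamma = %g): mismatch = %.3e, ",
      "smoothness = %.3e\n  Kc range [%.3g, %.3g], %d forward solves, ",
      "converged = %s\n"
    ),
    x$config$method, x$config$omega1, x$config$gamma,
    x$mismatch_cost, x$smoothness_cost, rng[1], rng[2],
    x$n_forward_solves, x$converged
  ))
  invisible(x)
}

#' Estimate the stiffness time course over furrow-radius bins
#'
#' Sequential estimation over observations ordered by decreasing furrow
#' radius, warm-starting each bin from the previous bin's profile.
#'
#' @param observations list of `shape_observation`, ordered by decreasing
#'   furrow-radius bin.
#' @param config an `inverse_config`.
#' @return list of `inverse_result` (one per bin); attribute "kc_matrix"
#'   holds the bins x s matrix of Kc evaluated on a 101-point s grid.
#' @export
estimate_timecourse <- function(observations, config = inverse_config()) {
  prev <- NULL
  res <- vector("list", length(observations))
  for (i in seq_along(observations)) {
    res[[i]] <- estimate_kc(observations[[i]], config, init_profile = prev)
    prev <- res[[i]]$profile
  }
  names(res) <- vapply(observations, `[[`, character(1), "bin_label")
  sg <- seq(0, 1, length.out = 101)
  mat <- t(vapply(res, function(r) kc_eval(r$profile, sg), numeric(101)))
  rownames(mat) <- names(res)
  attr(res, "kc_matrix") <- mat
  res
}

#' L-curve exploration of the smoothness weight
#'
#' Runs the estimator over a grid of omega1 values and reports the
#' (mismatch, smoothness) trade-off; the suggested value is the corner of
#' the log-log L-curve (maximum distance from the chord).
#'
#' @param observed a `shape_observation`.
#' @param config an `inverse_config`; its omega1 is ignored.
#' @param omegas positive grid of smoothness weights.
#' @return data.frame(omega1, mismatch, smoothness); attribute
#'   "suggested_omega1".
#' @export
omega1_lcurve <- function(observed, config = inverse_config(),
                          omegas = 10^seq(-4, 0, by = 1)) {
  stopifnot(all(omegas > 0))
  prev <- NULL
  rows <- lapply(sort(omegas), function(om) {
    cfg <- config
    cfg$omega1 <- om
    r <- estimate_kc(observed, cfg, init_profile = prev)
    prev <<- r$profile
    data.frame(omega1 = om, mismatch = r$mismatch_cost,
      smoothness = r$smoothness_cost)
  })
  out <- do.call(rbind, rows)
  lx <- log10(pmax(out$mismatch, 1e-300))
  ly <- log10(pmax(out$smoothness, 1e-300))
  n <- nrow(out)
  if (n >= 3) {
    dx <- lx[n] - lx[1]
    dy <- ly[n] - ly[1]
    nrm <- sqrt(dx^2 + dy^2)
    d <- abs(dx * (ly - ly[1]) - dy * (lx - lx[1])) / max(nrm, 1e-12)
    attr(out, "suggested_omega1") <- out$omega1[which.max(d)]
  } else {
    attr(out, "suggested_omega1") <- out$omega1[1]
  }
  out
}
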