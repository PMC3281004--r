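#' Constant-stiffness feasible region in shape space
#'
#' For each (V, A) pair the constant-Kc model spans, between zero ring
#' force and maximal constriction, a segment of shapes in the
#' (furrow radius, pole-to-furrow distance) plane; across a V/A series
#' the two boundary curves (gamma = 0 and gamma = Inf) enclose the
#' region reachable with spatially constant stiffness. Both descriptors
#' are normalized by (cell volume in cell units)^(-1/3). Full closure
#' (gamma = Inf) is only geometrically possible for reduced volume
#' <= 2^(-1/2); above that the maximal-constriction limit is computed at
#' a large finite force.
#'
#' @param VA_series data.frame with columns `V`, `A` (length-unit
#'   integrals) and optionally `bin_label`.
#' @param n_nodes contour nodes per solve.
#' @param gamma_cap finite force standing in for the constriction limit
#'   when full closure is infeasible.
#' @return object of class `feasible_region`: `curve_free` and
#'   `curve_max` data.frames, the enclosing `polygon`, and `classify`, a
#'   function(furrow_radius_norm, pole_to_furrow_norm) -> "inside" /
#'   "outside".
#' @export
feasible_region <- function(VA_series, n_nodes = 150, gamma_cap = 500) {
  stopifnot(all(c("V", "A") %in% names(VA_series)))
  free <- list()
  maxc <- list()
  for (i in seq_len(nrow(VA_series))) {
    V <- VA_series$V[i]
    A <- VA_series$A[i]
    v <- reduced_volume(V, A)
    eq0 <- solve_equilibrium(V, A, gamma = 0, n_nodes = n_nodes)
    gmax <- if (v <= 1 / sqrt(2) - 1e-4) Inf else gamma_cap
    eqm <- if (is.infinite(gmax)) {
      solve_equilibrium(V, A, gamma = Inf, n_nodes = n_nodes)
    } else {
      # closure is geometrically infeasible here: walk the pinned furrow
      # inward until the implied ring force reaches the cap
      max_constriction(V, A, eq0, gamma_cap, n_nodes)
    }
    d0 <- shape_descriptors(eq0$contour)
    dm <- shape_descriptors(eqm$contour)
    lab <- if ("bin_label" %in% names(VA_series)) VA_series$bin_label[i] else as.character(i)
    free[[i]] <- data.frame(
      bin_label = lab, v = v, gamma = 0,
      furrow_radius_norm = d0$furrow_radius_norm,
      pole_to_furrow_norm = d0$pole_to_furrow_norm
    )
    maxc[[i]] <- data.frame(
      bin_label = lab, v = v, gamma = gmax,
      furrow_radius_norm = max(dm$furrow_radius_norm, 0),
      pole_to_furrow_norm = dm$pole_to_furrow_norm
    )
  }
  curve_free <- do.call(rbind, free)
  curve_max <- do.call(rbind, maxc)
  poly <- rbind(
    curve_free[, c("furrow_radius_norm", "pole_to_furrow_norm")],
    curve_max[rev(seq_len(nrow(curve_max))), c("furrow_radius_norm", "pole_to_furrow_norm")]
  )
  # between-curve test: at the query furrow radius, interpolate the
  # pole-to-furrow distance of each boundary curve. Below the force-free
  # curve's radius range (only strongly constricted shapes reach there),
  # the enclosing boundary follows the final constriction path, taken as
  # the segment from the smallest-radius force-free point to the
  # smallest-radius maximal-constriction point.
  interp_curve <- function(curve, x) {
    o <- order(curve$furrow_radius_norm)
    stats::approx(curve$furrow_radius_norm[o], curve$pole_to_furrow_norm[o],
      xout = x, rule = 2
    )$y
  }
  ifree <- which.min(curve_free$furrow_radius_norm)
  imax <- which.min(curve_max$furrow_radius_norm)
  p_free_end <- c(
    curve_free$furrow_radius_norm[ifree],
    curve_free$pole_to_furrow_norm[ifree]
  )
  p_max_end <- c(
    curve_max$furrow_radius_norm[imax],
    curve_max$pole_to_furrow_norm[imax]
  )
  upper_bound <- function(x) {
    out <- interp_curve(curve_free, x)
    wedge <- x < p_free_end[1]
    if (any(wedge)) {
      span <- p_free_end[1] - p_max_end[1]
      frac <- if (span > 1e-9) {
        pmax(0, (x[wedge] - p_max_end[1]) / span)
      } else {
        0
      }
      out[wedge] <- p_max_end[2] + frac * (p_free_end[2] - p_max_end[2])
    }
    out
  }
  classify <- function(furrow_radius_norm, pole_to_furrow_norm, tol = 1e-6) {
    lo <- interp_curve(curve_max, furrow_radius_norm)
    hi <- upper_bound(furrow_radius_norm)
    inside <- pole_to_furrow_norm >= pmin(lo, hi) - tol &
      pole_to_furrow_norm <= pmax(lo, hi) + tol
    ifelse(inside, "inside", "outside")
  }
  structure(
    list(
      curve_free = curve_free, curve_max = curve_max,
      polygon = poly, classify = classify
    ),
    class = "feasible_region"
  )
}

max_constriction <- function(V, A, eq0, gamma_cap, n_nodes) {
  pin <- function(rt, warm) {
    tryCatch(
      suppressWarnings(solve_equilibrium(V, A,
        gamma = 0, r_eq = rt,
        n_nodes = n_nodes, init = warm
      )),
      error = function(e) NULL
    )
  }
  ok <- function(e) {
    !is.null(e) && e$converged && min(e$contour$r) > -1e-6
  }
  eq <- eq0
  fr <- eq0$contour$r[n_nodes]
  fr_fail <- NA
  repeat {
    fr_try <- fr - max(0.015, 0.03 * fr)
    if (fr_try <= 0.01) break
    cand <- pin(fr_try, eq$contour)
    if (!ok(cand)) {
      fr_fail <- fr_try
      break
    }
    eq <- cand
    fr <- fr_try
    if (cand$ring_force_equiv >= gamma_cap) break
  }
  # approach the geometric constriction bound from above
  if (!is.na(fr_fail) && eq$ring_force_equiv < gamma_cap) {
    for (it in 1:4) {
      mid <- (fr + fr_fail) / 2
      cand <- pin(mid, eq$contour)
      if (ok(cand)) {
        eq <- cand
        fr <- mid
        if (cand$ring_force_equiv >= gamma_cap) break
      } else {
        fr_fail <- mid
      }
    }
  }
  eq
}

#' Stiffness-swap in-silico experiment
#'
#' Replaces a cell's estimated stiffness profile with a donor profile
#' (e.g. the wild-type profile introduced into a mutant cell at the
#' matching furrow-radius bin) and reports how the equilibrium furrow
#' radius changes at the target cell's volume/area and ring force.
#' Each furrow radius is computed as the force-balance radius: the
#' pinned-furrow radius at which the profile's implied ring force equals
#' `gamma`, found by walking the pin inward from the force-free
#' equilibrium. (Under strong softening the fixed-force solve snaps
#' through the fold; the force-balance radius is the stable quantity.)
#' `furrow_only` blends the donor in only over the equatorial half
#' (s > 0.5, smooth logistic blend of the log profiles).
#'
#' @param target_obs the target cell's `shape_observation`.
#' @param target_profile the target cell's own estimated
#'   `stiffness_profile` (baseline).
#' @param donor_profile the donor `stiffness_profile`.
#' @param gamma ring force assumed for both solves.
#' @param furrow_only replace only the furrow-side half of the profile.
#' @param n_nodes contour nodes.
#' @return list with `furrow_radius_before`, `furrow_radius_after`,
#'   `percent_change` (signed; negative = deeper furrow), and both
#'   `equilibrium_shape` fits.
#' @export
kc_swap <- function(target_obs, target_profile, donor_profile, gamma = 20,
                    furrow_only = FALSE, n_nodes = 150) {
  V <- target_obs$volume
  A <- target_obs$area
  swapped_profile <- if (furrow_only) {
    blend_profiles(target_profile, donor_profile, s_split = 0.5)
  } else {
    donor_profile
  }
  base <- force_balance_radius(V, A, target_profile, gamma, n_nodes)
  swap <- force_balance_radius(V, A, swapped_profile, gamma, n_nodes)
  fr0 <- base$fr
  fr1 <- swap$fr
  list(
    furrow_radius_before = fr0, furrow_radius_after = fr1,
    percent_change = 100 * (fr1 - fr0) / fr0,
    fit_before = base$eq, fit_after = swap$eq,
    profile_used = swapped_profile
  )
}

# radius at which the profile's implied ring force balances gamma,
# found by pinned-furrow continuation from the force-free equilibrium
force_balance_radius <- function(V, A, profile, gamma, n_nodes) {
  eq0 <- suppressWarnings(
    solve_equilibrium(V, A, profile, 0, n_nodes = n_nodes)
  )
  fr <- eq0$contour$r[n_nodes]
  if (gamma <= 0) {
    return(list(fr = fr, eq = eq0))
  }
  pin <- function(rt, warm) {
    tryCatch(
      suppressWarnings(solve_equilibrium(V, A, profile, 0,
        r_eq = rt, n_nodes = n_nodes, init = warm
      )),
      error = function(e) NULL
    )
  }
  ok <- function(e) {
    !is.null(e) && (e$converged || max(abs(e$residuals)) < 1e-4) &&
      min(e$contour$r) > -1e-4
  }
  eq <- eq0
  lo <- NA # radius whose holding force exceeds gamma
  repeat {
    rt <- fr - max(0.015, 0.04 * fr)
    if (rt <= 0.005) break
    cand <- pin(rt, eq$contour)
    if (!ok(cand)) break
    eq <- cand
    fr <- rt
    if (cand$ring_force_equiv >= gamma) {
      lo <- rt
      break
    }
  }
  if (!is.na(lo)) {
    hi <- fr + max(0.015, 0.04 * fr)
    for (it in 1:8) {
      mid <- (lo + hi) / 2
      cand <- pin(mid, eq$contour)
      if (!ok(cand)) break
      eq <- cand
      if (cand$ring_force_equiv >= gamma) lo <- mid else hi <- mid
    }
  }
  list(fr = eq$contour$r[n_nodes], eq = eq)
}

blend_profiles <- function(polar, equatorial, s_split = 0.5, width = 0.1) {
  sg <- seq(0, 1, length.out = 41)
  wgt <- 1 / (1 + exp(-(sg - s_split) / (width / 4)))
  lk <- (1 - wgt) * log_kc(polar, sg) + wgt * log_kc(equatorial, sg)
  stiffness_profile("nodal", lk)
}

#' Required ring force across a V/A series
#'
#' For each bin, the force needed to constrict the furrow to the given
#' target radius under spatially constant Kc = 1. The required force
#' grows monotonically as the target radius decreases and rises sharply
#' once the target drops below the radius range the surface resists.
#'
#' @param VA_series data.frame with `V`, `A` and optionally `bin_label`.
#' @param targets target furrow radii (length units), one per row.
#' @param n_nodes contour nodes.
#' @param gamma_cap cap above which the force is reported as Inf.
#' @return data.frame(bin_label, target_furrow_radius, gamma).
#' @export
required_force_curve <- function(VA_series, targets, n_nodes = 150,
                                 gamma_cap = 2000) {
  stopifnot(nrow(VA_series) == length(targets))
  rows <- lapply(seq_along(targets), function(i) {
    g <- required_force(VA_series$V[i], VA_series$A[i],
      Kc_const = 1,
      target_furrow_radius = targets[i], n_nodes = n_nodes,
      gamma_cap = gamma_cap, clamp_above = TRUE
    )
    data.frame(
      bin_label = if ("bin_label" %in% names(VA_series)) {
        VA_series$bin_label[i]
      } else {
        as.character(i)
      },
      target_furrow_radius = targets[i], gamma = g
    )
  })
  do.call(rbind, rows)
}

#' Bending-energy landscape: ranked local minima
#'
#' Multi-start search for distinct equilibrium shapes under one
#' stiffness profile and fixed V/A in the absence of the ring force,
#' reported as an energy-sorted table. Deterministic for a fixed seed.
#'
#' @param profile a `stiffness_profile`.
#' @param V,A targets (length-unit integrals).
#' @param n_starts number of seed shapes.
#' @param seed RNG seed.
#' @param n_nodes contour nodes.
#' @return data.frame(rank, energy, furrow_radius, pole_to_furrow,
#'   basin_count); attribute "shapes" holds the `equilibrium_shape`
#'   objects.
#' @export
energy_landscape <- function(profile, V, A, n_starts = 10, seed = 1,
                             n_nodes = 150) {
  mins <- find_local_minima(V, A, profile,
    n_starts = n_starts, seed = seed,
    gamma = 0, n_nodes = n_nodes
  )
  rows <- lapply(seq_along(mins), function(i) {
    d <- shape_descriptors(mins[[i]]$contour)
    data.frame(
      rank = i, energy = mins[[i]]$energy,
      furrow_radius = d$furrow_radius, pole_to_furrow = d$pole_to_furrow,
      basin_count = mins[[i]]$basin_count
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "shapes") <- mins
  out
}
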