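#' Synthetic dividing-cell scenario
#'
#' Defines the ground-truthed study conditions emulated by the generator:
#' a constant cell volume of 1.0 cell unit, a monotonically increasing
#' surface area across furrow-radius bins (reduced volume falling from
#' near 1 to the two-lobe regime), and a per-bin stiffness profile.
#' `wildtype_like` deepens an equatorial soft dip over time, reaching a
#' pole-to-furrow stiffness ratio of 100 (two orders of magnitude) in
#' the final bin; `zen4_like` keeps the profile spatially constant and
#' stops at the 0.6-0.5 bin, where furrow ingression arrests in the
#' mutant; `sphere` is the trivial v = 1 control.
#'
#' @param scenario "wildtype_like", "zen4_like" or "sphere".
#' @param bins character vector of furrow-radius bin labels, descending.
#' @param volume cell volume in cell units (constant over the series).
#' @param v_schedule reduced volume per bin (monotone decreasing).
#' @param depth_max equatorial log-stiffness dip in the final bin
#'   (wildtype_like; default log(100)).
#' @param gamma ring force used when generating shapes (upper bound; the
#'   generator lowers it per bin to land the furrow radius inside the
#'   bin).
#' @param noise_sd contour noise SD in model length units.
#' @param n_cells quadrants per bin.
#' @param seed base RNG seed recorded with every artifact.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(scenario = c("wildtype_like", "zen4_like", "sphere"),
                               bins = NULL, volume = 1.0,
                               v_schedule = NULL, depth_max = log(100),
                               gamma = 20, noise_sd = 0.01, n_cells = 40,
                               seed = 1) {
  scenario <- match.arg(scenario)
  all_bins <- sprintf("%.1f-%.1f", seq(0.9, 0.1, by = -0.1), seq(0.8, 0, by = -0.1))
  # Reduced-volume schedule: area grows ahead of the furrow early (the
  # bin-centre radius sits just below the force-free equilibrium radius)
  # and barely keeps up late (the bin centre approaches the two-sphere
  # geometric bound, the minimum-area shape with that neck radius).
  # Calibrated once so that the ring force a spatially constant-Kc
  # surface would need at the bin centres rises monotonically and
  # steeply (~0.5, 1.5, 4, 15, 30, 55, 90, 150, 450 force units):
  # constriction beyond the arrest point costs more than the ring budget.
  all_v <- c(0.9550, 0.8971, 0.8437, 0.8100, 0.7762, 0.7486, 0.7277, 0.7141, 0.7077)
  if (is.null(bins)) {
    bins <- switch(scenario,
      wildtype_like = all_bins,
      zen4_like = all_bins[1:4], # arrest at 0.6-0.5
      sphere = "pre-ingression"
    )
  }
  if (is.null(v_schedule)) {
    v_schedule <- if (scenario == "sphere") 1.0 else all_v[match(bins, all_bins)]
  }
  stopifnot(
    length(v_schedule) == length(bins), all(v_schedule <= 1),
    !is.unsorted(rev(v_schedule)), depth_max >= 0, noise_sd >= 0, n_cells >= 1
  )
  structure(
    list(
      scenario = scenario, bins = bins, volume = volume,
      v_schedule = v_schedule, depth_max = depth_max, gamma = gamma,
      noise_sd = noise_sd, n_cells = n_cells, seed = seed
    ),
    class = "synthetic_scenario"
  )
}

bin_center <- function(bin_label) {
  if (bin_label == "pre-ingression") {
    return(1)
  }
  mean(as.numeric(strsplit(bin_label, "-")[[1]]))
}

#' Ground-truth stiffness profile for a scenario bin
#'
#' wildtype_like: log Kc(s) = -depth(bin) * (1 + cos(pi*(1 - s))) / 2, an
#' equatorial dip equal to 0 at the pole and -depth at the furrow, with
#' depth increasing linearly over the bin sequence up to `depth_max`
#' (pole-to-furrow stiffness ratio e^depth). zen4_like and sphere:
#' spatially constant Kc = 1.
#'
#' @param scenario a `synthetic_scenario`.
#' @param bin bin label (must be in `scenario$bins`).
#' @return a `stiffness_profile` (cosine form: a0 = -depth/2,
#'   a1 = depth/2).
#' @export
make_profile <- function(scenario, bin) {
  i <- match(bin, scenario$bins)
  if (is.na(i)) stop("unknown bin: ", bin)
  if (scenario$scenario != "wildtype_like") {
    return(stiffness_profile("constant", 0))
  }
  nb <- length(scenario$bins)
  depth <- if (nb == 1) scenario$depth_max else {
    scenario$depth_max * (0.05 + 0.95 * (i - 1) / (nb - 1))
  }
  # -depth*(1+cos(pi*(1-s)))/2 == -depth/2 + (depth/2)*cos(pi*s)
  stiffness_profile("cosine_basis", c(-depth / 2, depth / 2))
}

#' Generate a bin-averaged synthetic observation with ground truth
#'
#' Forward-solves the bin's equilibrium shape (volume from the scenario,
#' area from the reduced-volume schedule, the bin's stiffness profile,
#' with the furrow pinned at the bin centre by the ring; the implied
#' ring force is the constraint's dual value, and when it would exceed
#' `scenario$gamma` the bin arrests at the radius the capped force can
#' hold), perturbs `n_cells` quadrant
#' contours with seeded Gaussian noise in (r, z) (and a curvature noise
#' channel whose C_p component is inflated near the pole, where the
#' parallel radius makes curvature estimates unstable), and aggregates
#' them with [bin_and_average()].
#'
#' @param scenario a `synthetic_scenario`.
#' @param bin bin label.
#' @param seed RNG seed (defaults to the scenario seed).
#' @param n_nodes forward-solver nodes.
#' @return list with `observation` (a `shape_observation`) and `truth`
#'   (profile, clean equilibrium, gamma, volume, area, seed).
#' @export
generate_observation <- function(scenario, bin, seed = scenario$seed,
                                 n_nodes = 160) {
  i <- match(bin, scenario$bins)
  if (is.na(i)) stop("unknown bin: ", bin)
  V <- from_cell_volume_units(scenario$volume)
  v <- scenario$v_schedule[i]
  A <- 4 * pi * (3 * V / (4 * pi * v))^(2 / 3)
  profile <- make_profile(scenario, bin)
  target_fr <- bin_center(bin)
  eq <- solve_bin_shape(V, A, profile, scenario$gamma, target_fr, n_nodes)
  fr_eq <- eq$contour$r[n_nodes]
  clean <- resample_to_s_grid(eq$contour, 50)
  # near full closure the coarse resampling can drift the tip radius
  # slightly negative; pin the physical values
  clean$r[50] <- max(fr_eq, 1e-6)
  clean$r[-1] <- pmax(clean$r[-1], 1e-6)
  cv <- curvatures_of(clean)
  sg <- clean$s
  set.seed(seed)
  quads <- lapply(seq_len(scenario$n_cells), function(k) {
    sdv <- scenario$noise_sd
    r <- clean$r + stats::rnorm(50, sd = sdv)
    z <- clean$z + stats::rnorm(50, sd = sdv)
    r[1] <- 0
    z[1] <- 0
    r[50] <- abs(r[50])
    cm <- cv$C_m + stats::rnorm(50, sd = 5 * sdv)
    cp <- cv$C_p + stats::rnorm(50, sd = 5 * sdv * (1 + 3 * exp(-(sg / 0.1)^2)))
    list(
      s = sg, r = r, z = z, C_m = cm, C_p = cp,
      furrow_radius = fr_eq,
      volume = enclosed_volume(clean), area = surface_area(clean)
    )
  })
  obs <- bin_and_average(quads, bin_edges = c(1, 0), m = 50)[[1]]
  obs$bin_label <- bin
  obs$volume <- enclosed_volume(eq$contour)
  obs$area <- surface_area(eq$contour)
  list(
    observation = obs,
    truth = list(
      profile = profile, equilibrium = eq, contour = clean,
      gamma = eq$ring_force_equiv, volume = V, area = A, v = v,
      seed = seed, bin = bin
    )
  )
}

# Minimum-bending-energy shape with the furrow pinned at target_fr.
# Pinning the equatorial radius as a hard constraint excludes the
# lens-shaped branch (sharp soft rim, wide equator) that coexists with
# the in-vivo-like furrowed branch under soft-equator profiles, and its
# converged dual value is the ring line tension that would hold the
# furrow there. When that implied force exceeds gamma_max the ring
# cannot supply it: the bin is an arrest, and the shape returned is the
# one whose implied force equals gamma_max (found by bisection on the
# pinned radius).
solve_bin_shape <- function(V, A, profile, gamma_max, target_fr, n_nodes) {
  solve_pin <- function(prof, rt, warm) {
    solve_equilibrium(V, A, prof, 0,
      r_eq = rt, n_nodes = n_nodes,
      init = warm
    )
  }
  eq <- solve_pin(stiffness_profile("constant", 0), target_fr, NULL)
  for (frac in c(0.25, 0.5, 0.75, 1)) {
    eq <- solve_pin(profile_log_scale(profile, frac), target_fr, eq$contour)
  }
  if (eq$ring_force_equiv > gamma_max) {
    # arrest: find the radius the capped ring force can hold
    free_fr <- shape_descriptors(
      solve_equilibrium(V, A, profile, 0, n_nodes = n_nodes)$contour
    )$furrow_radius
    lo <- target_fr
    hi <- free_fr
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      cand <- solve_pin(profile, mid, eq$contour)
      if (cand$ring_force_equiv > gamma_max) lo <- mid else hi <- mid
      eq <- cand
      if (abs(cand$ring_force_equiv - gamma_max) < 0.05 * gamma_max) break
    }
  }
  eq
}

#' Render a membrane-labelled image of a cell contour
#'
#' Rasterizes the full mirrored contour as a bright Gaussian-profile
#' ridge (emulating a GFP-tagged membrane marker) on a dark background,
#' with optional seeded Gaussian noise, and returns the ground-truth CCP
#' mask for segmentation scoring.
#'
#' @param contour an `axisym_contour` (half-shape; the full cell is its
#'   mirror image).
#' @param scale_um_per_px micrometres per pixel.
#' @param membrane_width_px full width of the membrane ridge in pixels.
#' @param contrast peak ridge intensity above background.
#' @param noise SD of additive Gaussian noise (intensity units).
#' @param seed RNG seed.
#' @param background background intensity.
#' @param pad_px margin around the cell.
#' @param units model unit system.
#' @return list with `image` (matrix), `mask` (logical ground-truth CCP
#'   mask), `scale_um_per_px`, `seed`.
#' @export
render_image <- function(contour, scale_um_per_px, membrane_width_px = 3,
                         contrast = 5, noise = 0, seed = 1,
                         background = 1, pad_px = 12,
                         units = model_units()) {
  stopifnot(membrane_width_px >= 1, contrast >= 0)
  u2px <- units$unit_length_um / scale_um_per_px
  ct <- resample_to_s_grid(contour, 160)
  zq <- ct$z * u2px
  rq <- ct$r * u2px
  z_eq <- zq[length(zq)]
  # full meridian: pole (z=0) -> equator -> mirrored pole (z = 2*z_eq)
  zf <- c(zq, 2 * z_eq - rev(zq)[-1])
  rf <- c(rq, rev(rq)[-1])
  poly_x <- c(zf, rev(zf)[-1]) # closed polygon in (axis, radial) plane
  poly_y <- c(rf, -rev(rf)[-1])
  xr <- range(poly_x)
  yr <- range(poly_y)
  ox <- xr[1] - pad_px
  oy <- yr[1] - pad_px
  W <- ceiling(diff(xr)) + 2 * pad_px
  H <- ceiling(diff(yr)) + 2 * pad_px
  gx <- seq_len(W) - 1 + ox
  gy <- seq_len(H) - 1 + oy
  px <- matrix(rep(gy, W), H, W) # rows: radial axis, cols: rotation axis
  py <- matrix(rep(gx, each = H), H, W)
  d2 <- matrix(Inf, H, W)
  np <- length(poly_x)
  for (i in seq_len(np - 1)) {
    ax <- poly_x[i]; ay <- poly_y[i]
    bx <- poly_x[i + 1]; by <- poly_y[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    if (L2 < 1e-12) next
    t <- ((py - ax) * vx + (px - ay) * vy) / L2
    t[t < 0] <- 0
    t[t > 1] <- 1
    dd <- (py - (ax + t * vx))^2 + (px - (ay + t * vy))^2
    d2 <- pmin(d2, dd)
  }
  sigma <- membrane_width_px / 2.355 # FWHM -> SD
  ridge <- exp(-d2 / (2 * sigma^2))
  img <- background + contrast * ridge
  if (noise > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(H * W, sd = noise), H, W)
  }
  # ground-truth CCP mask: pixels where the ideal (noise-free) ridge
  # exceeds 15% of its peak amplitude
  list(
    image = img, mask = ridge >= 0.15,
    scale_um_per_px = scale_um_per_px, seed = seed
  )
}
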