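#' Axisymmetric half-contour of a dividing cell
#'
#' Represents the meridian of an axisymmetric, equator-mirror-symmetric
#' surface from the pole (t = 0) to the equatorial mirror plane (t = t1).
#' The tangent angle theta between the rotational z axis and the outward
#' surface normal is the primary field, sampled on a uniform arclength
#' grid; r and z follow from the tangent relations dr/dt = cos(theta),
#' dz/dt = -sin(theta) with r(0) = 0, z(0) = 0 (trapezoidal integration).
#' The normalized arclength s = t/t1 runs 0 at the pole to 1 at the furrow.
#'
#' @param theta numeric vector of tangent angles at the n nodes, with
#'   theta[1] = 0 (pole) and theta[n] = pi/2 (mirror plane).
#' @param t1 total pole-to-equator arclength (> 0).
#' @return object of class `axisym_contour`: list with `n`, `t`, `t1`,
#'   `theta`, `r`, `z`, `s`.
#' @examples
#' hemi <- contour_from_theta(seq(0, pi / 2, length.out = 101), pi / 2)
#' shape_descriptors(hemi)$furrow_radius # ~1
#' @export
contour_from_theta <- function(theta, t1) {
  n <- length(theta)
  stopifnot(n >= 3, is.finite(t1), t1 > 0, all(is.finite(theta)))
  t <- seq(0, t1, length.out = n)
  h <- t1 / (n - 1)
  r <- c(0, cumsum((cos(theta[-n]) + cos(theta[-1])) / 2 * h))
  z <- c(0, cumsum((-sin(theta[-n]) - sin(theta[-1])) / 2 * h))
  structure(
    list(n = n, t = t, t1 = t1, theta = theta, r = r, z = z, s = t / t1),
    class = "axisym_contour"
  )
}

#' @export
print.axisym_contour <- function(x, ...) {
  d <- shape_descriptors(x)
  cat(sprintf(
    "axisym_contour: %d nodes, t1 = %.4f, furrow radius = %.4f, pole-to-furrow = %.4f\n",
    x$n, x$t1, d$furrow_radius, d$pole_to_furrow
  ))
  invisible(x)
}

#' Validate an axisymmetric contour
#'
#' Checks the pole and mirror-plane boundary conditions, monotone s, and
#' consistency of (r, z) with theta through the tangent relations.
#'
#' @param contour an `axisym_contour`.
#' @param tol tolerance for boundary values and tangent-relation residuals.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_contour <- function(contour, tol = 1e-6) {
  stopifnot(inherits(contour, "axisym_contour"))
  with(contour, {
    stopifnot(length(theta) == n, length(r) == n, length(z) == n)
    if (abs(r[1]) > tol || abs(theta[1]) > tol) {
      stop("pole condition violated: need r(0) = 0 and theta(0) = 0")
    }
    if (abs(theta[n] - pi / 2) > max(tol, 1e-4)) {
      stop("mirror-plane condition violated: need theta(t1) = pi/2")
    }
    if (any(diff(s) <= 0)) stop("s must be strictly increasing")
    if (min(r[-1]) < -tol) stop("negative radius: contour self-intersects the axis")
    h <- t1 / (n - 1)
    drr <- diff(r) - (cos(theta[-n]) + cos(theta[-1])) / 2 * h
    dzz <- diff(z) - (-sin(theta[-n]) - sin(theta[-1])) / 2 * h
    if (max(abs(drr), abs(dzz)) > max(100 * tol, 1e-3 * h)) {
      stop("r/z inconsistent with theta via tangent relations")
    }
  })
  invisible(TRUE)
}

#' Principal curvatures of an axisymmetric contour
#'
#' The meridional curvature C_m = d(theta)/dt (centred differences,
#' one-sided at the ends) and the parallel curvature C_p = sin(theta)/r.
#' At the pole the surface is umbilic and C_p takes its limit C_m(0).
#' Both are positive on a convex cell; C_m turns negative in the furrow
#' concavity.
#'
#' @param contour an `axisym_contour`.
#' @return object of class `curvature_field`: list with `C_m`, `C_p`.
#' @export
curvatures_of <- function(contour) {
  n <- contour$n
  th <- contour$theta
  t <- contour$t
  C_m <- numeric(n)
  C_m[1] <- (th[2] - th[1]) / (t[2] - t[1])
  C_m[n] <- (th[n] - th[n - 1]) / (t[n] - t[n - 1])
  C_m[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  C_p <- sin(th) / contour$r
  # umbilic limit applies only when the curve actually starts on the axis
  if (abs(contour$r[1]) < 1e-9 * contour$t1) C_p[1] <- C_m[1]
  if (any(!is.finite(C_p))) {
    stop("non-finite parallel curvature: r = 0 away from the pole")
  }
  structure(list(C_m = C_m, C_p = C_p), class = "curvature_field")
}

#' Surface area of the full mirror-symmetric surface
#'
#' A = 2 * 2*pi * integral of r dt over the half-contour (composite
#' trapezoid); the leading factor 2 accounts for the mirror half.
#'
#' @param contour an `axisym_contour`.
#' @return area in squared length units (unit sphere: 4*pi).
#' @export
surface_area <- function(contour) {
  2 * 2 * pi * trapz_uniform(contour$r, contour$t1)
}

#' Enclosed volume of the full mirror-symmetric surface
#'
#' V = 2 * pi * integral of r^2 sin(theta) dt over the half-contour
#' (composite trapezoid).
#'
#' @param contour an `axisym_contour`.
#' @return volume in cubed length units (unit sphere: 4*pi/3).
#' @export
enclosed_volume <- function(contour) {
  2 * pi * trapz_uniform(contour$r^2 * sin(contour$theta), contour$t1)
}

trapz_uniform <- function(f, t1) {
  n <- length(f)
  (t1 / (n - 1)) * (sum(f) - (f[1] + f[n]) / 2)
}

#' Scalar shape descriptors
#'
#' Furrow radius (r at the equatorial plane) and pole-to-furrow distance
#' (|z(pole) - z(equator)|), plus volume-normalized versions in which each
#' length is multiplied by (cell volume in cell units)^(-1/3), making the
#' descriptors invariant to overall cell size.
#'
#' @param contour an `axisym_contour`.
#' @return list with `furrow_radius`, `pole_to_furrow`, `volume`, `area`
#'   (length-unit integrals) and `furrow_radius_norm`, `pole_to_furrow_norm`.
#' @export
shape_descriptors <- function(contour) {
  V <- enclosed_volume(contour)
  A <- surface_area(contour)
  fr <- contour$r[contour$n]
  pf <- abs(contour$z[1] - contour$z[contour$n])
  f <- cell_volume_units(V)^(-1 / 3)
  list(
    furrow_radius = fr, pole_to_furrow = pf, volume = V, area = A,
    furrow_radius_norm = fr * f, pole_to_furrow_norm = pf * f
  )
}

#' Resample a contour onto a uniform m-point arclength grid
#'
#' theta(t) is interpolated with a shape-preserving (monotone Hermite)
#' spline onto a uniform m-point t grid; r and z are re-integrated from
#' the tangent relations, so pole closure stays exact. Endpoint angles
#' are preserved exactly.
#'
#' @param contour an `axisym_contour`.
#' @param m number of nodes in the output (>= 8).
#' @return an `axisym_contour` with m nodes.
#' @export
resample_to_s_grid <- function(contour, m) {
  stopifnot(m >= 8)
  if (any(diff(contour$s) <= 0)) stop("non-monotone s: corrupt contour")
  f <- stats::splinefun(contour$t, contour$theta, method = "monoH.FC")
  tt <- seq(0, contour$t1, length.out = m)
  th <- f(tt)
  th[1] <- contour$theta[1]
  th[m] <- contour$theta[contour$n]
  contour_from_theta(th, contour$t1)
}

#' Build a contour from sampled (r, z) meridian points
#'
#' Utility for quantified image data: given ordered pole-to-equator (r, z)
#' samples, recovers arclength and tangent angles and re-integrates a
#' consistent `axisym_contour` on a uniform grid. The pole tangent is
#' clamped to 0 and the equatorial tangent to pi/2 to enforce the
#' axisymmetry and mirror boundary conditions.
#'
#' @param r,z ordered meridian coordinates, pole first (r[1] ~ 0).
#' @param m number of nodes for the uniform output grid.
#' @param smooth_df degrees of freedom for a smoothing spline on the
#'   tangent angle (0 = shape-preserving interpolation; use a small
#'   positive value, e.g. 8-12, for noisy digitized meridians).
#' @return an `axisym_contour`.
#' @export
contour_from_rz <- function(r, z, m = 100, smooth_df = 0) {
  n <- length(r)
  stopifnot(n >= 5, length(z) == n)
  dt <- sqrt(diff(r)^2 + diff(z)^2)
  if (any(dt == 0)) {
    keep <- c(TRUE, dt > 0)
    r <- r[keep]; z <- z[keep]
    n <- length(r)
    dt <- sqrt(diff(r)^2 + diff(z)^2)
  }
  t <- c(0, cumsum(dt))
  # tangent angle from centred differences of the polyline
  th <- numeric(n)
  idx <- 2:(n - 1)
  th[idx] <- atan2(-(z[idx + 1] - z[idx - 1]), r[idx + 1] - r[idx - 1])
  th[1] <- 0
  th[n] <- pi / 2
  # orientation: z should decrease pole -> equator; flip if needed
  if (z[n] > z[1]) th[idx] <- atan2(z[idx + 1] - z[idx - 1], r[idx + 1] - r[idx - 1])
  tt <- seq(0, t[n], length.out = m)
  if (smooth_df > 0 && n >= 8) {
    fit <- stats::smooth.spline(t, th, df = min(smooth_df, n - 2))
    thg <- stats::predict(fit, tt)$y
    thg[1] <- 0
    thg[m] <- pi / 2
  } else {
    f <- stats::splinefun(t, th, method = "monoH.FC")
    thg <- f(tt)
  }
  contour_from_theta(thg, t[n])
}

#' Write / read a contour as CSV
#'
#' Columns: s, t, theta, r, z, C_m, C_p (model units), header row, UTF-8.
#'
#' @param contour an `axisym_contour`.
#' @param path file path.
#' @export
write_contour_csv <- function(contour, path) {
  cv <- curvatures_of(contour)
  df <- data.frame(
    s = contour$s, t = contour$t, theta = contour$theta,
    r = contour$r, z = contour$z, C_m = cv$C_m, C_p = cv$C_p
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_contour_csv
#' @param units unit system recorded in the JSON mirror.
#' @export
write_contour_json <- function(contour, path, units = model_units()) {
  cv <- curvatures_of(contour)
  jsonlite::write_json(
    list(
      units = units,
      s = contour$s, t = contour$t, theta = contour$theta,
      r = contour$r, z = contour$z, C_m = cv$C_m, C_p = cv$C_p
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      n = length(x$t), t = x$t, t1 = x$t[length(x$t)], theta = x$theta,
      r = x$r, z = x$z, s = x$s
    ),
    class = "axisym_contour"
  )
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  stopifnot(all(c("s", "t", "theta", "r", "z") %in% names(df)))
  structure(
    list(
      n = nrow(df), t = df$t, t1 = df$t[nrow(df)], theta = df$theta,
      r = df$r, z = df$z, s = df$s
    ),
    class = "axisym_contour"
  )
}
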