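# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

hemisphere_contour <- function(R = 1, n = 201) {
  contour_from_theta(seq(0, pi / 2, length.out = n), R * pi / 2)
}

# prolate half-ellipse meridian: equatorial semi-axis b, polar semi-axis c
ellipse_contour <- function(b = 1, c = 1.5, n = 400) {
  phi <- seq(0, pi / 2, length.out = 8 * n)
  tarc <- c(0, cumsum(sqrt((b * diff(sin(phi)))^2 + (c * diff(cos(phi)))^2)))
  th <- atan2(c * sin(phi), b * cos(phi))
  f <- stats::splinefun(tarc, th, method = "monoH.FC")
  tt <- seq(0, tarc[length(tarc)], length.out = n)
  thu <- f(tt)
  thu[1] <- 0
  thu[n] <- pi / 2
  contour_from_theta(thu, tt[n])
}

# analytic principal curvatures of the ellipsoid of revolution at
# parameter phi (r = b sin(phi), z = c cos(phi))
ellipsoid_curvatures <- function(phi, b = 1, c = 1.5) {
  h <- sqrt(b^2 * cos(phi)^2 + c^2 * sin(phi)^2)
  list(C_m = b * c / h^3, C_p = c / (b * h))
}

# necked "dumbbell" test contour (bulge + neck via a sine tangent mode)
dumbbell_contour <- function(n = 400, amp = 0.8) {
  s <- seq(0, 1, length.out = n)
  contour_from_theta(pi / 2 * s + amp * sin(pi * s), 2.2)
}

# area/volume targets for a reduced volume v at unit cell volume
va_for_v <- function(v, Vc = 1) {
  V <- from_cell_volume_units(Vc)
  list(V = V, A = 4 * pi * (3 * V / (4 * pi * v))^(2 / 3))
}

# exact circle boundary points (possibly non-integer coordinates)
circle_points <- function(R, n = 72, center = c(0, 0)) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + R * cos(ang), center[2] + R * sin(ang))
}

# filled annulus mask (inner radius rin, outer rout) in an m x m image
annulus_mask <- function(m = 64, rin = 20, rout = 26, center = NULL) {
  if (is.null(center)) center <- c((m + 1) / 2, (m + 1) / 2)
  d <- sqrt(outer((seq_len(m) - center[1])^2, (seq_len(m) - center[2])^2, "+"))
  d >= rin & d <= rout
}
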