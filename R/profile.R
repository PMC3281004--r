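#' Spatial bending-modulus profile Kc(s)
#'
#' Positive stiffness profile over normalized arclength s in [0, 1],
#' parameterized on the log scale so positivity is structural:
#' \itemize{
#'   \item `constant`: log Kc = a0.
#'   \item `cosine_basis`: log Kc(s) = a0 + sum_k a_k cos(k*pi*s)
#'     (the cosine-curve estimation basis, "Method 2").
#'   \item `nodal`: log Kc given at M uniform s nodes and interpolated
#'     with a shape-preserving monotone Hermite spline ("Method 3").
#' }
#'
#' @param form one of "constant", "cosine_basis", "nodal".
#' @param coefficients for `constant` a single a0; for `cosine_basis` the
#'   vector (a0, a1, ..., aK); for `nodal` the M log-stiffness values on
#'   the uniform s grid.
#' @param normalization optional tag recording how the profile scale was
#'   pinned (e.g. "area_weighted_mean_log_zero").
#' @return object of class `stiffness_profile`.
#' @export
stiffness_profile <- function(form = c("constant", "cosine_basis", "nodal"),
                              coefficients = 0, normalization = NULL) {
  form <- match.arg(form)
  coefficients <- as.numeric(coefficients)
  stopifnot(all(is.finite(coefficients)), length(coefficients) >= 1)
  if (form == "constant" && length(coefficients) != 1) {
    stop("constant profile takes a single coefficient a0 = log Kc")
  }
  if (form == "nodal" && length(coefficients) < 2) {
    stop("nodal profile needs at least 2 node values")
  }
  structure(
    list(form = form, coefficients = coefficients, normalization = normalization),
    class = "stiffness_profile"
  )
}

#' Evaluate log Kc(s)
#' @param profile a `stiffness_profile`.
#' @param s numeric vector in [0, 1].
#' @return numeric vector of log stiffness values.
#' @export
log_kc <- function(profile, s) {
  stopifnot(inherits(profile, "stiffness_profile"))
  a <- profile$coefficients
  switch(profile$form,
    constant = rep(a[1], length(s)),
    cosine_basis = {
      out <- rep(a[1], length(s))
      for (k in seq_len(length(a) - 1)) out <- out + a[k + 1] * cos(k * pi * s)
      out
    },
    nodal = {
      grid <- seq(0, 1, length.out = length(a))
      stats::splinefun(grid, a, method = "monoH.FC")(pmin(pmax(s, 0), 1))
    }
  )
}

#' @rdname log_kc
#' @export
kc_eval <- function(profile, s) exp(log_kc(profile, s))

#' Rescale a profile by a positive factor
#' @param profile a `stiffness_profile`.
#' @param c positive scale factor applied to Kc.
#' @export
scale_profile <- function(profile, c) {
  stopifnot(c > 0)
  a <- profile$coefficients
  if (profile$form == "nodal") a <- a + log(c) else a[1] <- a[1] + log(c)
  stiffness_profile(profile$form, a, profile$normalization)
}

#' @export
print.stiffness_profile <- function(x, ...) {
  rng <- range(kc_eval(x, seq(0, 1, length.out = 101)))
  cat(sprintf(
    "stiffness_profile (%s, %d coefficients): Kc range [%.4g, %.4g]\n",
    x$form, length(x$coefficients), rng[1], rng[2]
  ))
  invisible(x)
}

#' Fractional stiffness profile
#'
#' Scales log Kc by `frac` (i.e. Kc^frac), which is linear in the
#' coefficients for every supported form. Used to ramp a profile in
#' gradually during warm-started continuation solves.
#'
#' @param profile a `stiffness_profile`.
#' @param frac scaling of the log profile (0 = constant Kc = 1).
#' @export
profile_log_scale <- function(profile, frac) {
  stiffness_profile(profile$form, profile$coefficients * frac,
    profile$normalization)
}

#' Smoothness cost of a stiffness profile
#'
#' Mean squared second derivative of log Kc, estimated by central second
#' differences on a uniform 101-point s grid. Vanishes for constant and
#' log-linear profiles; this is the quantity weighted by omega_1 in the
#' inverse cost function.
#'
#' @param profile a `stiffness_profile`.
#' @return nonnegative scalar.
#' @export
smoothness_penalty <- function(profile) {
  s <- seq(0, 1, length.out = 101)
  f <- log_kc(profile, s)
  ds <- s[2] - s[1]
  d2 <- (f[-c(1, 2)] - 2 * f[-c(1, 101)] + f[-c(100, 101)]) / ds^2
  mean(d2^2)
}

#' Write / read a stiffness profile as JSON
#'
#' Schema: {"form": ..., "coefficients": [...], "normalization": ...}.
#'
#' @param profile a `stiffness_profile`.
#' @param path file path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(
      form = profile$form,
      coefficients = profile$coefficients,
      normalization = profile$normalization
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stiffness_profile(x$form, x$coefficients, x$normalization)
}
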