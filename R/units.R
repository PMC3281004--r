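#' Model unit system
#'
#' The model works in dimensionless length units in which 1 unit length
#' equals the equatorial cell radius before furrow ingression (14.5 um for
#' the C. elegans AB cell). Derived units follow from the sphere of radius
#' one unit: one "cell volume unit" is its volume and one "cell area unit"
#' its surface area, so a non-divided spherical cell has volume 1.0 and
#' area 1.0 in cell units. Curvature units are reciprocal length units.
#'
#' @param unit_length_um physical length of one model unit, in micrometres.
#' @return list with `unit_length_um`, `unit_volume_um3`, `unit_area_um2`,
#'   `unit_curvature_per_um`.
#' @examples
#' u <- model_units()
#' u$unit_curvature_per_um # ~0.069 per um
#' @export
model_units <- function(unit_length_um = 14.5) {
  stopifnot(unit_length_um > 0)
  list(
    unit_length_um = unit_length_um,
    unit_volume_um3 = 4 / 3 * pi * unit_length_um^3,
    unit_area_um2 = 4 * pi * unit_length_um^2,
    unit_curvature_per_um = 1 / unit_length_um
  )
}

#' Convert between raw geometric integrals and cell units
#'
#' Volumes and areas returned by [enclosed_volume()] and [surface_area()]
#' are plain solids-of-revolution integrals in model length units (a unit
#' sphere gives 4*pi/3 and 4*pi). Cell units rescale these so that the
#' unit sphere has volume and area exactly 1, matching the axes used for
#' in vivo time courses.
#'
#' @param V,A volume / area in length-unit integrals.
#' @return numeric scalar in cell units.
#' @export
cell_volume_units <- function(V) V / (4 * pi / 3)

#' @rdname cell_volume_units
#' @export
cell_area_units <- function(A) A / (4 * pi)

#' @rdname cell_volume_units
#' @param Vc,Ac volume / area in cell units.
#' @export
from_cell_volume_units <- function(Vc) Vc * (4 * pi / 3)

#' @rdname cell_volume_units
#' @export
from_cell_area_units <- function(Ac) Ac * 4 * pi

#' Reduced volume
#'
#' v = V / volume of the sphere having the same area; v = 1 only for the
#' sphere, v < 1 admits furrowed shapes. In cell units this reduces to
#' v = Vc / Ac^(3/2).
#'
#' @param V volume (length-unit integral).
#' @param A area (length-unit integral).
#' @return reduced volume in (0, 1].
#' @export
reduced_volume <- function(V, A) {
  stopifnot(V > 0, A > 0)
  V / ((4 * pi / 3) * (A / (4 * pi))^1.5)
}

#' Area of the sphere with a given volume (isoperimetric minimum)
#' @param V volume (length-unit integral).
#' @export
sphere_area_for_volume <- function(V) {
  4 * pi * (3 * V / (4 * pi))^(2 / 3)
}
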