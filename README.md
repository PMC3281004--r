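# furrowbend

Forward and inverse mechanics of cytokinetic cell shape.

During cytokinesis the contractile ring constricts the equator of the
cell, but the mechanics of the surrounding cell surface decide whether
the furrow can ingress at all. `furrowbend` implements a quantitative
test of the *equatorial softening* idea on axisymmetric dividing cells
(the C. elegans AB blastomere is the motivating system): it computes
minimum-bending-energy cell shapes, estimates the spatial profile of
cortical bending stiffness from observed contours, quantifies contours
and curvatures from membrane-labeled micrographs, and generates
ground-truthed synthetic data for validation.

## The model

The cell surface carries a Helfrich-type bending energy

    E = ∮ (Kc(s)/2) (C_m + C_p)² dA ,

with principal curvatures C_m (meridional) and C_p (parallel), zero
spontaneous curvature, and a bending modulus Kc(s) that may vary along
the normalized meridian s (0 at the pole, 1 at the furrow). Equilibrium
shapes minimize

    H = E + γ · 2π r_eq     subject to  V = V₀, A = A₀ ,

where γ is the contractile-ring line tension on the equatorial
circumference; the volume/area multipliers P and T are reported from
the converged duals. The inverse estimator searches for the Kc(s) —
parameterized as a truncated cosine series ("Method 2") or by nodal
values ("Method 3"), both on the log scale — whose equilibrium shape
matches an observed contour, with a smoothness penalty weighted by ω₁.

Lengths are measured in units of the pre-ingression equatorial radius
(14.5 µm); volumes and areas in units of the unit-radius sphere
(1.27x10⁴ µm³ and 2.63x10³ µm²); curvature in 1/14.5 µm⁻¹ = 0.069 µm⁻¹.

## Worked example

Solve the equilibrium shape of a mid-cytokinesis cell (reduced volume
0.83, ring force 5) whose equator is 10x softer than its poles, and
inspect it:

```r
library(furrowbend)

V <- from_cell_volume_units(1.0)                 # constant cell volume
A <- 4 * pi * (3 * V / (4 * pi * 0.83))^(2 / 3)  # area at reduced volume 0.83
dip <- stiffness_profile("cosine_basis", c(-log(10) / 2, log(10) / 2))

eq <- solve_equilibrium(V, A, dip, gamma = 5)
eq
#> equilibrium_shape: E = 13.524283, furrow radius = 0.5720, pole-to-furrow = 1.3486
#>   gamma = 5, converged = TRUE, max |residual| = 2.99e-07
```

The energy is in units of the reference modulus (a sphere costs
8π ≈ 25.13; softening the equator makes the furrowed shape far
cheaper), and the furrow has ingressed to 0.57 of the original radius.
Recovering the stiffness profile back from that shape alone:

```r
obs <- observation_from_contour(eq$contour)
fit <- estimate_kc(obs, inverse_config("cosine_basis",
  n_basis = 3, omega1 = 1e-8, gamma = 5, n_nodes = 100))
round(log_kc(fit$profile, c(0, 0.5, 1)), 2)   # truth: 0, -1.15, -2.30
#> [1]  0.00 -1.15 -2.30
```

The estimator returns the equatorial dip it was given, to two decimals
in log stiffness.

## What is in the package

* `shape_geometry`: axisymmetric half-contours, curvatures, areas,
  volumes, descriptors, resampling, CSV/JSON I/O.
* `bending_solver`: constrained shape solver (finite γ, γ = ∞ closure,
  pinned furrow radius with implied-force dual), force sweeps, required
  force, multi-start minima; plus an independent Euler–Lagrange
  shooting cross-check for constant Kc.
* `stiffness_inversion`: Method 2 / Method 3 estimators, SD weighting,
  the ω₁ smoothness trade-off and an L-curve utility, bin-by-bin time
  courses.
* `image_quantification`: ridge binarization, Moore boundary tracing
  (BP1), curvature-adaptive subsampling (BP2), circumcircle-normal
  curvature, full-cell quadrant quantification.
* `experiments`: constant-Kc feasible region in shape space, stiffness
  swap between cell types, required-force curves, bending-energy
  landscapes.
* `synthetic_data`: wild-type-like and mutant-like scenario generator
  with ground truth, and a membrane-image renderer.
* `inst/scripts/furrowbend`: command-line interface (solve, sweep,
  estimate, quantify, simulate, minima).

The methods vignette (`vignettes/furrowbend-methods.Rmd`) documents the
model assumptions, the numerical design, parameter defaults, and known
limitations.

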