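---
title: "Bending mechanics of the cleavage furrow: model, estimator, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bending mechanics of the cleavage furrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(furrowbend)
```

## The mechanical model

`furrowbend` treats the surface of a dividing cell as a thin elastic
shell whose dominant energy is Helfrich-type bending:

$$E \;=\; \oint \frac{K_c(s)}{2}\,\bigl(C_m + C_p\bigr)^2\, dA ,$$

with $C_m$ and $C_p$ the meridional and parallel principal curvatures,
zero spontaneous curvature (the red-blood-cell / liposome lineage of the
model), and a bending modulus $K_c(s)$ that may vary along the
normalized meridian coordinate $s$ ($s=0$ at a pole, $s=1$ at the
furrow). The cell is assumed axisymmetric and mirror-symmetric about
the equator, so only the pole-to-equator half-meridian is represented;
full-cell volume, area and energy are twice the half-integrals.

Equilibrium shapes minimize

$$H \;=\; E \;+\; \gamma\, 2\pi r_{\mathrm{eq}}
\quad\text{subject to}\quad V = V_0,\; A = A_0 ,$$

where $\gamma$ is the line tension of the contractile ring acting on
the equatorial circumference, and the volume and area are fixed at
their observed values. The Lagrange multipliers of the two constraints
are reported as the pressure-like and tension-like duals $P$ and $T$.
Because $E$ is scale-invariant at zero spontaneous curvature, jointly
rescaling $K_c$ and $\gamma$ by a constant leaves the equilibrium shape
unchanged; with $\gamma = 0$ the scale of $K_c$ is a pure gauge.

### Units

One model length unit is the pre-ingression equatorial radius
(14.5 µm for the *C. elegans* AB cell). The package's "cell units"
rescale volume and area so the unit-radius sphere has $V = A = 1$,
matching the axes on which in vivo time courses are drawn; the raw
solids-of-revolution integrals (sphere: $4\pi/3$, $4\pi$) are used
internally. Reduced volume $v = V_c/A_c^{3/2}$ equals 1 only for a
sphere; $v \le 2^{-1/2}$ is required for a fully closed furrow, because
each mirror half must satisfy its own isoperimetric bound.

## Forward solver

The half-meridian is discretized by its tangent angle $\theta(t)$ on a
uniform arclength grid ($N = 200$ nodes by default); $r$ and $z$ follow
by trapezoidal integration of $dr/dt=\cos\theta$, $dz/dt=-\sin\theta$,
which makes pole closure exact and smoothness automatic. The unknowns
are the interior angles and $\log t_1$. Curvatures are evaluated at
interval midpoints, which is regular at the pole; a softplus floor on
the midpoint radius (0.01 of a grid step) acts as a smooth barrier
against axis crossings and preserves the exact scale invariance of the
discrete energy. Negative node radii are additionally penalized,
because the ring term $\gamma\,2\pi r_{\mathrm{eq}}$ is linear and
would otherwise pay for crossing the axis.

Constrained minimization uses an augmented-Lagrangian outer loop around
L-BFGS-B with fully analytic gradients (reverse accumulation through
the cumulative trapezoid sums; the $\log t_1$ derivative exploits the
exact scale invariance of the discrete energy). Multipliers are
initialized by a least-squares dual estimate at the starting contour:
without it, the first inner solve trades constraint violation for
energy and can leave the warm start's shape branch (e.g. slide from the
prolate to the oblate branch). Default constraint tolerance is
$10^{-6}$ relative.

Three constriction modes are supported: a finite ring force $\gamma$; a
fully closed furrow ($\gamma = \infty$, implemented as the hard
constraint $r_{\mathrm{eq}} = 0$); and a pinned furrow radius
$r_{\mathrm{eq}} = r^\ast$, whose converged dual value is reported as
`ring_force_equiv` — the line tension that would hold the furrow there.
Cold starts under strong constriction walk in gradually (doubling
$\gamma$, or stepping the pinned radius from the force-free value), so
the solve tracks the furrowed branch.

An independent Euler-Lagrange shooting solver (`shooting_equilibrium`)
integrates the classic axisymmetric shape equations for spatially
constant $K_c$ with `deSolve` and solves the boundary conditions by
Levenberg-Marquardt with reduced-volume continuation. It exists as a
cross-check: direct minimization and shooting agree to contour RMSD
$\sim 10^{-5}$ length units at $v = 0.80$–$0.95$. Direct minimization
is the production path because spatially varying $K_c(s)$ breaks the
standard shooting formulation.

### Branch structure, folds, and the pinned-furrow formulation

Under a deep equatorial soft dip the energy landscape holds several
axisymmetric equilibria: the in-vivo-like furrowed shape, a lens-like
shape that concentrates all bending in a sharp soft rim (larger
equatorial radius, lower energy), and near-spherical shapes. The
furrow-radius-versus-force map folds: past a critical $\gamma$ the soft
neck snaps shut, so intermediate radii are unreachable at fixed force.
Mid-to-late shapes are therefore *ring-stabilized* — consistent with
the energy-landscape picture in which shapes with larger furrow radius
have lower bending energy and the ring acts as a ratchet. The
synthetic-data generator consequently pins the furrow radius as a hard
constraint and reports the implied ring force from the dual value,
while the inverse estimator keeps the fixed-$\gamma$ forward model the
paper-style estimation assumes.

## Inverse estimation of the stiffness profile

$K_c(s)$ is parameterized on the log scale (positivity is structural)
either as a truncated cosine series, $\log K_c = a_0 + \sum_k a_k
\cos(k\pi s)$ with $K = 6$ terms by default ("Method 2"), or by $M=20$
nodal values with monotone Hermite interpolation ("Method 3"). The
fit minimizes

$$\text{mean}_s\bigl[(r-\hat r)^2 + (z-\hat z)^2\bigr]
\;+\; \omega_1\, \text{mean}_s\bigl[(\partial_s^2 \log K_c)^2\bigr],$$

optionally weighting the shape residuals by the observed per-$s$
variances (floored at their 10th percentile). With $\gamma = 0$ the
mismatch is invariant under rescaling $K_c$; the gauge is fixed by
setting the area-weighted mean of $\log K_c$ (weights $\propto r(s)$)
to zero. With $\gamma > 0$ the force sets the absolute scale.

The optimizer is Levenberg-Marquardt on the stacked residuals
(restarted once with a fresh trust region), after priming the forward
solver by ramping the initial profile in from constant so the first
solve sits on the furrowed branch. Two implementation details
matter. First, each cost evaluation warm-starts the forward solve from
the *best* solution found so far, and only improvements replace it;
line-search or trust-region probes far from the optimum then cannot hop
the forward problem onto another shape branch and poison later
evaluations. Second, the finite-difference step for the Jacobian is
widened (`epsfcn = 1e-6`, i.e. steps of order $10^{-3}$ in the log
coefficients) above the forward solver's numerical noise; with
machine-precision steps the Jacobian is noise and the optimizer stalls
after a few iterations. Plain BFGS with finite-difference gradients,
tried first, reliably stalls in the shallow, curved mismatch valley —
most often in a spurious local optimum in which a *uniform* softening
(small constant $K_c$ against the fixed $\gamma$) imitates an
equatorial dip. For the same reason, with no starting profile the
estimator multi-starts from a constant profile and two generic
equatorial dips and keeps the best fit.

### Choosing $\omega_1$

The smoothness weight matters and is deliberately exposed
(`omega1_lcurve()` maps the trade-off and suggests the L-curve corner).
Two scales set the useful range. The second-difference smoothness of a
genuine two-orders-of-magnitude dip is $\sim a_1^2\pi^4/2 \approx 250$,
so any $\omega_1 \gtrsim 10^{-6}$ makes the *constant* profile the
regularized optimum and flattens the estimate — the estimator is doing
exactly what it is told. Conversely, noise-driven wiggles live in high
cosine modes, which the penalty weights as $k^4$; weights of order
$10^{-8}$ (cosine basis) to $10^{-10}$ (nodal basis) suppress them
while biasing the deep dip by well under 0.1 in $\log K_c$. The package
default is $10^{-6}$ (a conservative, general-purpose value); the
parameter-recovery experiments use the smaller mode-selective values
above, chosen from the L-curve on noiseless pilots.

Identifiability is weakest exactly where the biology is most
interesting: near the furrow the area element $r\,dt$ vanishes, so the
shape is insensitive to $K_c$ there, and at fixed noise the furrow-end
uncertainty dominates the error budget. The estimation conditions of
the recovery study (below) were chosen with this in mind.

## Image quantification

The microscopy pipeline mirrors the standard membrane-label workflow:
a directional ridge test binarizes the bright membrane (a pixel is kept
when its intensity exceeds `ratio_f` times *both* flanking pixels at
distance `offset_d` in at least one of four principal directions;
largest 8-connected component retained); Moore boundary following
along the pixels facing the enclosed cytoplasmic region yields the
ordered inner boundary (BP1); a curvature-adaptive walk accepts the
next point once its deviation from the line through the two previous
accepted points exceeds 2 px, inserting a midpoint where the interior
angle turns acute in hairpins (BP2); discrete curvature per arc is the
reciprocal of the mean distance from the crossing point of neighbouring
circumcircle normals to the two arc endpoints (exact on circles), signed
negative when the crossing point lies outside the cell.

`quantify_cell` then: refines BP2 points to subpixel by intensity-
weighted centroids along the local normals (two passes; the second pass
recomputes normals from refined points and removes the radial bias);
finds the rotational axis as the principal second-moment axis through
the *arclength-weighted* centroid (unweighted moments are biased by
uneven BP2 spacing); places the equatorial plane at a strict interior
minimum of the radius envelope within the central half of the axis span
(midpoint fallback otherwise, the choice is recorded); splits the cycle
into four pole-to-equator quadrants, interpolating exact pole
($r = 0$) and equator anchors on the local circumcircular arcs; and
summarizes each quadrant on a uniform $s$ grid with
endpoint-pinned smoothing splines of the measured meridian (reporting
$r$, $z$, furrow radius, solid-of-revolution $V$ and $A$ from the data
avoids the drift a tangent-angle re-integration of noisy points would
accumulate). Per-arc $C_m$ values are mapped to the $s$ grid by a
chord-length-weighted Gaussian kernel (bandwidth 0.08 in $s$) with
outlier clipping at 4 MAD, because short arcs give unstable
circumcircle estimates. $C_p$ values at $s < 0.2$ are flagged: near the
pole $C_p = \sin\theta/r$ amplifies any radial error, so large
uncertainties there are intrinsic, not a defect.

## Synthetic data: what it emulates, and what not

The generator's conditions are fixed as the study design. Volume is
constant at 1.0 cell unit. The per-bin area schedule emulates the
observed pattern that area growth runs ahead of the furrow early and
barely keeps up late: in early bins the bin-centre radius sits just
below the force-free equilibrium radius (constriction is nearly free),
while in late bins it approaches the two-sphere geometric bound (the
minimum-area shape with that neck radius). The schedule was calibrated
once so the ring force a spatially *constant*-stiffness surface would
need at the bin centres rises monotonically and steeply (about 0.5,
1.5, 4, 15, 30, 55, 90, 150, 450 force units) — constriction beyond
the mutant's arrest point costs more than a plausible ring budget,
which is the arrest mechanism. Note that `required_force` reports this
holding force as the dual of a pinned-furrow solve: under deep
constriction the fixed-force furrow-radius map folds (the neck snaps
shut), so inverting it would yield the snap threshold instead of the
force balance. The wild-type-like stiffness profile is an
equatorial dip, $\log K_c = -d(b)\,(1+\cos(\pi(1-s)))/2$, with depth
growing linearly over bins to $\ln 100$ (a pole-to-furrow ratio of two
orders of magnitude); the mutant-like scenario keeps $K_c$ spatially
constant and stops at the 0.6–0.5 bin, where ingression arrests in the
mutant. Bin shapes are solved with the furrow pinned at the bin centre;
the implied ring force is slightly negative in the earliest bin (the
cell is rounder than the force-free equilibrium — other mechanics hold
early shapes spherical), rises through mid-cytokinesis, and falls again
late as softening takes over. Observations perturb quadrant meridians
with i.i.d. Gaussian noise (SD 0.01 length units, i.e. 1% of the unit
radius), with a separate curvature noise channel whose $C_p$ term is
inflated near the pole; every artifact records its seed and ground
truth.

The renderer draws the mirrored contour as a Gaussian ridge (FWHM =
`membrane_width_px`) over a dark background and returns the true CCP
mask (ideal ridge above 15% of peak). It does not emulate a PSF,
z-sectioning, photobleaching, multi-cell scenes, or non-axisymmetric
shapes — so passing round-trip tests demonstrates correctness of the
quantification algorithms, not robustness to every microscopy artefact.

## Numerical choices and problem sizes

Defaults: forward solver $N = 200$ nodes (tests and estimation loops
use 100–160); constraint tolerance $10^{-6}$ relative; multi-start
minimum search perturbs the seed's neck mode over amplitudes
$[-0.8, 1.4]$ with seeded jitter and clusters solutions at contour RMSD
0.02. The parameter-recovery study uses a stable fixed-force fixture
($v = 0.82$, $\gamma = 5$, dip depth up to $\ln 100$), 117 quadrant
contours per observation (a typical per-bin sample size for this assay),
a 50-point $s$ grid, and estimator forward solves at $N = 100$; Method 3
is warm-started from the Method 2 estimate, its initial profile being
free by construction. These sizes were chosen once, as the study design,
to keep every experiment reproducible on a single CPU.

## Known limitations

* The forward model is quasi-static: no viscous flows, cytoplasmic
  mechanics, or astral forces.
* Surface tension is not part of the model; the alternative
  tension-based estimator is out of scope.
* The estimator assumes the observation is an equilibrium of the
  assumed-$\gamma$ forward model. Ring-stabilized late shapes violate
  this at face value; fits under several fixed $\gamma$ values (0, 5,
  20, 50) are the supported workflow, as in the original analyses.
* Furrow-region stiffness is weakly identified from shape alone
  (vanishing area element); pointwise errors there dominate the
  recovery budget, and real-data estimates inherit the same weakness,
  modulated by $\omega_1$.
* The quadrant split assumes a single cell with one furrow on a
  roughly elliptical outline; multi-cell scenes and 3-D segmentation
  are out of scope.
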