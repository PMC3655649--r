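---
title: "Measuring Poisson's ratio of soft materials from four-marker quadrilaterals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Poisson's ratio of soft materials from four-marker quadrilaterals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadpoisson)
```

## The measurement model

Soft hydrogels stretch by tens of percent under loads too small to measure
with contact gauges, so their Poisson's ratio is measured optically: ink
spots sprayed on the surface are tracked through a microscope + CCD camera
mounted over a micro X-Y stage. Two practical complications motivate this
package.

**Coordinate fusion.** Each marker is observed as a pair (stage reading in
mm, in-image position in px). The two frames are rotated against each other
by an offset $\theta_{s\text{-}c}$, so the global position is

$$\mathbf{g} = \mathbf{s} + \mathbf{o} + p \, R(\theta_{s\text{-}c})\,\mathbf{c},$$

with $p$ the pixel scale (mm/px), $R$ the counterclockwise rotation and
$\mathbf{o}$ an arbitrary origin offset. Only *differences* of global
positions enter the strain computation, so $\mathbf{o}$ defaults to zero.
$\theta_{s\text{-}c}$ is estimated by driving the stage along one of its
axes while imaging a stationary marker: the track in the image is a line
whose direction relative to the declared axis is the offset. We fit that
line by total least squares (the first principal direction of the camera
positions) because both image coordinates carry comparable error; the fit
is invariant to translation and uniform scaling of the track. If sweeps
along both axes are provided, the two angle estimates are averaged — the
axes are orthogonal, so both measure the same offset and averaging halves
the variance. The pixel scale cannot be identified from an angle sweep and
is taken as an explicit input from a user-supplied reference distance,
which keeps the calibration deterministic and auditable. Raw image rows
grow downward; readers flip the camera y-axis to the mathematical
convention at ingest (`flip_camera_y`, default on) — leaving this silent
would flip the sign of every estimated angle. One convention the user must
fix per rig: whether the estimated angle or its negative enters the fusion
depends on whether the stage carries the sample or the camera.

**Misalignment.** The classical estimator assumes the stretch axis is the
global y-axis. With initial coordinates $(x_i, y_i)$ measured from the
loading-axis origin and final $(x_f, y_f)$,

$$x_f = x_i(1 - \epsilon_y \nu), \qquad y_f = y_i(1 + \epsilon_y),$$

and $\nu$ follows from coordinate ratios (`naive_poisson()`, per-marker
estimates combined by arithmetic mean — the simplest unbiased choice, and
fixing it makes the bias demonstrations reproducible). A specimen clamped
at an angle violates the assumption and biases this estimator severely;
the package keeps it only as the comparison baseline.

## Element kinematics

The robust estimator treats the four markers as vertices of a first-order
isoparametric quadrilateral. With bilinear shape functions
$N_k(\xi,\eta) = \tfrac14 (1+\xi_k\xi)(1+\eta_k\eta)$ over
$(\xi,\eta) \in [-1,1]^2$, both the geometry and the displacement field are
interpolated from the vertices, and the deformation gradient at any
interior point is

$$F = \left(\textstyle\sum_k \mathbf{x}_k \nabla_\xi N_k\right)
      \left(\textstyle\sum_k \mathbf{X}_k \nabla_\xi N_k\right)^{-1},$$

initial coordinates $\mathbf{X}$, deformed $\mathbf{x}$. For a homogeneous
(affine) deformation $F$ is constant over the element and exact. Strain
measures derived from $F$:

| measure | formula | use |
|---|---|---|
| `small` (default) | $\mathrm{sym}(F) - I$ | matches engineering strain; exact for stretches without rigid rotation *during* deformation |
| `green_lagrange` | $(F^\top F - I)/2$ | invariant to rigid rotation of the deformed state; principal values $(\lambda^2-1)/2$ |
| `biot` | $\sqrt{F^\top F} - I$ | rotation-invariant *and* principal values equal stretch $-\,1$ |

Poisson's ratio is $\nu = -\epsilon_2/\epsilon_1$ from the principal
strains (closed-form 2×2 symmetric eigendecomposition; the principal
direction is $\tfrac12 \operatorname{atan2}(2\epsilon_{xy},
\epsilon_{xx}-\epsilon_{yy})$, normalized to $(-90°, 90°]$).

Choice of default: under a uniaxial stretch of 40 % with $\nu = 0.2$ the
small-strain measure reports principal strains $(0.4, -0.08)$ and
$\nu = 0.2$ — engineering-strain values. Green–Lagrange would report
$(0.48, -0.0768)$, hence $\nu = 0.16$: it is rotation-invariant but its
ratio is *not* the engineering $\nu$ at finite strain. Biot combines both
virtues (principal values $\lambda - 1$, so $\nu$ is exact even when the
specimen rotates while deforming) and is the recommended measure whenever
rigid rotation during the deformation step cannot be excluded:

```{r measures}
q <- make_quad("rectangle", 10, 0.3)
pair <- apply_deformation(q, deformation_scenario(0.4, nu_true = 0.2,
                                                  post_rotation_deg = 25))
c(small = evaluate_step(pair, measure = "small")$nu,
  green_lagrange = evaluate_step(pair, measure = "green_lagrange")$nu,
  biot = evaluate_step(pair, measure = "biot")$nu)
```

Rotating *both* configurations together (camera mounted at an angle) leaves
every measure unchanged — that is the core misalignment-robustness
property, and the property suite asserts it to 1e-10 over random rotations.

**Evaluation point.** The default is the element centroid
$(\xi,\eta)=(0,0)$, the single-value-per-element convention. The
`gauss_mean` mode averages the four 2×2 Gauss points $(\pm 1/\sqrt3)$;
both agree exactly for affine deformations. The heterogeneity diagnostic —
the largest Frobenius distance between a Gauss-point tensor and the
centroid tensor — is exactly zero for homogeneous deformation and grows
with bilinear (hourglass) non-uniformity, flagging specimens that violate
the homogeneity assumption between the markers.

**Vertex ordering.** Input marker order is arbitrary: vertices are
re-ordered counterclockwise starting from the lexicographically smallest
vertex of the initial quad, and the deformed quad follows by label. This
makes every result invariant to marker relabeling and row order. Simple but
non-convex quads are accepted (the centroid Jacobian of any positive-area
simple quad is valid); self-intersecting marker sets are rejected, and a
non-positive Jacobian determinant at a requested off-centre point raises an
error naming the offending $(\xi,\eta)$.

## Tunable parameters

- `tol` (default `1e-6`, dimensionless strain): smallest $|\epsilon_1|$
  treated as a real deformation; below it $\nu$ is undefined and an
  undeformed-specimen error is raised. At the generator's default noise of
  zero this only triggers for genuinely identical configurations.
- Equibiaxial states ($\epsilon_1 = \epsilon_2$) legitimately give
  $\nu = -1$; the principal direction is then undefined, so a warning (not
  an error) is attached.
- Elongation is reported as $100\,\epsilon_1$: for an aligned specimen this
  is grip-to-grip engineering strain, and unlike a grip-based definition it
  remains meaningful under misalignment. Per-step results are always
  computed against the *original* reference configuration (total strain),
  matching a stepwise tension protocol that re-images the same markers at
  every elongation.
- All interfaces use degrees; internals use radians.

## The synthetic generator

`deformation_scenario()` applies
$R(\rho)\,[R(\theta)\,\mathrm{diag}(1-\nu\epsilon_a,\, 1+\epsilon_a)\,R(\theta)^\top]$
plus translation and iid Gaussian coordinate noise: a homogeneous stretch
$\epsilon_a$ along an axis tilted $\theta$ from global y (specimen
misalignment), with optional rigid rotation $\rho$ acquired during
deformation. Defaults mirror the hydrogel experiment the package targets: a
10 × 3 mm marker rectangle, $\nu_{\mathrm{true}} = 0.44$ (near-incompressible
hydrogel), elongations swept over roughly 2.6–47 %, misalignments up to
~32°. No noise magnitude is published for such optical rigs; the default is
0 and the illustrative level used in the stochastic tests is 0.01 mm
(≈ 10 µm, i.e. 0.2 px at the 0.05 mm/px spot-image default — a realistic
subpixel centroiding error).

The image layer renders markers as isotropic Gaussian spots (peak 1000,
background 100 grey levels, $\sigma = 3$ px) and detects them by
thresholding at a fraction of the background-to-peak range, 8-connected
labelling, and intensity-weighted centroids; the quality score
(minor/major second-moment ratio) flags merged spots. Real ink spots are
irregular and their photon noise is not Gaussian-stationary; what
downstream stages consume is centroiding *accuracy*, which the round-trip
tests bound at 0.05 px, not spot realism.

What passing tests therefore show: the estimator is exact for homogeneous
deformation at any orientation and unbiased under small Gaussian
coordinate noise. What they cannot show: behaviour under real inhomogeneous
strain fields, viscoelastic drift (experimentally, $\nu$ of a drying
hydrogel falls with time under load), or out-of-plane thickness effects —
the method is strictly 2D.

## Numerical choices and problem sizes

Principal strains use the closed-form Mohr's-circle solution (cross-checked
against a general symmetric eigensolver to 1e-12 in the tests); the Biot
square root uses the eigendecomposition of $F^\top F$ with eigenvalues
clamped at zero. The test suite runs the affine-map oracle on 20 random
simple quads × 5 interior points, 1e4 shape-function samples, 100 random
co-rotations, a 3 × 3 × 5 (strain × $\nu$ × angle) noiseless recovery grid,
and a 500-replicate noise study at $\sigma$ = 0.01 mm; finite-difference
cross-checks of $F$ use central differences with step 1e-6 in natural
coordinates at tolerance 1e-8.

## Limitations

Single element only — no meshing, no stress computation, no constitutive
model (the displacement-driven strain computation needs none). The naive
baseline requires markers off the coordinate axes; the element method has
no such restriction. Calibration assumes a pure rotation between frames:
lens distortion, perspective and stage backlash are out of scope.
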