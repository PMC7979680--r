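---
title: "Personalizing hexahedral head models: registration, morphing, and strain analysis"
author: "morphhead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing hexahedral head models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphhead)
```

## The problem

Finite-element (FE) head models predict how brain tissue deforms during an
impact. Anatomically detailed models are built once, at great cost, on a
template anatomy and meshed with millions of hexahedra. To study a specific
person, the template (baseline) mesh must be *morphed* onto that subject's
MRI: an image registration pipeline produces a dense displacement field
representing the anatomical difference, the field moves the mesh nodes while
preserving connectivity, and the morphed mesh must retain solver-grade
element quality. Once a subject-specific mesh exists, diffusion-tensor
imaging supplies a per-element white-matter fiber direction, and the strain
tensors from an impact simulation can be projected onto those directions to
obtain *axonal strain*, a candidate injury predictor alongside the maximum
principal strain.

`morphhead` implements this machinery end to end at desk scale: the field
algebra, a hierarchical two-stage deformable registration, hexahedral
morphing with scaled-Jacobian gating, DTI eigen-analysis and fiber mapping,
Green–Lagrange strain post-processing with regional peak extraction, and the
two validation metrics used to quantify the result — DICE overlap for
personalization accuracy and the CORA cross-correlation rating for
time-history biofidelity. A synthetic module generates every input with
closed-form ground truth, so the whole pipeline is testable without any
imaging download.

## Displacement fields and their two conventions

All spatial data live in world millimetres; voxel indices are 0-based with
voxel centres at integer indices (the NIfTI convention). A single
displacement field can be read in two incompatible ways, so the convention
is a tagged, first-class property of every `VectorField`:

* **resampling** (pull-back): `out(x) = in(x + u(x))` — how images are
  warped;
* **forward** (push-forward): `x' = x + u(x)` — how mesh nodes move.

Registration returns resampling fields (fixed = subject, moving =
baseline); `invertField()` converts between the conventions by fixed-point
iteration and flips the tag; `morphMesh()` only accepts forward fields.
This discipline makes the warped baseline image and the morphed mesh
provably consistent: both are pushed through the same map, one by pull-back
of intensities, the other by push-forward of nodes.

Sampling is trilinear, exact on affine fields. Out-of-domain lookups are a
hard error beyond 0.5 voxel for point sampling (a silently zero-filled
displacement would corrupt mesh morphing invisibly), while image warping
clamps at the boundary, which is the conventional resampling behaviour.
Composition is true function composition
`u1(x) + u2(x + u1(x))`; a literal voxelwise sum is also provided
(`mode = "sum"`) because the two stage fields of the hierarchical pipeline
are often described as simply "adding up" — with true composition as the
default, since it is the mathematically consistent choice. Both modes agree
exactly for constant fields and differ at second order for smooth ones.

## Diffeomorphic demons registration

The deformable engine is intensity demons with a stationary velocity field.
Per pyramid level it iterates the classical optical-flow force

$$ d = \frac{(m\circ\varphi - f)\,\nabla f}{\|\nabla f\|^2 + (m\circ\varphi - f)^2}, $$

caps each update at `maxStep` voxels, Gaussian-smooths the update
(`sigmaUpdate`, fluid-like regularization) and the accumulated velocity
(`sigmaField`, diffusion-like), and exposes the displacement as the
exponential of the velocity by scaling and squaring, with enough squarings
that each half-step stays below half a voxel. The exponential of a smooth
velocity is a diffeomorphism, and the package checks the discrete Jacobian
determinant of every returned field. The iterate with the lowest SSD is
retained per level, so the final similarity never exceeds the initial one;
a level that cannot improve at all aborts with diagnostics.

The defaults — pyramid (4, 2, 1), iterations (100, 50, 20), `sigmaUpdate`
1.0 voxel, `sigmaField` 1.5 voxels, `maxStep` 2.0 voxels, at least 4
squarings — are this package's own calibration: the published pipeline
inherits its parameters from external registration software and does not
state them. They were chosen so that synthetic diffeomorphisms with a few
voxels of displacement are recovered on phantom pairs, and every one is
exposed through `demonsSettings()`.

The force is invariant to a common intensity rescaling of both images, so
binary masks and T1-like intensities can use the same defaults.

## The hierarchical personalization pipeline

`personalize()` runs, on the baseline grid:

1. **Rigid pre-alignment.** A deterministic 6-DOF principal-axes transform:
   centroids and covariance eigenvectors of the two cranial masks, with the
   overlap-maximizing proper sign assignment among the four candidates.
   For a perfect sphere the rotation is unconstrained (any principal basis
   is valid) while the translation remains exact; this is documented
   behaviour, not an error. Deterministic axes were preferred over
   iterative optimization because mask-level alignment does not need more
   and the result is platform-stable.
2. **Stage 1: cranial-mask demons** (field 1). Masks are softened with a
   1-voxel Gaussian so that boundary forces have capture range. This stage
   absorbs the large head-size and head-shape difference.
3. **Skull stripping.** The baseline T1 warped through field 1, and the
   subject T1, are both multiplied by their *cranial* (intracranial) masks.
   Stripping with the intracranial rather than the brain-only mask keeps
   the CSF–skull edge in the images, so the next stage has data support up
   to the cranial surface and cannot drift the alignment that stage 1
   established there.
4. **Stage 2: intensity demons** on the stripped images (field 2), refining
   interior structures. An externally computed field (e.g. from an
   attribute-matching registration) can be substituted verbatim via
   `personalizeConfig(stage2Field = ...)`; the pipeline contract only needs
   *a* dense second-stage resampling field.
5. **Combination.** The resampling composition is
   `composeFields(field2, field1)`: an image lookup first passes through
   field 2, then field 1, matching the order in which the warps were
   estimated. (`composeMode = "sum"` reproduces the literal voxelwise
   reading.)
6. **Mesh morphing.** The combined field is numerically inverted to the
   forward baseline-to-subject map and applied to the mesh nodes;
   connectivity and part labels are untouched.
7. **Reporting.** Element quality, warped T1, and DICE against the
   subject's masks and optional region labels.

## Element quality: the scaled Jacobian

"Jacobian" thresholds for hexahedra are solver-dialect-dependent; this
package reads them as the corner-based *scaled* Jacobian: at each of the 8
corners, the determinant of the three emanating edge vectors divided by the
product of their lengths, minimized over corners. The metric lives in
[-1, 1], equals 1 for any axis-orthogonal box regardless of aspect ratio,
is invariant to rigid motion and uniform scaling, and goes negative exactly
when a corner inverts. This reading is consistent with quality floors
quoted as 0.2/0.45/0.5 in the head-model literature, which would be
unit-dependent under a raw-determinant definition. The morphing acceptance
gate is: at least 95% of elements at or above 0.5 *and* a minimum not below
0.2 — two separate gates, both reported, with exact integer counting.

## DTI: FA, fiber mapping, tractography

Fractional anisotropy uses the standard closed form
`FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`. Mapping to the
mesh follows the nearest-voxel rule: each element takes the FA and first
eigenvector of the tensor voxel closest to its centroid, in world
coordinates, with ties resolved to the lowest linear index (deterministic
across platforms). Streamline tracking integrates the first eigenvector
with Euler steps (default 0.5 mm), bidirectionally from each seed, with
sign continuity and the standard termination triad (FA < 0.2, turning
angle > 45 degrees, domain exit). Euler rather than Runge–Kutta matches
the cited classical streamline construction and keeps the circular-arc
error bound (< one step over a quarter arc) analytically testable.
Directions are obtained by interpolating the six *tensor* components and
re-solving the eigenproblem at the sample point, which sidesteps the
eigenvector sign ambiguity that makes direct eigenvector interpolation
ill-defined. The sign ambiguity is irrelevant to axonal strain because the
projection is a quadratic form — asserted by test, not assumed.

## Strain: Green–Lagrange, principal, axonal

`elementStrainHistory()` computes the deformation gradient at each element
centroid from the trilinear shape-function gradients of the reference
configuration, `F = I + du/dX`, and `E = (F'F - I)/2`. Single-point
centroid evaluation mirrors common solver element output; Gauss-point
averaging is deliberately out of scope. The construction is exact for
affine motions and identically zero for rigid ones (objectivity), and both
properties are enforced by oracle tests rather than assumed.

Axonal strain is the projection `eps_axon = v' E v` onto the element fiber
direction. It obeys the Rayleigh bounds `lambda3 <= eps_axon <= lambda1`
and never exceeds the first principal strain. `regionalPeaks()` extracts,
per region, the maximum (or a stated percentile, nearest-rank rule on the
per-element peak distribution — deterministic, no interpolation ambiguity)
of principal strain (MPS) and axonal strain (MAS), with the peak's element
and time. MAS is evaluated only in regions with coherent fiber orientation
(cerebral white matter, corpus callosum, brain stem); gray-matter
structures such as thalamus and hippocampus are excluded as nearly
isotropic. Where peak bookkeeping is ambiguous (max-over-time of the
regional curve versus max of per-element peaks — identical values,
different argmax), the reported element/time locate the reported element's
own peak, which coincides with the global argmax at percentile 100. Strain
tensors are stored with tensor shear (`Exy = gamma/2`); CSV import honours
a JSON header field declaring `"engineering"` shear and halves it, because
solver dialects differ.

## Validation metrics

**DICE** is the standard overlap `2|A∩B| / (|A|+|B|)`; two empty masks are
defined as 1, with a warning. **CORA** is implemented as the
cross-correlation sub-method only (the corridor sub-method is deliberately
absent): shape V from the maximal normalized cross-correlation over shifts
up to `dMax`·T, phase P from the shift magnitude through the linear window
(`dMin`, `dMax`), size G from the ratio of the squared-curve integrals
after the optimal shift, each clipped to [0, 1], combined with equal
weights as (V + G + P)/3 and aggregated across channels and cases by
arithmetic mean with the sample (n−1) standard deviation — the n−1 choice
is validated against a published "mean ± SD" row that only the sample
definition reproduces. The window/exponent defaults (`dMin` 0.01, `dMax`
0.12, unit exponents) are config-exposed; no package result depends on
them, only on the stated combination and aggregation. A cross-correlation
maximum at the scan boundary is rated as a shift of `dMax`·T (phase 0),
the formula's limit.

## The synthetic module and what it does (not) show

Phantoms are nested ellipsoids — cranial space, brain, and eight labeled
subregions — with piecewise-constant T1-like intensities, 1-voxel Gaussian
smoothing and optional seeded noise; masks are exact pre-noise geometry.
Ellipsoids keep every downstream ground truth closed-form: volumes,
overlaps, and the effect of analytic warps. The default 64-cube grid at
1 mm spacing with cranial semi-axes (26, 22, 20) mm is the package's study
condition; a scale factor of 1.37 reproduces the roughly 2.6-fold
smallest-to-largest adult intracranial-volume range reported for large
imaging cohorts. Analytic warps (`affine`, `sinusoid`, `radial`) carry an
amplitude gate derived from an operator-norm bound guaranteeing an
analytic Jacobian determinant of at least 0.2, plus exact forward and
inverse evaluators. Modal impact histories apply a raised-cosine envelope
to affine spatial modes — with the rotation mode scaled in *angle* so the
motion is rigid at every instant — and return the closed-form strain peak
for recovery tests.

What passing these tests shows: the algebra, the registration contract,
the morphing/quality/strain/rating machinery are correct on data whose
ground truth is known exactly. What they do not show: performance on real
MRI, where intensity nonuniformity, anatomical detail far richer than
nested ellipsoids, and genuinely non-smooth inter-subject correspondence
make registration harder. One observation from the phantom studies
transfers directly, though: a deformation component *tangential* to tissue
interfaces is invisible to edge-driven registration (the aperture
problem), so warp-recovery claims are only meaningful for fields with
interface-normal structure — the package's acceptance study uses a radial
bulge, which is normal to every nested surface, for exactly that reason.

## Numerical choices and limitations

* Field inversion: fixed-point iteration, tolerance 0.01 voxel, 30
  iterations; non-convergence is an error unless the input was already
  flagged non-diffeomorphic, in which case a best-effort result is
  returned under a warning.
* Nearest-voxel ties: lowest linear index, everywhere.
* The acceptance study sizes (64-cube grid, 12x10x9-element mesh, 10^4
  random draws) are the package's chosen study conditions; they keep the
  full suite runnable on a laptop in a few minutes.
* The second registration stage is intensity demons, not the
  attribute-matching method used alongside demons in the published
  pipeline; the import hook accepts such a field when one is available.
* No mesh generation, smoothing or repair; no constitutive modeling or FE
  solving; no tensor fitting from raw diffusion-weighted images; no
  probabilistic tractography.

## A worked example

```{r example, eval = FALSE}
base <- makeHeadPhantom(headPhantomSpec())
warp <- makeWarp("radial", amplitude = 0.4, grid = base$t1)
subject <- list(
  t1 = warpImage(base$t1, warp$field, "linear"),
  cranialMask = warpImage(base$cranialMask, warp$field, "nearest"),
  brainMask = warpImage(base$brainMask, warp$field, "nearest"))
mesh <- makeHexLattice(12, 10, 9, spacing = 2,
                       origin = c(31.5 - 12, 31.5 - 10, 31.5 - 9))
res <- personalize(c(base, list(mesh = mesh)), subject)
res@quality
res@diceTable
mean(sqrt(rowSums((meshNodes(res@morphedMesh) -
                   warp$inverse(meshNodes(mesh)))^2)))
```

On the author's machine this prints a passing quality report (all scaled
Jacobians above 0.9), cranial/brain DICE near 0.98, and a mean node
endpoint error of about half a voxel against the analytic ground truth;
`scripts/acceptance.R` recomputes these numbers from scratch.
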