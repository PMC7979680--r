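# morphhead

Subject-specific finite-element (FE) head models by mesh morphing, and the
strain analysis that follows. `morphhead` is an R package for researchers in
head-impact biomechanics and neuroimage-driven FE modeling who need to:

* morph a baseline hexahedral head mesh onto a subject's anatomy through a
  hierarchical deformable registration pipeline (rigid principal-axes
  alignment, then two stages of diffeomorphic demons), with the element
  quality of the morphed mesh gated by the corner-based scaled Jacobian;
* map diffusion-tensor data onto mesh elements (fractional anisotropy and
  first eigenvector at the voxel nearest each element centroid), track
  white-matter streamlines, and project Green–Lagrange strain tensors onto
  fiber directions to obtain axonal strain;
* quantify personalization accuracy (DICE overlap) and time-history
  biofidelity (CORA cross-correlation rating, combined as `(V + G + P)/3`
  and aggregated as mean ± sample SD).

The core quantities, in the field's notation:

* scaled Jacobian of a hexahedron: at each corner,
  `J_c = det[e1 e2 e3] / (|e1||e2||e3|)` over the three emanating edges,
  minimized over the 8 corners; the morphing gate requires ≥ 95% of
  elements at `J ≥ 0.5` with minimum `J ≥ 0.2`;
* Green–Lagrange strain `E = (FᵀF − I)/2` at the element centroid, with
  `F = I + ∂u/∂X` from trilinear shape-function gradients;
* axonal strain `ε_axon = vᵀ E v` along the element fiber direction `v`
  (first eigenvector of the local diffusion tensor), bounded by the extreme
  principal strains;
* fractional anisotropy `FA = √(3/2) · ‖λ − λ̄‖ / ‖λ‖`;
* `DICE(A, B) = 2|A∩B| / (|A| + |B|)`.

Everything is testable offline: a synthetic module generates ellipsoid head
phantoms with nested labeled subregions, analytic diffeomorphic warps with
exact inverses, hexahedral lattices, tensor fields of prescribed FA, and
modal impact histories with closed-form strain peaks.

## Worked example

```r
library(morphhead)

# baseline phantom head + a known analytic deformation as "the subject"
base <- makeHeadPhantom(headPhantomSpec())
warp <- makeWarp("radial", amplitude = 0.4, grid = base$t1)
subject <- list(
  t1          = warpImage(base$t1, warp$field, "linear"),
  cranialMask = warpImage(base$cranialMask, warp$field, "nearest"),
  brainMask   = warpImage(base$brainMask, warp$field, "nearest"))

mesh <- makeHexLattice(12, 10, 9, spacing = 2,
                       origin = c(31.5 - 12, 31.5 - 10, 31.5 - 9))
res <- personalize(c(base, list(mesh = mesh)), subject)

res@quality
#> QualityReport: min SJ 0.9604 | >=0.50: 100.0% | >=0.45: 100.0% | PASS (floor 0.20)
res@diceTable
#>   cranial     brain
#> 0.9755517 0.9769213
mean(sqrt(rowSums((meshNodes(res@morphedMesh) -
                   warp$inverse(meshNodes(mesh)))^2)))
#> [1] 0.5295182
```

The quality report says every morphed element keeps a scaled Jacobian above
0.96 (the gate needs 95% above 0.5), the warped baseline overlaps the
subject's cranial and brain masks with DICE ≈ 0.98, and the morphed mesh
nodes land within about half a voxel (0.53 mm on a 1 mm grid) of the exact
analytic baseline-to-subject map, on average.

Strain post-processing on the same mesh:

```r
imp <- makeImpactHistory(mesh, "stretch", peakTime = 36, amplitude = 1.2)
sh  <- elementStrainHistory(mesh, imp$motion)
regionalPeaks(sh, labels = rep(2L, nrow(meshElements(mesh))))
#>       region metric peak element time percentile
#> 1 cerebralWM    MPS 0.22       1   36        100
```

A 20% uniaxial stretch peaks at `E_xx = (1.2² − 1)/2 = 0.22` at the 36 ms
envelope peak — recovered exactly.

A thin CLI (`exec/morphhead`) wraps the main operations
(`quality`, `morph`, `dice`, `cora`, `phantom`, `dti-map`) for shell use on
the standard formats: NIfTI volumes and displacement fields (with a JSON
sidecar naming the field convention), legacy ASCII VTK meshes and
polylines, and long-format CSV histories.

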