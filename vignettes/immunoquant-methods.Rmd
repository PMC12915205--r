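---
title: "Methods: spot calling on ELISPOT membranes and 3D T-cell infiltration scoring"
author: "immunoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot calling and 3D infiltration scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoquant)
```

# Scope

`immunoquant` quantifies two immune-imaging readouts that are usually
handled by closed commercial software:

1. **ELISPOT spot calling** — counting IFN-γ-secreting T-cells from a
   membrane photograph, where every dark spot marks one cytokine-secreting
   cell. The pipeline is adaptive thresholding → morphological cleanup →
   connected-component labelling → physical size filtration → a per-well
   report with counts, size distribution and per-spot metrics.
2. **3D T-cell infiltration scoring** — in two-channel confocal z-stacks
   of tumor-organoid/T-cell co-cultures on a microfluidic chip: detect
   individual T-cells as bright blobs, segment the organoid body and
   measure its volume, compute each cell's signed shortest distance to the
   organoid surface, and classify cells against a depth window (default
   0 µm contact down to 200 µm deep). Replicate chips are pooled as
   mean ± SEM with a minimum of two chips per condition.

Both pipelines operate on calibrated containers (`CalibratedImage2D`,
`CalibratedStack3D`) that carry physical pixel/voxel sizes, so every
interface parameter is in micrometres; pixel and voxel units exist only
internally. 3D arrays use `(z, y, x)` axis order; physical positions are
voxel-centre positions, i.e. 0-based index `i` maps to `(i + 0.5)·d` µm at
spacing `d`. This one-convention rule is what keeps anisotropic stacks
(`dz > dx`, the usual confocal situation) correct everywhere: smoothing
scales, minimum separations and distance transforms are all expressed in
µm and converted per axis.

# The 2D spot-calling model

A membrane image is modelled as a slowly varying background (illumination
and membrane texture) with compact dark spots on top. The segmentation
statistic is the **local mean**: pixel `p` is foreground when

```
I(p) < mean(I, window (2r+1)²) − offset        (dark spots on light)
```

with the comparison flipped for fluorescent (light-on-dark) readouts.
Borders use symmetric reflection. A local statistic makes the threshold
invariant to illumination gradients; the simple mean (rather than a
Gaussian-weighted one) was chosen because it is exactly computable with an
integral image and easy to reason about: the response to a neighbouring
object is just `depth × (object area / window area)`.

Two parameter interactions matter in practice, and both are visible in
that formula:

* **The window must be larger than the largest object radius.** If an
  object is wider than the window, its interior sees a local mean equal to
  its own dark level and hollows out; fragments of its rim can then fall
  into the accepted size range. Hole filling recovers moderately large
  objects, but the robust regime is `window radius ≥ largest object
  radius`. The package default (25 px) suits images where spots are tens
  of pixels; the validation suite, whose synthetic wells contain artifacts
  up to 120 µm at 1 µm/px, uses 100 px.
* **The offset sets the noise/sensitivity trade-off.** Pixels pass the
  threshold spuriously with probability `Φ(−offset/σ_noise)`; the
  subsequent opening (disc radius 1) removes any component not containing
  a full 3×3 block, which in practice eliminates random false positives
  for `offset ≥ 2σ_noise`. The suite uses `offset = 60` against noise
  SD 30.

Morphology runs in the fixed order opening → closing → hole filling
(disc-shaped elements; radius 0 skips a step). Opening removes speckle,
closing re-attaches fragments across thin eroded gaps, hole filling
restores interiors of large adaptive-thresholded objects. In dense wells
(≈150 spots) the accumulated local-mean depression from many neighbours
can split the rim of a large object; a closing radius of 3 px re-attaches
such fragments and is safe as long as distinct objects are further apart
than twice the closing radius. The package defaults stay at (1, 1, fill);
the validation conditions use closing 3 for this reason.

Connected components use 8-connectivity by default (diagonal pixel runs
remain one spot); labels are assigned in array storage order of each
component's first pixel, which makes labelling — and therefore every
report — fully deterministic. No watershed splitting of confluent spots is
attempted: merged spots remain one component, which is the documented
behaviour of the counting rule, and the generator keeps planted objects
non-overlapping for exactly this reason.

The size filter is physical and inclusive: a component is accepted iff
`min_area_um2 ≤ area ≤ max_area_um2`. The default range **[40, 4000] µm²**
(equivalent diameters ≈ 7–71 µm) spans typical ELISPOT spot sizes; since
no universal range exists, the range actually applied is echoed into every
report so no filtering is ever implicit. Reported per-spot metrics are
pixel and physical area, unweighted centroid, equivalent circular diameter
`2·sqrt(area/π)`, mean intensity, and the eccentricity of the
second-moment ellipse.

# The 3D infiltration model

## T-cell detection

T-cells appear as anisotropic bright blobs of roughly 5 µm diameter in XY
and 10 µm extent in Z (the axial elongation reflecting the point-spread
function). Detection follows the standard blob-scale relation
`σ_axis = diameter_axis / (2·sqrt(3))` per axis in µm, converted to voxels
through the stack's voxel sizes. The response is a difference of
Gaussians (σ and 1.6σ); candidate cells are its 26-neighbourhood local
maxima above a detection floor, thinned so no two detections lie within
one expected diameter of each other along any axis (ellipsoidal
suppression, strongest response wins), then refined to sub-voxel centroids
by an intensity-weighted mean over the blob neighbourhood.

The floor combines two terms: the response quantile given by
`min_intensity_quantile` (default 0.99) and a robust noise guard,
`median(response) + 10·MAD(response)`. The guard is what makes a
background-only stack yield zero detections — a pure quantile floor, by
construction, calls something in any noise field. The quantile default is
deliberately mild (top 1 %) because in a realistic chamber the blobs
occupy a tiny volume fraction and an aggressive quantile can land inside
blob-response territory and censor true cells. If the stack is thinner
than the expected cell height, detection warns and proceeds in-plane.

## Organoid segmentation and volumetry

The organoid channel contains one large contiguous bright body. It is
binarised (Otsu on a 256-bin histogram of the full 3D channel by default,
or a fixed threshold), the largest 26-connected component is kept, and
fully internal cavities are filled (background components not reaching the
stack border). Volume is voxel counting times voxel volume. The closed
surface is triangulated directly from exposed voxel faces with outward,
consistent winding; its enclosed volume is therefore *identical* to the
voxel volume (both count the same voxels), which the tests assert exactly.
The mesh is a faithful boundary representation at grid resolution, not a
smoothed rendering.

## Signed distances and the depth window

Each cell centroid gets the Euclidean distance in µm to the nearest
organoid surface point, negative inside. It is computed from two exact
anisotropy-aware distance transforms (Felzenszwalb–Huttenlocher with
per-axis spacing): distance to the mask for outside points and distance to
the complement for inside points, combined with signs and sampled at the
voxel containing the centroid. The sign is exact by construction
(negative ⇔ the centroid voxel is inside the mask); the magnitude carries
a discretisation error below one voxel diagonal, which the sphere
closed-form tests bound.

Distances are centroid-to-surface. The original measurements were made
between object *surfaces*; an optional `cell_radius_um` correction
(subtract a nominal radius from outside distances, floored at contact) is
provided but off by default, because centroid distances are exactly
testable against analytic geometry while a radius correction folds in an
assumption about cell size.

Classification against the depth window `[−200, 0] µm` is inclusive at
both bounds: contact (0 µm) counts as infiltrated, as does a cell exactly
200 µm deep. Cells deeper than the window are reported separately as
`excluded_deep`, following the literal depth filter; whether such cells
should instead count as infiltrated is genuinely ambiguous (the stated
bound may simply describe the deepest observation), so a flag
(`include_deeper`) merges them and the result type reports both counts.
The result also carries the infiltrated count normalised per mm³ of
organoid alongside the absolute count, since either normalisation is a
reasonable summary and the volume is measured anyway.

Pooling across replicate chips reports mean and SEM (sample SD/√n) of the
infiltrated count and fraction, and refuses to pool fewer than 2 chips —
per-condition statistics need replication, and that minimum is enforced
rather than assumed.

# The synthetic generators

Both generators are seeded, bit-reproducible, and emit integer "camera
count" images plus an exact answer key; they are the acceptance oracle for
both engines.

**Wells.** Background plane (level 200) with a linear illumination
gradient, anti-aliased dark disks rendered by 4×4 sub-pixel coverage,
Gaussian optical blur (σ 1.5 µm), additive Gaussian noise (SD 30 — an
amplitude SNR of 5 against the spot depth of 150, the hardest condition
the recovery properties are stated for), quantised to integers. Planted
classes are separable by construction: spot diameters 20–60 µm lie
strictly inside the paired size filter, small debris (3.9–4.2 µm) strictly
below it, large blotches (90–120 µm) strictly above it, and the spec
constructor refuses ranges that violate this. Two rendering choices mirror
real membranes and keep the answer key meaningful: small debris is drawn
3× darker than spots (pen marks and pigment specks are, and otherwise
4 µm objects blur below any threshold that still rejects noise), while
large blotches use spot depth (a much darker large object depresses the
adaptive local mean over its whole window footprint and would perturb
*neighbouring* spots — an occlusion effect, not a property of the spot
being tested). Placement is rejection sampling with a pairwise centre
separation of `max(min_separation, r_i + r_j + 10 µm)`, so the separation
rule holds and objects never overlap; small debris additionally keeps a
60 µm clearance so its detectability is intrinsic.

**Scenes.** The organoid channel is a filled analytic sphere or
axis-aligned ellipsoid plus noise; the T-cell channel holds anisotropic
Gaussian blobs (FWHM 10×5×5 µm, peak 100 over background 20, noise SD 10)
at positions solved so each cell's analytic signed distance equals the
requested depth: radially for spheres (exact), along the outward surface
normal for ellipsoids (exact while the offset stays within the smallest
radius of curvature, which the generator respects by restricting ellipsoid
depths). Stored ground-truth distances are closed-form for spheres and
dense-surface-sampled (2×10⁵ points, ≤0.2 µm error) for ellipsoids. Cells
are pairwise ≥10 µm apart.

**What passing on synthetic data does and does not show.** The generators
emulate geometry, calibration, anisotropy, blur, noise and quantisation —
the features the algorithms actually consume — so recovery results
validate the *measurement machinery*: counting, volumetry, distance signs
and magnitudes, window logic, determinism. They do not emulate membrane
texture, uneven staining, confluent spots, irregular organoid shapes,
scattering or depth-dependent attenuation; performance on real
acquisitions therefore still depends on parameter choice (offset vs noise,
window vs object size), which is why every report echoes its parameters.

# Numerical and validation choices

* Computation is double precision throughout regardless of storage dtype;
  integer images in [0, 65535] round-trip TIFF bit-exactly via a 16-bit
  path, arbitrary intensities via float32 with an affine rescale recorded
  in the JSON calibration sidecar (≈1e-9 relative error).
* Label order, NMS tie-breaks (by response, then array index) and JSON
  serialisation are all deterministic; identical input + parameters +
  seed give byte-identical report files, and the suite asserts it.
* Validation problem sizes: 1000 random 32×32 masks against a brute-force
  BFS oracle for labelling; 100 wells of 0–150 spots and 0–20 artifacts at
  SNR 5 for 2D recovery; spheres of R = 60 µm in (2,1,1) µm voxels for
  geometry; ten chambers of 20 infiltrated + 30 outside cells (sphere
  R = 170 µm, (4,2,2) µm voxels) for end-to-end 3D recovery. The 3D scenes
  use 4 µm z-steps — a realistic confocal z-spacing that also keeps each
  chamber around 5×10⁶ voxels.

# Known limitations

* Merged/confluent spots count as one; no declumping is attempted.
* The organoid threshold (Otsu) assumes a bimodal intensity histogram; a
  faint or hollow organoid may need the fixed-threshold mode.
* Signed distances are grid-sampled: sub-voxel accuracy is bounded by one
  voxel diagonal, so very coarse grids coarsen the infiltration boundary
  accordingly.
* The detector assumes roughly Gaussian, separated blobs; tightly packed
  T-cell clusters closer than one cell diameter are suppressed to the
  strongest member.
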