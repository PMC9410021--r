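---
title: "Anatomical sanity checks for vertebra identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical sanity checks for vertebra identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesanity)
```

## The method in one page

Vertebra identification is posed as dense regression: every pixel of a
sagittal-plane view receives a continuous value whose half-up rounding is a
vertebra id (1 = C1 ... 26 = S2, 0 = background). Two stages cooperate:

1. a **detection** stage labels voxels spine/background, trained patchwise
   with class-weighted binary cross-entropy and cleaned by keeping only the
   largest 3D connected component;
2. an **identification** stage regresses per-pixel vertebra values,
   trained by strict alternation of supervised mini-batches (L1 loss against
   dense labels, source domain) and unsupervised mini-batches (the domain
   sanity loss, target domain).

The domain sanity loss encodes four invariances of spinal anatomy that hold
for any patient, hence need no target labels:

| term | invariance | exact form | default weight |
|------|-----------|------------|----------------|
| s1 | vertebra values ascend along the spine | count of descending pixel pairs within `n_shift = 30` columns, / n_pix | c1 = 20 |
| s2 | one label per image column | count of pixels deviating from their column's median spine value, / n_pix | c2 = 1 |
| s3 | adjacent centroids are anatomically spaced | L1 between predicted adjacent-centroid distances and reference distances (mm), / 25 | c3 = 1/40 |
| s4 | predictions are not translated along the spine | per weak-mask component, unique nonzero rounded labels − 1, / n_components | c4 = 1/100 |

The weights bring the terms to a comparable numeric scale. All four
invariances are statements about spine pixels, so the raw prediction is
multiplied by the detection mask first; background pixels are exactly zero
and (by default) excluded from the comparisons.

## Assumptions

* The spine runs roughly parallel to the column axis of the sagittal plane
  (strong rotation should be corrected upstream).
* The adult reference-distance table applies; the absolute-distance check s3
  mis-scores patients far from it (children), a known limitation of
  absolute rather than ratio-based references.
* The standard 26-vertebra constellation; supernumerary or transitional
  vertebrae (L6, lumbalized S1) are outside the label set.
* The spine is the largest bright connected structure in the detection
  output — the premise of largest-component post-processing.

## Exact and surrogate loss modes

The printed forms of the four checks are indicator counts: piecewise
constant, with zero gradient almost everywhere. The package therefore ships
two modes:

* **exact** (`dsl_config(mode = "exact")`) — the counting definitions,
  used for evaluation and verified bitwise against brute-force loop oracles
  in the test suite;
* **surrogate** (`mode = "surrogate"`) — hinge/absolute-deviation
  relaxations used during training: s1 averages the positive part of the
  descent `max(ŷ(i,j) − ŷ(i,j+s), 0)`; s2 and s4 average absolute deviations
  from the (detached) column/component median; s3 is evaluated exactly and
  contributes no gradient, because its centroids are medians of *rounded*
  pixel coordinates and are piecewise constant in the pixel values.

The two modes agree at the optimum: a surrogate of zero implies an exact
count of zero (for s1/s2 the two zero sets coincide; for s4 the surrogate is
the stricter of the two). One ordering subtlety: the order check as printed
would count *equal* neighbouring pixels as violations, which penalizes the
constant plateau inside a single vertebra; the package counts only strictly
descending pairs (`strict_margin = 0`), with the literal variant available as
`strict_ge = TRUE`. Similarly, the normalizer is the total pixel count
`n_pix` as stated, with a `normalize_spine` switch for the
spine-pixels-only variant.

### Balancing the two training signals

The weights c1..c4 calibrate the four *terms* against each other, not the
unsupervised step against the supervised one. The s1 hinge accumulates up to
`c1 · n_shift` subgradient per pixel (one unit per violated shift), whereas
the L1 loss contributes exactly one unit per pixel. Left unscaled, the
sanity step dominates and drives the network to its trivial optimum (a
constant prediction). The target step is therefore scaled by
`uda_grad_scale`, default `1/(c1 · n_shift)` (= 1/600 at the default
constants), which puts the two subgradients on the same footing; the
scaled-down study is insensitive to this value over about an order of
magnitude.

## The weak mask

The shift check needs an image-derived, label-free grouping of pixels into
vertebra-like components. The pipeline is: multiply the scan (not the
prediction) by the detection mask; zero pixels below **180 HU** (cancellous
bone sits well above, soft tissue below); segment with the
Felzenszwalb–Huttenlocher graph algorithm (implemented in C++ in `src/`,
8-neighbour graph, weight = absolute intensity difference, Gaussian
pre-smoothing `felz_sigma = 0.8` px, merging scale `felz_scale = 100`,
`felz_min_size = 40` px); discard segments dominated by zero-intensity
pixels. Components are then filtered by shape heuristics (area within
[25, 5000] px, bounding-box aspect ratio ≤ 3) and components whose bounding
box lies inside another's are merged. The Felzenszwalb parameters and the
filters are configuration, tuned on phantoms: the mask is deliberately weak
— the loss only requires that one component not span two vertebrae, not that
it cover one exactly.

Weak masks (and the loss) are computed in 2D on the sagittal plane of
identification patches, collapsing the thin slab axis by maximum-intensity
projection; the alternative of a full-3D weak mask would be slower and the
shift check is a sagittal-plane notion.

## The spine phantom

The generator emulates what the method actually consumes: a craniocaudal
chain of bright cuboid "vertebral bodies" (≈400 HU) whose centroid spacing
follows the same reference-distance table the loss uses, soft-tissue
background (≈40 HU), Gaussian noise, an optional bright bed-like slab far
from the spine, and a posterior rod (150 HU) that keeps the spine one 3D
connected component the way posterior elements do in real anatomy. Design
points worth making explicit:

* The rod intensity sits *below* the 180 HU weak-mask threshold, so the 2D
  weak mask still resolves individual vertebrae, while the 3D detection
  target stays connected.
* The rod occupies sagittal slabs 3–5 voxels off-centre, symmetric about the
  midplane: the central sagittal slice contains only the perfectly symmetric
  body boxes, so per-slice centroid medians equal the true centroids exactly
  and the ground truth incurs exactly zero loss in all four terms — a
  property the test suite asserts for every seed.
* The target-domain variant multiplies intensities by 0.85, raises the noise
  standard deviation from 20 to 60 HU and randomly crops up to 10 voxels
  from either end of the column axis — a caricature of a different
  scanner/protocol with lower dose and different field of view.

What the phantom does **not** emulate: trabecular texture, pathology,
scoliosis or kyphosis (the chain is straight), partial-volume effects, metal
artefacts, and the anatomical variability of real vertebra shapes. Passing
tests on phantoms therefore demonstrate the *mechanics* of the method — the
loss arithmetic, its invariances, the direction of the adaptation effect —
not clinical performance.

### Shift aliasing

On an idealized phantom, a translation of the labels by exactly one
inter-centroid period (or exactly one body extent) can escape the weak-mask
check: every component then sees exactly one — wrong — label. The check is
provably positive for translations strictly between the gap width and the
body extent, which is what the sensitivity tests use (10 voxels against a
16 mm body and 5 mm gap). On real scans the weak mask is irregular enough
that this aliasing is unlikely, but it is a genuine blind spot of s4 worth
knowing about.

## Numerical choices

* **Rounding** is half-up (`7.5 → 8`); values above 26 clip to 26, and a
  detected spine pixel below 0.5 is floored to 1 (a spine pixel cannot be
  background).
* **Binarization** of detection probabilities at 0.5, with probability 0.5
  mapping to spine; component ties keep the component whose first voxel has
  the smaller column-major position. Connectivity is 26-neighbour by
  default so diagonally touching structures stay one component.
* **Box overlap** in sparse-to-dense conversion resolves to the nearer
  centroid, ties to the lower id.
* **Degenerate inputs**: an all-background prediction, a weak mask with no
  components, or a prediction with fewer than two vertebra ids all yield a
  loss of 0 (not an error); an empty detection mask post-processes to an
  empty mask with a warning.
* **Distance statistics** use the population standard deviation; the
  identification threshold (20 mm) is inclusive.
* **Overall segmentation metrics** micro-average the spine and background
  classes over all voxels (so overall recall and Dice coincide with
  accuracy); the vertebrae-only metrics score the spine class alone and are
  the ones that actually discriminate.

## The default model

The two stages define model contracts (features in, per-pixel output and
gradients out); the default implementation is a deliberately small per-pixel
multilayer perceptron (tanh hidden layer; 8 units for detection, 24 for
identification) over local image features — raw and box-smoothed intensity,
a soft bone indicator centred at 180 HU, and scan-absolute position in mm —
with hand-written backpropagation and Adam. Identification patches
(default 8×80×320 voxels) are collapsed to the sagittal plane by
maximum-intensity projection, with labels from the central slab.
Architecture fidelity to any particular network is a non-goal; the package's
contribution is the training procedure and the loss, and anything exposing
`mlp_forward`/`mlp_backward` semantics can be swapped in.

## Problem sizes of the scaled-down study

`run_e2e_demo()` uses phantoms of 24×48×176 voxels at 1 mm spacing with six
thoracic vertebrae; 3 source, 3 target and 2 held-out target scans;
detection patches 24×24×48 (10 per scan, ≥8 containing spine, 30 epochs,
Adam 1e-2); identification patches 4×40×160 (40 per scan, 12 epochs, batch
8, Adam 3e-3). These sizes were chosen so the full study runs in a couple of
minutes on one CPU core while leaving the domain gap large enough that the
supervised baseline visibly degrades on the target domain; the full-scale
configuration (80×80×96 and 8×80×320 patches, 70/100 epochs, Adam
1e-3/5e-4) remains the package default for real use.

The study asserts *orderings* — adaptation beats the supervised-only
baseline on target-domain pixel accuracy, a couple of labeled target scans
do not hurt the identification rate, post-processing does not hurt detection
IoU — rather than any absolute numbers, which at this scale would be
meaningless.

## Known limitations

* s3/s4 depend on absolute reference distances; ratio-based checks would be
  more robust across body sizes but are not implemented.
* The surrogate mode is a package design decision for differentiability, not
  a claim about how the counting losses were originally optimized.
* Whether s3/s4 should be computed per patch or per assembled scan is an
  open choice; the package computes them per patch, whose 320-column field
  of view spans several vertebrae.
* The weak mask inherits every failure of thresholding + graph segmentation:
  osteoporotic (dim) vertebrae can vanish below 180 HU, and fused or
  bridged vertebrae can merge into one component.
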