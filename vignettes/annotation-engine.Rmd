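---
title: "The voxann annotation engine: model, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The voxann annotation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxann)
```

## The problem and the data model

Training data for medical-image segmentation and classification models is
produced by teams of annotators working over hundreds of NIfTI series.
`voxann` models that process with three commitments:

1. **Dataset-level schemas.** ROI definitions (name, RadLex ID, colour,
   mask value, area/point kind, lock flag) and text-field definitions
   (optionally restricted to a value set) belong to the *project*, not to
   individual images. Every series is annotated against the same
   definitions, so a given ROI has the same name and mask value everywhere.
2. **Imaging is read-only.** Annotation state (label grids, points,
   provenance, versions, custody) lives in a store independent of the
   imaging; no operation writes to a source file. The test suite asserts
   byte-identity of source files across full annotate/export sessions.
3. **Label grids are bit words.** Each voxel holds the sum (bitwise OR) of
   the power-of-two mask values of the ROIs labelling it, so overlapping
   labels (a voxel that is both "kidney" and "tumor") coexist in one grid
   and export losslessly to a single combined mask volume. A project-level
   exclusive mode instead enforces one ROI per voxel; switching it on is
   refused while any voxel is multi-labelled, so no data is silently lost.

### Mask values and the 53-ROI word

Mask values are assigned as the lowest *never-used* power of two: deletion
does not recycle bits, so a stale bit in an old export can never be
reinterpreted as a different ROI. Label words are stored as doubles, which
represent sums of distinct powers of two exactly up to $2^{52}$; the
project therefore caps one export word at 53 ROIs (bit 0 through bit 52)
and raises a capacity error beyond that. Larger schemas must export per-ROI
files. This cap is a storage-representation choice, not a workflow limit;
the largest project the engine is aimed at (a few dozen organs) fits in
one word.

Coordinates are 0-based `(x, y, z)` voxel indices in data-array order;
world coordinates exist only through the 4×4 affine, which is copied from
the source volume and re-attached verbatim to every exported mask. Note
that NIfTI stores affines in single precision: "the exported affine equals
the source affine" means equality with the affine *as stored in the source
file*, which is what any downstream reader sees.

## Editing operators

All editing verbs pass the same gates — target ROI unlocked, acting user
holds the series when a workflow is attached — and push the prior state
onto a per-series undo stack (default depth 100, full-state snapshots;
undo/redo restore labels, provenance and points bit-exactly).

- **Paint/erase** apply a footprint (explicit voxel set or a brush disc) on
  slices $z-k \ldots z+k$, clamped to the volume. The cross-slice extension
  is symmetric; a directional variant would be a trivial generalisation but
  the symmetric form matches how annotators sweep through a stack. An
  optional closed intensity window $[lo, hi]$ restricts the operation to
  in-range voxels — the "threshold painting" idiom for high-contrast
  tissue. Erase clears only the target ROI's bit. In exclusive mode, paint
  is last-write-wins (it replaces the existing label), matching
  interactive expectations.
- **Flood fill** labels the in-slice connected component of the seed among
  in-window voxels (4- or 8-connectivity), or, without a window, within
  the region not yet labelled by this ROI. A seed outside the fillable
  region is a notice and a no-op, not an error.
- **Morphology** uses the smallest standard structuring elements: the
  in-plane 3×3 cross, or the 6-neighbourhood for volume scope.
  Out-of-volume neighbours count as background for dilation and foreground
  for erosion, which keeps dilation from inventing labels outside the
  volume while preserving the extensivity of closing
  ($X \subseteq \mathrm{closing}(X)$) at the border — the property the
  test suite asserts against an independent image-processing oracle. In
  exclusive mode dilation refuses to grow over voxels owned by other ROIs
  (erosion needs no such rule), preventing silent growth over neighbouring
  organs.
- **Points** are landmark annotations for point-kind ROIs; duplicates at
  the same coordinate are rejected.

### Provenance

Provenance is tracked per (slice, ROI) — the granularity at which viewers
display machine-generated labels in a lighter shade. Manual edits mark a
slice manual; refinement and model drafting mark it auto unless the slice
had prior manual edits.

## Contour refinement

`snap_contour()` replaces one slice's region with a refiner's output. The
refiner is a plain function `(plane, mask, ref_values) -> mask`, so any
edge-refinement algorithm can be plugged in; the default is deliberately
simple and fully specified:

1. estimate the intensity band as the 2nd–98th percentiles of the
   currently labelled voxels' intensities (or of `ref_values` when given);
2. take the 4-connected component of the in-band candidate voxels that
   contains the current region's centroid (falling back to the labelled
   in-band voxel nearest the centroid when the centroid itself is
   off-band);
3. fill enclosed holes — voxels outside the percentile band that are
   completely surrounded by the region are organ voxels whose noise
   excursion fell outside the band, and an organ mask should not contain
   salt-noise holes.

Step 3 matters quantitatively: the band excludes 4% of in-organ voxels by
construction, independent of the noise level, capping a literal
band-component refiner near Dice 0.95 on noisy phantoms; with hole filling
the refiner reaches Dice ≥ 0.97 per slice on the cylinder fixture.

`auto_contour()` marches outward from the already-labelled slices, seeding
each empty slice with its neighbour's refined region. The intensity band is
always estimated from the *seed slices'* human-initiated regions rather
than re-estimated per slice: re-estimation compounds the percentile
truncation slice by slice, and a band anchored to the organ's true
distribution empties out where the object vanishes, which is exactly the
stopping rule.

## Metrics

Per-slice Dice and Jaccard are computed on one ROI's bit planes; slices
where both masks are empty agree vacuously (1.0, flagged). The volume
summary pools the voxels of the selected slices rather than averaging
per-slice values: pooling is invariant to how the object's mass is
distributed across slices and does not let many small both-empty or
near-empty slices dominate the summary. Both conventions exist in
practice; the pooled one is declared and tested here
(`volume metric = metric of the concatenated planes`). The identity
$J = D/(2-D)$ is asserted to $10^{-12}$ over 1,000 random mask pairs.

ROI statistics use the affine's 3×3 determinant for the voxel volume and a
64-bin equal-width histogram over the observed range (bin count chosen for
a readable display of 8-16-bit medical intensities; a single-valued ROI
gets one degenerate bin).

## The model harness

A model is its metadata: weights file (HDF5), input mode, spatial ops,
normalization, and an output mapping. Execution is behind a
`function(array) -> scores` contract produced by a named loader, so the
tests (and the AID harness) run pure-array models with no deep-learning
runtime; a backend binding is one registered loader away.

Choices the metadata does not dictate, fixed here:

- **3-D tiling**: stride = patch/2 per axis, last patch snapped to the
  volume edge; per-class scores blended with separable raised-cosine
  windows (plus a small floor so border voxels covered by one patch keep
  weight), normalised so the per-voxel weights sum to exactly 1 — asserted
  numerically for every tested layout.
- **Decision rule**: argmax with class 0 = background by default; an
  optional per-class threshold rule exists for binary channels.
- **Registry versioning**: importing a name again auto-increments its
  version and activates it; discovery of a dropped bundle honours a higher
  declared version (pushed models carry their own numbering) and is
  idempotent on unchanged directories; malformed bundles are skipped with
  a report.

## Interpretability maps

The built-in toy-network engine (dense, same-padding 3×3 convolution,
global average pooling, flatten; linear/relu/sigmoid) computes exact
reverse-mode gradients of a class score with respect to the input and any
layer's output, verified against central finite differences to relative
error ≤ 1e-3 (observed ~1e-10).

- **Saliency** = |∂score/∂input|, channels reduced by max (a common
  convention; sum would differ only by scale on one-channel inputs).
- **Grad-CAM** at layer $l$: $\alpha_k = \mathrm{mean}(\partial y_c /
  \partial A^k)$, map $= \mathrm{ReLU}(\sum_k \alpha_k A^k)$, bilinearly
  upsampled to input resolution.
- **CAM** requires the GAP + single linear head architecture and refuses
  anything else with an architecture error. On such models CAM and
  final-layer Grad-CAM coincide up to the positive factor $1/(HW)$
  carried by the gradient means; the equivalence is asserted on min-max
  normalised maps (and the exact $HW$ proportionality separately).
- **SAM** is implemented as the product of the min-max-normalised saliency
  and Grad-CAM maps, renormalised to [0, 1]. The originating method's
  exact formula is published elsewhere; this stand-in is clearly flagged
  and the combination rule is a pluggable argument.

Maps are nonnegative; automatic thresholding hides values below
`fraction × max(map)` (default fraction 0.2 — low enough to keep diffuse
activation visible, high enough to suppress near-zero background), keeps
the originals so the threshold is dynamically adjustable, and is idempotent
at a fixed fraction.

## Workflow state machine

Workflows are YAML: users with roles, pools, per-role rights
(`may_acquire_from`, `may_assign_to`, and optional per-user
`may_assign_to_users` overrides), and an `initial_pool` for unannotated
series. Rights attach to roles with per-user target sets because the two
kinds of statement the format must express — "analysts take work from the
analyst pool" and "this reviewer may hand work to that specific analyst" —
are naturally role-level and user-level respectively. The custody invariant
(exactly one of pool/owner; only the owner can edit; an ownership change
commits exactly one version) is model-checked by randomized operation
interleavings in the tests. Custody mutations go through the project
environment serially; the contract is that no two mutations observe the
same prior state, which a networked backend would realise with an advisory
lock.

## Phantoms and the AID harness

The phantom generator emulates the one property of real series the engine's
correctness arguments need: objects of known extent at a foreground
intensity over background, with additive Gaussian noise. Defaults — 32³
voxels, one ellipsoid with semi-axes 4-8 voxels, foreground 100 over
background 0, noise σ = 20 (contrast-to-noise ratio 5, an ordinary value
for soft-tissue CT), seeded RNG — are the package's declared test
conditions. What phantoms do *not* emulate: anatomical texture, partial
volume effects, anisotropic spacing, or inter-annotator disagreement;
passing tests certify the engine's mechanics, not clinical segmentation
difficulty.

The AID loop mirrors iterative model-assisted annotation: iteration 0
annotates `batch_per_iteration` phantoms from scratch (edit cost = full
truth size); each later iteration trains on all corrected volumes, drafts
the next batch through the *same* inference path user models take, and
corrects drafts against truth. Two declared proxies:

- **Edit cost** is the symmetric-difference voxel count between draft and
  truth. Human annotation time cannot be reproduced at desk scale; voxels
  an annotator must add or remove is the natural mechanical surrogate.
- **Correction is perfect** (corrected = truth), modelling the
  reviewed-and-approved end state of the multiuser workflow.

The default trainer is per-voxel logistic regression on intensity and a
3×3 in-slice local mean — trainable in milliseconds, yet genuinely learned
from the corrected data, so the loop's limit behaviours are testable: an
oracle trainer gives zero edit cost after iteration 0, a null trainer stays
at de-novo cost, and the default trainer on a 20-phantom suite (4
iterations, 3 seeds) cuts mean edit cost from ~870 voxels to single digits.
Problem sizes throughout (32³ phantoms, 20-volume suites, 1,000-pair metric
sweeps, 100-project round trips) are chosen so the full property suite
exercises every code path in well under a minute of CPU per module.

## Known limitations

- DICOM is out of scope; imaging enters as NIfTI.
- No network/content-management backend; the storage seam is the
  filesystem store behind `project_save()`/`project_load()`.
- Whole-volume 3-D models are not supported (2-D slice and patch-wise 3-D
  modes are).
- The default refiner is a documented stand-in for a dedicated
  edge-refinement algorithm; swap it via the `refiner` argument.
- Surface-distance metrics (e.g. Hausdorff) are not provided; agreement is
  overlap-based.
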