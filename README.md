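# voxann

A headless R engine for annotating volumetric medical imaging (NIfTI) at the
dataset level, built for teams producing voxel-label training data for
machine-learning models.

Annotating hundreds of CT/MRI series for segmentation or classification
models has two recurring failure modes: annotation definitions drift across
a dataset (the same organ ends up with different names, colours or mask
values in different volumes), and annotation metadata gets entangled with,
or corrupts, the source imaging. `voxann` addresses both. A **project**
defines the region-of-interest (ROI) and text-annotation schemas once;
every series is annotated against those definitions, and all annotation
state lives in a store independent of the imaging, which is never modified.

On top of that data model the package provides:

- **Voxel editing operators** — brush painting/erasing with an intensity
  threshold window and symmetric cross-slice extension, in-slice flood fill
  (4/8-connectivity), binary dilation/erosion (3×3 cross in-plane,
  6-neighbourhood in 3-D), point landmarks, undo/redo, and per-(slice, ROI)
  manual/auto provenance.
- **Semi-automated contouring** — `snap_contour()` refines one slice's rough
  region via a pluggable refiner (default: connected component around the
  region centroid within the [p2, p98] intensity band of the labelled
  voxels, with hole filling); `auto_contour()` propagates refinement across
  slices and stops where the object vanishes.
- **Agreement metrics** — per-slice and pooled-volume Dice
  `D = 2|A∩B| / (|A|+|B|)` and Jaccard `J = |A∩B| / |A∪B|`
  (with `J = D/(2−D)`), plus ROI descriptive statistics (voxel count,
  physical volume from the affine determinant, moments, 64-bin histogram).
- **Mask I/O** — masks export as NIfTI volumes whose affine equals the
  source affine, either one binary file per ROI or a single combined file
  whose voxel values are the bitwise OR of the ROIs' power-of-two mask
  values, next to a `roi_name,radlex_id,mask_value` sidecar CSV, in a
  directory hierarchy mirroring the dataset. Import inverts export
  bit-exactly. Tables export as CSV or XLSX.
- **Multiuser workflow** — a YAML-defined state machine of users, roles,
  pools and assignment rights. A series is held by exactly one pool or
  owner; only the owner may edit; every ownership change auto-commits a
  version.
- **Model plugin harness** — models are described by metadata (HDF5 weights
  + YAML sidecar): input mode (2-D slices or patch-wise 3-D with
  cosine-window blending whose per-voxel weights sum to 1), spatial ops,
  normalization (minmax / zscore / fixed window), and an output mapping
  from class indices to ROIs (segmentation) or text values
  (classification). A registry versions models and discovers pushed
  bundles.
- **Interpretability** — saliency, CAM, Grad-CAM and SAM activation maps
  with exact reverse-mode gradients on the built-in toy network engine, and
  automatic thresholding that hides activations below a fraction of the map
  maximum.
- **AID harness** — annotation by iterative deep learning: annotate a small
  batch, train, draft the next batch with the model, correct, retrain.
  Synthetic ellipsoid phantoms with exact ground truth make the whole loop
  testable; human correction effort is proxied by the symmetric-difference
  voxel count between draft and truth.

## Worked example

```r
library(voxann)

ph <- generate_phantom(phantom_config(seed = 7))   # 32^3, one ellipsoid
p  <- project_create()
define_roi(p, "lesion", color = c(255, 0, 0))
add_series(p, "s1", image = ph$image)

# rough manual seed on the mid-lesion slice + threshold paint
# (the seed-7 ellipsoid is centred near voxel (9, 10, 22), 0-based)
apply_edit(p, "s1", edit_request("lesion", "paint", slice = 22,
                                 center = c(9, 10), radius = 3,
                                 threshold = c(50, 150)))

# refine that slice, then propagate across the volume
snap_contour(p, "s1", "lesion", 22)
auto_contour(p, "s1", "lesion", c(0, 31))

# compare against the phantom's exact truth
truth <- label_volume(dim(ph$image)); truth$labels[ph$truth] <- 1
agreement(truth, get_label_volume(p, "s1"), 1)
#> agreement over 32 slice(s): volume Dice 0.9890, Jaccard 0.9783

roi_statistics(p, "s1", "lesion")
#> ROI statistics (volume): n=813, volume=813.00 mm^3, mean=100.436,
#> sd=19.068, range=[37.0268, 166.99]
```

One rough brush stroke plus refinement recovers the 829-voxel ellipsoid at
Dice 0.989. The statistics summarize the labelled voxels' intensities
(mean ≈ the phantom's foreground intensity of 100, sd ≈ its noise level of
20) — the histogram behind them is how an annotator picks threshold windows
in practice.

A thin command-line front end over the same functions ships in
`inst/cli/voxann.R` (`project init`, `roi add`, `annotate paint|fill|morph`,
`metrics`, `export`, `import`, `version`, `workflow validate`, `aid run`).

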