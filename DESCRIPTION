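Package: voxann
Title: Dataset-Level Voxel Annotation Engine for Medical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless engine for annotating volumetric medical imaging
    (NIfTI) at the dataset level. Projects define region-of-interest and
    text-annotation schemas once and enforce them across every series;
    voxels are labelled through manual and semi-automated operators
    (painting, erasing, flood filling, morphology, contour snapping) with
    threshold constraints, cross-slice extension, undo/redo and per-slice
    provenance. Annotations are stored independently of the source imaging,
    versioned, and exported as bitmask volumes aligned to the source
    geometry with sidecar label mappings. Includes Dice/Jaccard agreement
    metrics, a metadata-driven model plugin harness for 2-D and patch-wise
    3-D inference, gradient-based interpretability maps (saliency, CAM,
    Grad-CAM, SAM), a YAML-defined multiuser annotation workflow state
    machine, and a harness for annotation by iterative deep learning (AID)
    with synthetic phantom fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    RNifti,
    yaml,
    digest,
    rhdf5,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
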