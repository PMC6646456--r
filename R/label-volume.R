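# Per-series multi-label bitmask grid. `labels` is an X x Y x Z double array
# of bit words; `provenance` maps "z:mask_value" -> "manual"/"auto" at the
# per-(slice, ROI) granularity the lighter-colour display distinguishes;
# `points` holds point-kind ROI landmarks as 0-based voxel coordinates.

#' Construct an empty label volume
#'
#' @param shape integer triple (X, Y, Z) of voxel counts.
#' @param affine 4x4 voxel-to-world transform, copied exactly from the source
#'   volume so exported masks align with the imaging.
#' @return object of class `voxann_labels`: a list with `labels` (bit-word
#'   array), `shape`, `affine`, `provenance`, `points`.
#' @export
label_volume <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1))
    va_stop("shape", "label volume shape must be three positive extents")
  structure(list(
    labels = array(0, dim = shape),
    shape = shape,
    affine = affine,
    provenance = character(0),   # named: "<z>:<mask_value>" -> manual|auto
    points = data.frame(mask_value = numeric(0), x = integer(0),
                        y = integer(0), z = integer(0))
  ), class = "voxann_labels")
}

#' @export
print.voxann_labels <- function(x, ...) {
  cat("voxann label volume ", paste(x$shape, collapse = "x"), ": ",
      sum(x$labels > 0), " labelled voxel(s), ",
      nrow(x$points), " point(s)\n", sep = "")
  invisible(x)
}

labels_nonempty <- function(lv) any(lv$labels > 0) || nrow(lv$points) > 0

# Logical mask of one ROI's bit plane (whole volume or a single slice).
roi_mask <- function(lv, mask_value, slice = NULL) {
  if (is.null(slice)) bit_test(lv$labels, mask_value)
  else bit_test(lv$labels[, , slice + 1L, drop = FALSE][, , 1L], mask_value)
}

prov_key <- function(slice, mask_value) paste0(slice, ":", mask_value)
prov_bits <- function(keys) as.numeric(sub("^.*:", "", keys))

set_provenance <- function(lv, slices, mask_value, origin) {
  for (z in slices) lv$provenance[[prov_key(z, mask_value)]] <- origin
  lv
}

#' Provenance of a (slice, ROI) pair
#'
#' Whether the labels an ROI carries on a slice were human-edited
#' (`"manual"`), wholly machine-generated (`"auto"`), or absent (`NA`).
#' Viewers display auto slices in a lighter shade of the ROI colour.
#'
#' @param lv a `voxann_labels` object.
#' @param slice 0-based slice index.
#' @param mask_value the ROI's mask value.
#' @export
slice_provenance <- function(lv, slice, mask_value) {
  key <- prov_key(slice, mask_value)
  if (key %in% names(lv$provenance)) unname(lv$provenance[[key]])
  else NA_character_
}

# Deep snapshot/restore of annotation content (used by undo and versioning).
labels_snapshot <- function(lv) {
  list(labels = lv$labels, provenance = lv$provenance, points = lv$points)
}

labels_restore <- function(lv, snap) {
  lv$labels <- snap$labels
  lv$provenance <- snap$provenance
  lv$points <- snap$points
  lv
}
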