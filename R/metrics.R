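# Descriptive ROI statistics and segmentation agreement metrics. Dice and
# Jaccard are computed per slice on one ROI's bit plane; the volume summary
# pools the voxels of the selected slices (scale-invariant) rather than
# averaging per-slice values.

#' Descriptive statistics of an ROI's intensities
#'
#' Statistics of the image intensities under one ROI's mask, over the whole
#' volume or a single slice. The physical volume is the voxel count times the
#' voxel volume, `|det(A[1:3,1:3])|` of the affine, in mm^3 for standard
#' NIfTI affines.
#'
#' @inheritParams apply_edit
#' @param roi ROI name.
#' @param scope `"volume"` or `"slice"`.
#' @param slice 0-based slice index (required for slice scope).
#' @param bins number of equal-width histogram bins over `[min, max]`.
#' @return an object of class `voxann_roi_stats`: voxel_count,
#'   physical_volume, mean, std, min, max, histogram (breaks + counts),
#'   empty flag.
#' @export
roi_statistics <- function(project, series, roi,
                           scope = c("volume", "slice"), slice = NULL,
                           bins = 64L) {
  scope <- match.arg(scope)
  def <- roi_get(project, roi)
  img <- series_image(project, series)
  lv <- get_label_volume(project, series)
  if (scope == "slice") {
    if (is.null(slice)) va_stop("validation", "slice scope needs a slice")
    mask <- roi_mask(lv, def$mask_value, slice)
    vals <- img[, , slice + 1L][mask]
  } else {
    mask <- roi_mask(lv, def$mask_value)
    vals <- img[mask]
  }
  vox_vol <- abs(det(lv$affine[1:3, 1:3]))
  n <- length(vals)
  if (n == 0) {
    return(structure(list(scope = scope, voxel_count = 0L,
                          physical_volume = 0, mean = NA_real_,
                          std = NA_real_, min = NA_real_, max = NA_real_,
                          histogram = NULL, empty = TRUE),
                     class = "voxann_roi_stats"))
  }
  rng <- range(vals)
  breaks <- if (rng[1] == rng[2]) c(rng[1] - 0.5, rng[1] + 0.5) else
    seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- hist(vals, breaks = breaks, plot = FALSE)$counts
  structure(list(
    scope = scope, voxel_count = n, physical_volume = n * vox_vol,
    mean = mean(vals), std = if (n == 1) 0 else stats::sd(vals),
    min = rng[1], max = rng[2],
    histogram = list(breaks = breaks, counts = counts), empty = FALSE
  ), class = "voxann_roi_stats")
}

#' @export
print.voxann_roi_stats <- function(x, ...) {
  if (x$empty) {
    cat("ROI statistics (", x$scope, "): empty ROI\n", sep = "")
  } else {
    cat(sprintf(
      "ROI statistics (%s): n=%d, volume=%.2f mm^3, mean=%.3f, sd=%.3f, range=[%g, %g]\n",
      x$scope, x$voxel_count, x$physical_volume, x$mean, x$std, x$min, x$max))
  }
  invisible(x)
}

dice_jaccard <- function(a, b) {
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  if (na + nb == 0) return(c(dice = 1, jaccard = 1, both_empty = 1))
  d <- 2 * ni / (na + nb)
  j <- ni / (na + nb - ni)
  c(dice = d, jaccard = j, both_empty = 0)
}

#' Segmentation agreement (Dice / Jaccard) between two label volumes
#'
#' Metrics on one ROI's bit plane, per slice and pooled over the selected
#' slices. Slices where both masks are empty agree vacuously and report 1.0
#' with a `both_empty` flag.
#'
#' @param reference,prediction `voxann_labels` objects of identical shape.
#' @param mask_value the ROI's mask value (bit plane to compare).
#' @param slices 0-based slice indices; default all.
#' @return an object of class `voxann_agreement`: `per_slice` data frame
#'   (slice, dice, jaccard, both_empty) and `volume_dice`/`volume_jaccard`
#'   over the pooled voxels.
#' @export
agreement <- function(reference, prediction, mask_value, slices = NULL) {
  if (!identical(reference$shape, prediction$shape))
    va_stop("shape", "reference and prediction shapes differ")
  nz <- reference$shape[3]
  slices <- slices %||% (0:(nz - 1L))
  if (any(slices < 0) || any(slices >= nz))
    va_stop("validation", "slice index out of range")
  per <- t(vapply(slices, function(z) {
    dice_jaccard(roi_mask(reference, mask_value, z),
                 roi_mask(prediction, mask_value, z))
  }, c(dice = 0, jaccard = 0, both_empty = 0)))
  a <- roi_mask(reference, mask_value)[, , slices + 1L, drop = FALSE]
  b <- roi_mask(prediction, mask_value)[, , slices + 1L, drop = FALSE]
  vol <- dice_jaccard(a, b)
  structure(list(
    per_slice = data.frame(slice = slices, dice = per[, "dice"],
                           jaccard = per[, "jaccard"],
                           both_empty = per[, "both_empty"] == 1),
    volume_dice = unname(vol["dice"]),
    volume_jaccard = unname(vol["jaccard"]),
    both_empty = vol["both_empty"] == 1
  ), class = "voxann_agreement")
}

#' @export
print.voxann_agreement <- function(x, ...) {
  cat(sprintf("agreement over %d slice(s): volume Dice %.4f, Jaccard %.4f\n",
              nrow(x$per_slice), x$volume_dice, x$volume_jaccard))
  invisible(x)
}
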