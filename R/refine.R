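# Semi-automated edge refinement. The refiner is pluggable: it receives the
# intensity plane and the current in-slice ROI mask and returns the refined
# mask. The default grows the connected component around the current region's
# centroid among voxels whose intensity lies within the 2nd-98th percentile
# band of the currently labelled voxels — a simple high-contrast-organ
# refiner standing behind the same interface a more elaborate algorithm
# would plug into.

#' Default percentile-band edge refiner
#'
#' @param plane 2-D intensity matrix of the slice.
#' @param mask logical matrix, the current in-slice ROI region (nonempty).
#' @param ref_values optional intensities to estimate the band from (used by
#'   cross-slice propagation, where the trusted region lives on the
#'   neighbouring slice); default the intensities under `mask`.
#' @return logical matrix, the refined region.
#' @export
percentile_band_refiner <- function(plane, mask, ref_values = NULL) {
  vals <- ref_values %||% plane[mask]
  band <- stats::quantile(vals, c(0.02, 0.98), names = FALSE, type = 7)
  cand <- plane >= band[1] & plane <= band[2]
  ij <- which(mask, arr.ind = TRUE)
  ctr <- round(colMeans(ij))
  ctr <- pmin(pmax(ctr, 1L), dim(plane))
  if (!cand[ctr[1], ctr[2]]) {
    # centroid off the band (e.g. concave region): seed from the labelled
    # in-band voxel nearest the centroid
    inband <- ij[cand[ij], , drop = FALSE]
    if (nrow(inband) == 0) return(mask & FALSE)
    d2 <- (inband[, 1] - ctr[1])^2 + (inband[, 2] - ctr[2])^2
    ctr <- inband[which.min(d2), ]
  }
  comp <- connected_component2(cand, ctr, connectivity = 4)
  fill_holes2(comp)
}

# Fill enclosed holes: complement pixels not 4-connected to the image border
# belong to the region (noise voxels falling outside the percentile band
# should not punch holes in an organ mask).
fill_holes2 <- function(region) {
  bg <- !region
  outside <- matrix(FALSE, nrow(bg), ncol(bg))
  outside[1, ] <- bg[1, ]; outside[nrow(bg), ] <- bg[nrow(bg), ]
  outside[, 1] <- outside[, 1] | bg[, 1]
  outside[, ncol(bg)] <- outside[, ncol(bg)] | bg[, ncol(bg)]
  repeat {
    grown <- dilate2(outside, 4) & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  region | (bg & !outside)
}

#' Refine one slice's ROI region ("snap contour")
#'
#' Replaces the ROI's region on the slice with the refiner's output. If the
#' slice carried no manual edits for this ROI before the call, the result is
#' flagged as auto provenance (displayed in a lighter shade); otherwise it
#' stays manual.
#'
#' @inheritParams flood_fill
#' @param slice 0-based slice index; the ROI must already label at least one
#'   voxel there.
#' @param refiner a `function(plane, mask) -> mask`; defaults to
#'   [percentile_band_refiner()].
#' @return the updated label volume, invisibly.
#' @export
snap_contour <- function(project, series, roi, slice,
                         refiner = percentile_band_refiner, user = NULL) {
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user)
  img <- series_image(project, series)
  lv <- get_label_volume(project, series)
  word <- lv$labels[, , slice + 1L]
  mask <- bit_test(word, def$mask_value)
  if (!any(mask))
    va_stop("precondition", "ROI '", def$name,
            "' has no labelled voxel on slice ", slice)
  snap <- labels_snapshot(lv)
  refined <- refiner(img[, , slice + 1L], mask)
  was_manual <- identical(slice_provenance(lv, slice, def$mask_value),
                          "manual")
  word <- bit_clear(word, def$mask_value)
  if (project$exclusive_mode) {
    free <- word == 0
    word[refined & free] <- def$mask_value
  } else {
    word[refined] <- bit_set(word[refined], def$mask_value)
  }
  lv$labels[, , slice + 1L] <- word
  lv <- set_provenance(lv, slice, def$mask_value,
                       if (was_manual) "manual" else "auto")
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' Propagate contour refinement across slices ("auto contouring")
#'
#' Starting from the slices already labelled within `slice_range`, each
#' unlabelled slice is seeded with the refined region of its nearest refined
#' neighbour and then refined itself, marching outward until the range ends
#' or a refined region comes back empty (the object has vanished).
#'
#' @inheritParams snap_contour
#' @param slice_range 0-based `c(from, to)` inclusive slice range.
#' @return the updated label volume, invisibly.
#' @export
auto_contour <- function(project, series, roi, slice_range,
                         refiner = percentile_band_refiner, user = NULL) {
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user)
  img <- series_image(project, series)
  lv <- get_label_volume(project, series)
  zr <- slice_range[1]:slice_range[2]
  if (any(zr < 0) || any(zr >= lv$shape[3]))
    va_stop("validation", "slice_range out of bounds")
  seeded <- zr[vapply(zr, function(z) {
    any(bit_test(lv$labels[, , z + 1L], def$mask_value))
  }, logical(1))]
  if (!length(seeded))
    va_stop("precondition", "no seed slice labelled within the range")
  snap <- labels_snapshot(lv)

  takes_ref <- length(formals(refiner)) >= 3
  refine_one <- function(z, seed_mask, ref_values = NULL) {
    word <- lv$labels[, , z + 1L]
    cur <- bit_test(word, def$mask_value)
    if (!any(cur)) {
      if (!any(seed_mask)) return(FALSE)
      word[seed_mask] <- bit_set(word[seed_mask], def$mask_value)
      cur <- seed_mask
    }
    refined <- if (takes_ref && !is.null(ref_values))
      refiner(img[, , z + 1L], cur, ref_values)
    else refiner(img[, , z + 1L], cur)
    word <- bit_clear(lv$labels[, , z + 1L], def$mask_value)
    word[refined] <- bit_set(word[refined], def$mask_value)
    lv$labels[, , z + 1L] <<- word
    was_manual <- identical(slice_provenance(lv, z, def$mask_value), "manual")
    lv <<- set_provenance(lv, z, def$mask_value,
                          if (was_manual) "manual" else "auto")
    any(refined)
  }

  # refine the seed slices in place, then march outward from each flank.
  # Propagated slices are seeded with the neighbour's refined region but the
  # intensity band is always estimated from the refined *seed* slices (the
  # trusted, human-initiated regions): re-estimating it slice-by-slice would
  # compound the percentile truncation, and a band anchored to the organ's
  # true distribution empties out where the object vanishes, stopping the
  # march.
  ref_values <- unlist(lapply(seeded, function(z) {
    img[, , z + 1L][bit_test(lv$labels[, , z + 1L], def$mask_value)]
  }))
  for (z in seeded) refine_one(z, NULL)
  march <- function(zs) {
    prev <- NULL
    for (z in zs) {
      already <- any(bit_test(lv$labels[, , z + 1L], def$mask_value))
      if (already) {
        prev <- bit_test(lv$labels[, , z + 1L], def$mask_value)
        next
      }
      if (is.null(prev)) next
      ok <- refine_one(z, prev, ref_values = ref_values)
      if (!ok) break
      prev <- bit_test(lv$labels[, , z + 1L], def$mask_value)
    }
  }
  march(zr[zr >= min(seeded)])        # upward from the lowest seed
  march(rev(zr[zr <= max(seeded)]))   # downward from the highest seed
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}
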