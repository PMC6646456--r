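# Manual and semi-automated voxel editing verbs. All of them go through the
# same gates: the target ROI must be unlocked, the acting user must hold the
# series when a multiuser workflow is defined, and every mutation pushes the
# prior annotation state onto the series' undo stack. Coordinates are 0-based
# (x, y, z) voxel indices in data-array order.

#' Describe a paint or erase operation
#'
#' The footprint is either an explicit set of in-slice voxels or a brush disc
#' of radius `radius` around `center`. The operation applies to slices
#' `slice - slice_extent ... slice + slice_extent` (clamped to the volume),
#' and, when a threshold range is given, only to voxels whose image intensity
#' lies in the closed interval `[lo, hi]`.
#'
#' @param roi ROI name.
#' @param mode `"paint"` or `"erase"`.
#' @param slice 0-based z index of the edited slice.
#' @param center in-slice `(x, y)` 0-based brush centre (with `radius`).
#' @param radius brush disc radius in voxels; 0 is a single voxel.
#' @param footprint alternatively, an explicit n x 2 matrix of 0-based
#'   `(x, y)` coordinates.
#' @param slice_extent nonnegative number of adjacent slices on each side to
#'   extend the operation to (cross-slice painting).
#' @param threshold optional `c(lo, hi)` intensity window restricting the
#'   operation.
#' @return an `edit_request` list.
#' @export
edit_request <- function(roi, mode = c("paint", "erase"), slice,
                         center = NULL, radius = 0, footprint = NULL,
                         slice_extent = 0, threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(footprint)) {
    if (is.null(center))
      va_stop("validation", "either footprint or center must be given")
    r <- floor(radius)
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, , drop = FALSE]
    footprint <- cbind(x = center[1] + offs$dx, y = center[2] + offs$dy)
  }
  footprint <- matrix(as.integer(footprint), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  if (nrow(footprint) == 0)
    va_stop("validation", "footprint must be nonempty")
  if (!is.null(threshold)) {
    if (length(threshold) != 2 || threshold[1] > threshold[2])
      va_stop("validation", "threshold must be c(lo, hi) with lo <= hi")
  }
  if (slice_extent < 0)
    va_stop("validation", "slice_extent must be nonnegative")
  list(roi = roi, mode = mode, slice = as.integer(slice),
       footprint = footprint, slice_extent = as.integer(slice_extent),
       threshold = threshold)
}

check_edit_gate <- function(project, series, def, user,
                            need_kind = "area") {
  if (!is.null(need_kind) && def$kind != need_kind) {
    va_stop("wrong_tool", "ROI '", def$name, "' is a ", def$kind,
            " annotation; this tool edits ", need_kind, " annotations")
  }
  if (def$locked)
    va_stop("locked_roi", "ROI '", def$name, "' is locked")
  if (!is.null(project$workflow) && !can_edit(project, user, series))
    va_stop("permission", "user '", user %||% "<none>",
            "' does not hold series '", series, "'")
  invisible(TRUE)
}

history_of <- function(project, series, capacity = 100L) {
  project$history[[series]] %||%
    list(undo = list(), redo = list(), capacity = capacity)
}

push_history <- function(project, series, snap) {
  h <- history_of(project, series)
  h$undo <- c(h$undo, list(snap))
  if (length(h$undo) > h$capacity) h$undo <- h$undo[-1L]
  h$redo <- list()
  project$history[[series]] <- h
  invisible(NULL)
}

#' Apply a paint or erase edit
#'
#' Painting sets the ROI's bit (in exclusive mode it replaces any other
#' label); erasing clears only this ROI's bit, leaving co-labels intact.
#' Provenance of every modified (slice, ROI) pair is set to manual and the
#' previous state is pushed onto the undo stack.
#'
#' @param project a `voxann_project`.
#' @param series series identifier.
#' @param request an [edit_request()].
#' @param user acting user id (checked against workflow custody when a
#'   workflow is defined).
#' @return the updated label volume, invisibly.
#' @export
apply_edit <- function(project, series, request, user = NULL) {
  def <- roi_get(project, request$roi)
  check_edit_gate(project, series, def, user)
  img <- series_image(project, series)
  lv <- get_label_volume(project, series)
  snap <- labels_snapshot(lv)
  d <- dim(img)
  zmax <- d[3] - 1L
  slices <- max(0L, request$slice - request$slice_extent):
    min(zmax, request$slice + request$slice_extent)
  fp <- request$footprint
  ok <- fp[, 1] >= 0 & fp[, 1] < d[1] & fp[, 2] >= 0 & fp[, 2] < d[2]
  fp <- fp[ok, , drop = FALSE]
  touched <- integer(0)
  for (z in slices) {
    idx <- cbind(fp[, 1] + 1L, fp[, 2] + 1L, z + 1L)
    if (!is.null(request$threshold)) {
      v <- img[idx]
      idx <- idx[v >= request$threshold[1] & v <= request$threshold[2], ,
                 drop = FALSE]
    }
    if (nrow(idx) == 0) next
    if (request$mode == "paint") {
      if (project$exclusive_mode) lv$labels[idx] <- def$mask_value
      else lv$labels[idx] <- bit_set(lv$labels[idx], def$mask_value)
    } else {
      lv$labels[idx] <- bit_clear(lv$labels[idx], def$mask_value)
    }
    touched <- c(touched, z)
  }
  lv <- set_provenance(lv, touched, def$mask_value, "manual")
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' Flood-fill an in-slice region
#'
#' Labels the connected component of the seed voxel within the given
#' intensity window, or, when no threshold is supplied, within the
#' yet-unlabelled region bounded by this ROI's existing labels on the slice.
#' A seed falling outside the candidate region is a no-op (a notice, not an
#' error).
#'
#' @inheritParams apply_edit
#' @param roi ROI name.
#' @param seed 0-based `(x, y, z)` seed voxel.
#' @param threshold optional `c(lo, hi)` intensity window.
#' @param connectivity in-slice connectivity, 4 or 8.
#' @return the updated label volume, invisibly.
#' @export
flood_fill <- function(project, series, roi, seed, threshold = NULL,
                       connectivity = 4, user = NULL) {
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user)
  img <- series_image(project, series)
  d <- dim(img)
  if (any(seed < 0) || any(seed >= d))
    va_stop("validation", "seed out of bounds")
  lv <- get_label_volume(project, series)
  z <- seed[3]
  plane <- img[, , z + 1L]
  cand <- if (!is.null(threshold)) {
    plane >= threshold[1] & plane <= threshold[2]
  } else {
    !bit_test(lv$labels[, , z + 1L], def$mask_value)
  }
  if (!cand[seed[1] + 1L, seed[2] + 1L]) {
    message("flood_fill: seed outside the fillable region; nothing labelled")
    return(invisible(lv))
  }
  comp <- connected_component2(cand, c(seed[1] + 1L, seed[2] + 1L),
                               connectivity)
  snap <- labels_snapshot(lv)
  word <- lv$labels[, , z + 1L]
  word[comp] <- if (project$exclusive_mode) def$mask_value else
    bit_set(word[comp], def$mask_value)
  lv$labels[, , z + 1L] <- word
  lv <- set_provenance(lv, z, def$mask_value, "manual")
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' Dilate or erode an ROI's mask
#'
#' Binary morphology on one ROI's bit plane; other ROIs' bits are untouched.
#' Slice scope uses the in-plane 3x3 cross element on one slice; volume scope
#' uses the 3-D 6-neighbourhood on the whole grid. In exclusive mode dilation
#' refuses to grow over voxels already labelled by another ROI.
#'
#' @inheritParams flood_fill
#' @param op `"dilate"` or `"erode"`.
#' @param iterations number of elementary applications (>= 1).
#' @param scope `"slice"` (requires `slice`) or `"volume"`.
#' @param slice 0-based slice index for slice scope.
#' @return the updated label volume, invisibly.
#' @export
morph <- function(project, series, roi, op = c("dilate", "erode"),
                  iterations = 1, scope = c("slice", "volume"),
                  slice = NULL, user = NULL) {
  op <- match.arg(op); scope <- match.arg(scope)
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user)
  if (iterations < 1) va_stop("validation", "iterations must be >= 1")
  lv <- get_label_volume(project, series)
  snap <- labels_snapshot(lv)
  apply_bin <- function(mask, free) {
    for (i in seq_len(iterations)) {
      grown <- if (scope == "slice") {
        if (op == "dilate") dilate2(mask, 4) else erode2(mask, 4)
      } else {
        if (op == "dilate") dilate3(mask) else erode3(mask)
      }
      if (op == "dilate" && !is.null(free)) grown <- mask | (grown & free)
      mask <- grown
    }
    mask
  }
  if (scope == "slice") {
    if (is.null(slice)) va_stop("validation", "slice scope needs a slice")
    word <- lv$labels[, , slice + 1L]
    mask <- bit_test(word, def$mask_value)
    free <- if (project$exclusive_mode) word == 0 else NULL
    new <- apply_bin(mask, free)
    word <- bit_clear(word, def$mask_value)
    word[new] <- bit_set(word[new], def$mask_value)
    lv$labels[, , slice + 1L] <- word
    lv <- set_provenance(lv, slice, def$mask_value, "manual")
  } else {
    mask <- bit_test(lv$labels, def$mask_value)
    free <- if (project$exclusive_mode) lv$labels == 0 else NULL
    new <- apply_bin(mask, free)
    lv$labels <- bit_clear(lv$labels, def$mask_value)
    lv$labels[new] <- bit_set(lv$labels[new], def$mask_value)
    lv <- set_provenance(lv, 0:(lv$shape[3] - 1L), def$mask_value, "manual")
  }
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' Add or remove a point annotation
#'
#' Point-kind ROIs mark landmark locations (e.g. vertebral bodies). The same
#' coordinate may not be added twice for one ROI.
#'
#' @inheritParams flood_fill
#' @param coordinate 0-based `(x, y, z)` voxel coordinate.
#' @return the updated label volume, invisibly.
#' @export
add_point <- function(project, series, roi, coordinate, user = NULL) {
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user, need_kind = "point")
  lv <- get_label_volume(project, series)
  if (any(coordinate < 0) || any(coordinate >= lv$shape))
    va_stop("validation", "coordinate out of bounds")
  dup <- lv$points$mask_value == def$mask_value &
    lv$points$x == coordinate[1] & lv$points$y == coordinate[2] &
    lv$points$z == coordinate[3]
  if (any(dup))
    va_stop("validation", "duplicate point for ROI '", def$name, "' at (",
            paste(coordinate, collapse = ","), ")")
  snap <- labels_snapshot(lv)
  lv$points <- rbind(lv$points,
                     data.frame(mask_value = def$mask_value,
                                x = coordinate[1], y = coordinate[2],
                                z = coordinate[3]))
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' @rdname add_point
#' @export
remove_point <- function(project, series, roi, coordinate, user = NULL) {
  def <- roi_get(project, roi)
  check_edit_gate(project, series, def, user, need_kind = "point")
  lv <- get_label_volume(project, series)
  hit <- which(lv$points$mask_value == def$mask_value &
                 lv$points$x == coordinate[1] & lv$points$y == coordinate[2] &
                 lv$points$z == coordinate[3])
  if (!length(hit))
    va_stop("lookup", "no such point for ROI '", def$name, "'")
  snap <- labels_snapshot(lv)
  lv$points <- lv$points[-hit[1], , drop = FALSE]
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

#' Undo / redo the last edit on a series
#'
#' Restores the label grid, provenance and point list bit-exactly to the
#' prior (or re-done) state. An empty stack is a no-op notice, not an error.
#'
#' @inheritParams apply_edit
#' @return the (possibly unchanged) label volume, invisibly.
#' @export
undo <- function(project, series) {
  h <- history_of(project, series)
  lv <- get_label_volume(project, series)
  if (!length(h$undo)) {
    message("undo: nothing to undo")
    return(invisible(lv))
  }
  snap <- h$undo[[length(h$undo)]]
  h$undo <- h$undo[-length(h$undo)]
  h$redo <- c(h$redo, list(labels_snapshot(lv)))
  project$history[[series]] <- h
  lv <- labels_restore(lv, snap)
  set_label_volume(project, series, lv)
  invisible(lv)
}

#' @rdname undo
#' @export
redo <- function(project, series) {
  h <- history_of(project, series)
  lv <- get_label_volume(project, series)
  if (!length(h$redo)) {
    message("redo: nothing to redo")
    return(invisible(lv))
  }
  snap <- h$redo[[length(h$redo)]]
  h$redo <- h$redo[-length(h$redo)]
  h$undo <- c(h$undo, list(labels_snapshot(lv)))
  project$history[[series]] <- h
  lv <- labels_restore(lv, snap)
  set_label_volume(project, series, lv)
  invisible(lv)
}
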