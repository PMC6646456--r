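# A project is the dataset-level unit: it owns the annotation schema (ROI
# table, text fields), the series list, custody/workflow state, per-series
# label volumes, edit histories and version logs. Mutable state is kept in an
# environment so that editing operators behave like the stateful engine they
# model; accessors return plain values.

#' Create an annotation project
#'
#' A project defines voxel and text annotation schemas at the dataset level so
#' that every series in the dataset is annotated against the same definitions.
#' ROI mask values are distinct powers of two assigned by the project and
#' never recycled, so label grids written as the bitwise OR of overlapping
#' ROIs can always be decoded.
#'
#' @param exclusive_mode logical; when `TRUE` the project enforces one ROI per
#'   voxel (painting replaces any existing label instead of adding a bit).
#' @param annotation_store optional directory in which annotation metadata is
#'   persisted, independent of the imaging files.
#' @return an object of class `voxann_project` (environment semantics: the
#'   editing verbs mutate it in place and return values invisibly).
#' @examples
#' p <- project_create()
#' define_roi(p, "kidney", radlex_id = "RID205", color = c(255, 0, 0))
#' define_roi(p, "tumor", color = c(0, 255, 0))
#' roi_table(p)
#' @export
project_create <- function(exclusive_mode = FALSE, annotation_store = NULL) {
  p <- new.env(parent = emptyenv())
  p$rois <- list()
  p$text_fields <- list()
  p$series <- list()
  p$annotations <- list()     # series_id -> label_volume
  p$images <- list()          # series_id -> cached image array
  p$affines <- list()         # series_id -> 4x4 voxel-to-world
  p$history <- list()         # series_id -> edit history (undo/redo stacks)
  p$versions <- list()        # series_id -> list of version entries
  p$custody <- list()         # series_id -> custody record
  p$extra_metadata <- NULL
  p$workflow <- NULL
  p$exclusive_mode <- isTRUE(exclusive_mode)
  p$annotation_store <- annotation_store
  p$next_bit <- 0L            # lowest never-used bit exponent (not recycled)
  class(p) <- "voxann_project"
  p
}

#' @export
print.voxann_project <- function(x, ...) {
  cat("voxann project:",
      length(x$rois), "ROI(s),",
      length(x$text_fields), "text field(s),",
      length(x$series), "series",
      if (x$exclusive_mode) "[exclusive: one ROI per voxel]" else "", "\n")
  invisible(x)
}

# ---- ROI schema --------------------------------------------------------------

#' Define a region-of-interest schema entry
#'
#' Adds an ROI definition to the project's dataset-level schema. The project
#' assigns the lowest unused power-of-two mask value; mask values are never
#' recycled, even after deletion, so stale bits in old exports can never be
#' re-interpreted as a different ROI.
#'
#' @param project a `voxann_project`.
#' @param name ROI name, unique (case-sensitive) within the project.
#' @param radlex_id optional RadLex lexicon identifier.
#' @param color RGB triple, each component in 0..255.
#' @param kind `"area"` (multi-voxel mask) or `"point"` (point landmarks).
#' @return the new ROI definition (a list with `name`, `radlex_id`, `color`,
#'   `mask_value`, `kind`, `locked`), invisibly.
#' @export
define_roi <- function(project, name, radlex_id = NULL,
                       color = c(255L, 0L, 0L), kind = c("area", "point")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (name %in% names(project$rois))
    va_stop("schema", "ROI name already defined: '", name, "'")
  if (project$next_bit > VOXANN_MAX_BIT_EXP)
    va_stop("capacity", "ROI bit budget exhausted: at most ",
            VOXANN_MAX_BIT_EXP + 1L,
            " ROIs can share one export word; export in multiple files")
  color <- as.integer(color)
  if (length(color) != 3 || any(is.na(color)) || any(color < 0 | color > 255))
    va_stop("schema", "color must be an RGB triple in 0..255")
  roi <- list(name = name, radlex_id = radlex_id, color = color,
              mask_value = 2^project$next_bit, kind = kind, locked = FALSE)
  project$next_bit <- project$next_bit + 1L
  project$rois[[name]] <- roi
  invisible(roi)
}

roi_get <- function(project, roi) {
  if (is.list(roi) && !is.null(roi$mask_value)) roi <- roi$name
  out <- project$rois[[roi]]
  if (is.null(out)) va_stop("lookup", "unknown ROI: '", roi, "'")
  out
}

#' Lock or unlock an ROI
#'
#' A locked ROI rejects all modification: manual painting, semi-automated
#' refinement and model-driven annotation alike.
#'
#' @inheritParams define_roi
#' @param roi ROI name or definition.
#' @param locked logical flag.
#' @return the updated definition, invisibly.
#' @export
set_roi_locked <- function(project, roi, locked = TRUE) {
  def <- roi_get(project, roi)
  def$locked <- isTRUE(locked)
  project$rois[[def$name]] <- def
  invisible(def)
}

#' Edit an ROI's display properties
#'
#' Name, RadLex ID and color can be changed freely: the mask value is fixed at
#' definition time, so renaming never touches stored label grids.
#'
#' @inheritParams set_roi_locked
#' @param name,radlex_id,color new values; `NULL` leaves a field unchanged.
#' @return the updated definition, invisibly.
#' @export
edit_roi <- function(project, roi, name = NULL, radlex_id = NULL,
                     color = NULL) {
  def <- roi_get(project, roi)
  if (!is.null(name) && !identical(name, def$name)) {
    if (name %in% names(project$rois))
      va_stop("schema", "ROI name already defined: '", name, "'")
    project$rois[[def$name]] <- NULL
    def$name <- name
  }
  if (!is.null(radlex_id)) def$radlex_id <- radlex_id
  if (!is.null(color)) {
    color <- as.integer(color)
    if (length(color) != 3 || any(color < 0 | color > 255))
      va_stop("schema", "color must be an RGB triple in 0..255")
    def$color <- color
  }
  project$rois[[def$name]] <- def
  invisible(def)
}

#' Delete an ROI definition
#'
#' Refuses by default when the ROI still labels voxels or points anywhere in
#' the project; `force = TRUE` clears those labels first. The retired mask
#' value is never reassigned.
#'
#' @inheritParams set_roi_locked
#' @param force logical; clear existing labels instead of refusing.
#' @export
delete_roi <- function(project, roi, force = FALSE) {
  def <- roi_get(project, roi)
  used <- vapply(project$annotations, function(lv) {
    any(bit_test(lv$labels, def$mask_value)) ||
      any(lv$points$mask_value == def$mask_value)
  }, logical(1))
  if (any(used) && !isTRUE(force))
    va_stop("schema", "ROI '", def$name, "' still labels voxels in ",
            sum(used), " series; use force = TRUE to clear them")
  if (any(used)) {
    for (sid in names(project$annotations)[used]) {
      lv <- project$annotations[[sid]]
      lv$labels <- bit_clear(lv$labels, def$mask_value)
      lv$points <- lv$points[lv$points$mask_value != def$mask_value, ,
                             drop = FALSE]
      lv$provenance <- lv$provenance[prov_bits(names(lv$provenance)) !=
                                       def$mask_value]
      project$annotations[[sid]] <- lv
    }
  }
  project$rois[[def$name]] <- NULL
  invisible(project)
}

#' ROI schema table
#'
#' @inheritParams define_roi
#' @return data frame with one row per defined ROI.
#' @export
roi_table <- function(project) {
  if (!length(project$rois))
    return(data.frame(name = character(), radlex_id = character(),
                      mask_value = numeric(), kind = character(),
                      locked = logical()))
  data.frame(
    name = vapply(project$rois, `[[`, "", "name"),
    radlex_id = vapply(project$rois,
                       function(r) r$radlex_id %||% NA_character_, ""),
    mask_value = vapply(project$rois, `[[`, 0, "mask_value"),
    kind = vapply(project$rois, `[[`, "", "kind"),
    locked = vapply(project$rois, `[[`, TRUE, "locked"),
    row.names = NULL
  )
}

# ---- Text annotation schema --------------------------------------------------

#' Define a text annotation field
#'
#' Text fields capture location-independent observations per series (image
#' quality, contrast phase, comments). When `allowed_values` is given the
#' field is restricted to that set, standardising annotations across the
#' dataset; otherwise it is free text.
#'
#' @inheritParams define_roi
#' @param name field name, unique within the project.
#' @param allowed_values optional character vector of permitted values.
#' @export
define_text_field <- function(project, name, allowed_values = NULL) {
  if (name %in% names(project$text_fields))
    va_stop("schema", "text field already defined: '", name, "'")
  project$text_fields[[name]] <-
    list(name = name, allowed_values = allowed_values)
  invisible(project$text_fields[[name]])
}

#' Set a text annotation value on a series
#'
#' @inheritParams define_roi
#' @param series series identifier.
#' @param field defined text field name.
#' @param value the value; must belong to the field's allowed set when one is
#'   defined.
#' @return the updated series record, invisibly.
#' @export
set_text_value <- function(project, series, field, value) {
  rec <- series_get(project, series)
  fdef <- project$text_fields[[field]]
  if (is.null(fdef)) va_stop("lookup", "unknown text field: '", field, "'")
  if (!is.null(fdef$allowed_values) && !(value %in% fdef$allowed_values))
    va_stop("validation", "value '", value, "' not in the allowed set for '",
            field, "': ", paste(fdef$allowed_values, collapse = ", "))
  rec$text_values[[field]] <- as.character(value)
  project$series[[rec$series_id]] <- rec
  invisible(rec)
}

# ---- Series ------------------------------------------------------------------

#' Register an imaging series with a project
#'
#' A series is one acquisition volume. It may reference a NIfTI file on disk
#' (`source_path`) or carry an in-memory array (`image` + `affine`), which the
#' synthetic fixtures use. The source file is never modified by any
#' annotation operation.
#'
#' @inheritParams define_roi
#' @param series_id unique identifier.
#' @param source_path optional path to a 3-D NIfTI volume.
#' @param hierarchy_key ordered labels (e.g. patient/study/series) mirrored in
#'   exports; defaults to the series id.
#' @param image,affine in-memory alternative to `source_path`.
#' @return the series record, invisibly.
#' @export
add_series <- function(project, series_id, source_path = NULL,
                       hierarchy_key = NULL, image = NULL, affine = NULL) {
  if (series_id %in% names(project$series))
    va_stop("schema", "series already registered: '", series_id, "'")
  if (is.null(source_path) && is.null(image))
    va_stop("validation", "a series needs either source_path or image")
  rec <- list(series_id = series_id, source_path = source_path,
              hierarchy_key = hierarchy_key %||% series_id,
              text_values = list())
  project$series[[series_id]] <- rec
  if (!is.null(image)) {
    project$images[[series_id]] <- image
    project$affines[[series_id]] <- affine %||% diag(4)
  }
  # unannotated series start in the workflow's initial pool
  pool <- if (!is.null(project$workflow)) project$workflow$initial_pool
  project$custody[[series_id]] <- list(series_id = series_id, pool = pool,
                                       owner = NULL, locked = FALSE)
  invisible(rec)
}

series_get <- function(project, series) {
  rec <- project$series[[series]]
  if (is.null(rec)) va_stop("lookup", "unknown series: '", series, "'")
  rec
}

#' Image data and affine of a series
#'
#' Loads (and caches) the source NIfTI for file-backed series; in-memory
#' series return their array directly.
#'
#' @inheritParams set_text_value
#' @return `series_image`: the 3-D intensity array; `series_affine`: the 4x4
#'   voxel-to-world transform.
#' @export
series_image <- function(project, series) {
  rec <- series_get(project, series)
  img <- project$images[[series]]
  if (is.null(img)) {
    vol <- load_volume(rec$source_path)
    project$images[[series]] <- vol$data
    project$affines[[series]] <- vol$affine
    img <- vol$data
  }
  img
}

#' @rdname series_image
#' @export
series_affine <- function(project, series) {
  series_image(project, series)  # ensure cached
  project$affines[[series]]
}

#' Label volume of a series
#'
#' Created lazily (all-zero, affine copied from the source) on first access.
#'
#' @inheritParams set_text_value
#' @return a `voxann_labels` object.
#' @export
get_label_volume <- function(project, series) {
  lv <- project$annotations[[series]]
  if (is.null(lv)) {
    img <- series_image(project, series)
    lv <- label_volume(dim(img), project$affines[[series]])
    project$annotations[[series]] <- lv
  }
  lv
}

set_label_volume <- function(project, series, lv) {
  project$annotations[[series]] <- lv
  invisible(lv)
}

series_edited <- function(project, series) {
  lv <- project$annotations[[series]]
  nonempty_now <- !is.null(lv) && labels_nonempty(lv)
  nonempty_ever <- any(vapply(project$versions[[series]] %||% list(),
                              function(v) v$nonempty, logical(1)))
  nonempty_now || nonempty_ever
}

#' Tabulate the project's series
#'
#' One row per series in registration (hierarchy) order, with the edited flag
#' (true iff the series carries any annotation content) and any requested
#' text-annotation or attached-metadata columns.
#'
#' @inheritParams define_roi
#' @param columns character vector of text field names and/or attached
#'   metadata column names to include.
#' @return a data frame.
#' @export
list_series <- function(project, columns = character()) {
  meta_cols <- setdiff(colnames(project$extra_metadata %||% data.frame()),
                       "series_id")
  bad <- setdiff(columns, c(names(project$text_fields), meta_cols))
  if (length(bad))
    va_stop("lookup", "unknown column(s): ", paste(bad, collapse = ", "))
  ids <- names(project$series)
  out <- data.frame(series_id = ids %||% character(),
                    edited = vapply(ids, function(s) series_edited(project, s),
                                    logical(1), USE.NAMES = FALSE),
                    row.names = NULL)
  for (col in columns) {
    if (col %in% names(project$text_fields)) {
      out[[col]] <- vapply(ids, function(s) {
        project$series[[s]]$text_values[[col]] %||% ""
      }, "", USE.NAMES = FALSE)
    } else {
      md <- project$extra_metadata
      out[[col]] <- md[[col]][match(ids, md$series_id)]
    }
  }
  out
}

#' Toggle one-ROI-per-voxel enforcement
#'
#' Turning exclusive mode on is rejected while any voxel holds more than one
#' label, so no data is silently lost.
#'
#' @inheritParams define_roi
#' @param flag logical.
#' @export
set_exclusive_mode <- function(project, flag) {
  if (isTRUE(flag)) {
    for (sid in names(project$annotations)) {
      if (any(bit_popcount(project$annotations[[sid]]$labels) > 1))
        va_stop("validation", "cannot enable exclusive mode: series '", sid,
                "' has voxels with multiple labels")
    }
  }
  project$exclusive_mode <- isTRUE(flag)
  invisible(project)
}
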