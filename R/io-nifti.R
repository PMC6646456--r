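# Volume loading and mask import/export. Source imaging is read-only: no
# operation in the package ever writes to a series' source path. Exported
# masks are NIfTI volumes whose affine equals the source affine exactly, and
# are written in a directory hierarchy mirroring the source dataset, next to
# a sidecar CSV mapping mask values to ROI names and RadLex IDs.

#' Load a 3-D NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a list with `data` (3-D array), `affine` (4x4 voxel-to-world),
#'   and `header` (the `niftiImage`, kept as the reference for exports).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) va_stop("io", "no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) va_stop("io", "unreadable NIfTI: ",
                                              path, " (", conditionMessage(e),
                                              ")"))
  d <- dim(img)
  if (length(d) != 3)
    va_stop("shape", "expected a 3-D volume, got ", length(d), " dimensions")
  list(data = array(as.numeric(img), dim = d),
       affine = structure(RNifti::xform(img), code = NULL),
       header = img)
}

# Build a niftiImage for `arr` carrying `affine` (or copying the full header
# of a reference image when one is available).
make_nifti <- function(arr, affine, reference = NULL) {
  if (!is.null(reference)) return(RNifti::asNifti(arr, reference = reference))
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

mask_datatype <- function(max_value) {
  if (max_value < 2^8) "uint8"
  else if (max_value < 2^15) "int16"
  else if (max_value < 2^31) "int32"
  else "double"
}

series_dest_dir <- function(root, rec) {
  do.call(file.path, as.list(c(root, rec$hierarchy_key)))
}

#' Export a series' voxel annotations as binary masks
#'
#' With `combine_overlaps` the single exported volume holds, at each voxel,
#' the bitwise OR of the mask values of all ROIs labelling it; otherwise one
#' binary file per ROI is written with values {0, mask_value}. A sidecar CSV
#' (`roi_name,radlex_id,mask_value`) decodes the mask values. Files land in
#' a hierarchy mirroring the source dataset under `destination_root`.
#'
#' @inheritParams apply_edit
#' @param destination_root output directory.
#' @param combine_overlaps logical; single combined file vs one per ROI.
#' @param include_source_copy copy the source NIfTI next to the masks.
#' @param include_annotation_file also write the package's own annotation
#'   container (YAML header + compressed label grid).
#' @return invisibly, a list with `files` (written mask paths), `sidecar`
#'   (CSV path) and `mapping` (the sidecar data frame).
#' @export
export_masks <- function(project, series, destination_root,
                         combine_overlaps = TRUE,
                         include_source_copy = FALSE,
                         include_annotation_file = FALSE) {
  rec <- series_get(project, series)
  lv <- project$annotations[[series]]
  if (is.null(lv) || !labels_nonempty(lv))
    va_stop("precondition", "series '", series, "' has no annotations")
  dir <- series_dest_dir(destination_root, rec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series_image(project, series)   # ensure header cache for file-backed series
  ref <- if (!is.null(rec$source_path)) RNifti::readNifti(rec$source_path)
  present <- bits_present(lv$labels)
  tab <- roi_table(project)
  tab <- tab[tab$kind == "area" & tab$mask_value %in% present, , drop = FALSE]
  files <- character(0)
  if (combine_overlaps) {
    f <- file.path(dir, paste0(series, "_mask.nii.gz"))
    img <- make_nifti(lv$labels, lv$affine, ref)
    RNifti::writeNifti(img, f, datatype = mask_datatype(max(lv$labels)))
    files <- f
  } else {
    for (i in seq_len(nrow(tab))) {
      mv <- tab$mask_value[i]
      arr <- array(0, dim = lv$shape)
      arr[bit_test(lv$labels, mv)] <- mv
      f <- file.path(dir, paste0(series, "_", tab$name[i], "_mask.nii.gz"))
      img <- make_nifti(arr, lv$affine, ref)
      RNifti::writeNifti(img, f, datatype = mask_datatype(mv))
      files <- c(files, f)
    }
  }
  mapping <- data.frame(roi_name = tab$name,
                        radlex_id = ifelse(is.na(tab$radlex_id), "",
                                           tab$radlex_id),
                        mask_value = tab$mask_value)
  sidecar <- file.path(dir, paste0(series, "_mask_labels.csv"))
  utils::write.csv(mapping, sidecar, row.names = FALSE)
  if (include_source_copy && !is.null(rec$source_path))
    file.copy(rec$source_path, file.path(dir, basename(rec$source_path)),
              overwrite = TRUE)
  if (include_annotation_file)
    write_annotation_container(project, series, dir)
  invisible(list(files = files, sidecar = sidecar, mapping = mapping))
}

#' Import voxel annotations from a binary mask
#'
#' Decodes a mask volume against a `roi_name`/`mask_value` mapping (the
#' sidecar CSV of [export_masks()], or any data frame with those columns)
#' into the series' label volume. Importing an export reproduces the label
#' grid bit-exactly. All imported (slice, ROI) provenance is manual.
#'
#' @inheritParams apply_edit
#' @param path mask NIfTI file.
#' @param mapping data frame or CSV path with columns `roi_name`,
#'   `mask_value`.
#' @return the updated label volume, invisibly.
#' @export
import_masks <- function(project, series, path, mapping) {
  if (is.character(mapping))
    mapping <- utils::read.csv(mapping, stringsAsFactors = FALSE)
  if (!all(c("roi_name", "mask_value") %in% names(mapping)))
    va_stop("validation", "mapping needs roi_name and mask_value columns")
  vol <- load_volume(path)
  img <- series_image(project, series)
  if (!identical(dim(vol$data), dim(img)))
    va_stop("shape", "mask shape does not match the series volume")
  file_bits <- bits_present(vol$data)
  unknown <- setdiff(file_bits, mapping$mask_value)
  if (length(unknown))
    va_stop("unknown_label", "mask contains value bit(s) absent from the ",
            "mapping: ", paste(unknown, collapse = ", "))
  lv <- get_label_volume(project, series)
  for (mv in file_bits) {
    nm <- mapping$roi_name[mapping$mask_value == mv][1]
    def <- project$rois[[nm]]
    if (is.null(def))
      va_stop("lookup", "mask value ", mv, " maps to ROI '", nm,
              "' which is not defined in the project")
    sel <- bit_test(vol$data, mv)
    lv$labels[sel] <- bit_set(lv$labels[sel], def$mask_value)
    zs <- unique(which(sel, arr.ind = TRUE)[, 3]) - 1L
    lv <- set_provenance(lv, zs, def$mask_value, "manual")
  }
  set_label_volume(project, series, lv)
  invisible(lv)
}

# The package's own annotation container: a YAML header plus a compressed
# label-grid blob, stored independently of the imaging.
write_annotation_container <- function(project, series, dir) {
  lv <- get_label_volume(project, series)
  rec <- series_get(project, series)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blob <- file.path(dir, "labels.rds.gz")
  saveRDS(lv$labels, blob, compress = "gzip")
  header <- list(
    series_id = rec$series_id,
    shape = as.integer(lv$shape),
    affine = as.numeric(lv$affine),
    provenance = as.list(lv$provenance),
    points = lapply(seq_len(nrow(lv$points)), function(i)
      as.list(lv$points[i, ])),
    text_values = rec$text_values,
    label_blob = basename(blob)
  )
  yaml::write_yaml(header, file.path(dir, "annotations.yaml"))
  invisible(dir)
}

read_annotation_container <- function(dir) {
  header <- yaml::read_yaml(file.path(dir, "annotations.yaml"))
  labels <- readRDS(file.path(dir, header$label_blob))
  lv <- label_volume(header$shape,
                     matrix(header$affine, 4, 4))
  lv$labels <- labels
  lv$provenance <- unlist(header$provenance) %||% character(0)
  if (length(header$points)) {
    lv$points <- do.call(rbind, lapply(header$points, as.data.frame))
  }
  list(label_volume = lv, text_values = header$text_values,
       series_id = header$series_id)
}
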