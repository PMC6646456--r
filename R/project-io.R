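# Project persistence: a YAML descriptor holding the schema (ROI table, text
# fields, exclusive mode, annotation store, optional embedded workflow) and,
# under the annotation store, one container per annotated series (YAML header
# + compressed label grid) in a hierarchy mirroring the dataset. Imaging is
# referenced, never copied or touched.

#' Save / load a project
#'
#' `project_save` writes the project descriptor YAML and, when the project
#' has an annotation store, every series' annotation container and version-
#' independent state. `project_load` reconstructs the project; series images
#' are re-read lazily from their source paths.
#'
#' @param project a `voxann_project`.
#' @param path descriptor file path (`.yaml`).
#' @return `project_save`: the path, invisibly; `project_load`: the project.
#' @export
project_save <- function(project, path) {
  desc <- list(
    exclusive_mode = project$exclusive_mode,
    annotation_store = project$annotation_store,
    next_bit = project$next_bit,
    rois = lapply(unname(project$rois), function(r)
      list(name = r$name, radlex_id = r$radlex_id, color = as.integer(r$color),
           mask_value = r$mask_value, kind = r$kind, locked = r$locked)),
    text_fields = lapply(unname(project$text_fields), function(f)
      list(name = f$name, allowed_values = f$allowed_values)),
    series = lapply(unname(project$series), function(s)
      list(series_id = s$series_id, source_path = s$source_path,
           hierarchy_key = s$hierarchy_key, text_values = s$text_values)),
    workflow = if (!is.null(project$workflow)) unclass(project$workflow),
    custody = lapply(unname(project$custody), function(c)
      list(series_id = c$series_id, pool = c$pool, owner = c$owner,
           locked = c$locked))
  )
  yaml::write_yaml(desc, path)
  if (!is.null(project$annotation_store)) {
    for (sid in names(project$annotations)) {
      rec <- project$series[[sid]]
      dir <- series_dest_dir(project$annotation_store, rec)
      write_annotation_container(project, sid, dir)
      vs <- project$versions[[sid]]
      if (!is.null(vs)) saveRDS(vs, file.path(dir, "versions.rds"),
                                compress = "gzip")
    }
  }
  invisible(path)
}

#' @rdname project_save
#' @export
project_load <- function(path) {
  desc <- yaml::read_yaml(path)
  p <- project_create(exclusive_mode = isTRUE(desc$exclusive_mode),
                      annotation_store = desc$annotation_store)
  for (r in desc$rois) {
    p$rois[[r$name]] <- list(name = r$name, radlex_id = r$radlex_id,
                             color = as.integer(unlist(r$color)),
                             mask_value = as.numeric(r$mask_value),
                             kind = r$kind, locked = isTRUE(r$locked))
  }
  p$next_bit <- as.integer(desc$next_bit %||% length(desc$rois))
  for (f in desc$text_fields)
    p$text_fields[[f$name]] <- list(name = f$name,
                                    allowed_values =
                                      unlist(f$allowed_values))
  if (!is.null(desc$workflow))
    p$workflow <- structure(desc$workflow, class = "voxann_workflow")
  for (s in desc$series) {
    p$series[[s$series_id]] <-
      list(series_id = s$series_id, source_path = s$source_path,
           hierarchy_key = unlist(s$hierarchy_key),
           text_values = s$text_values %||% list())
    p$custody[[s$series_id]] <- list(series_id = s$series_id,
                                     pool = NULL, owner = NULL,
                                     locked = FALSE)
  }
  for (c in desc$custody %||% list()) {
    p$custody[[c$series_id]] <- list(series_id = c$series_id,
                                     pool = c$pool, owner = c$owner,
                                     locked = isTRUE(c$locked))
  }
  if (!is.null(p$annotation_store)) {
    for (sid in names(p$series)) {
      dir <- series_dest_dir(p$annotation_store, p$series[[sid]])
      if (file.exists(file.path(dir, "annotations.yaml"))) {
        cont <- read_annotation_container(dir)
        p$annotations[[sid]] <- cont$label_volume
      }
      vfile <- file.path(dir, "versions.rds")
      if (file.exists(vfile)) p$versions[[sid]] <- readRDS(vfile)
    }
  }
  p
}
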