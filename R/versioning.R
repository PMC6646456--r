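# Append-only per-series version log. A commit snapshots the full annotation
# state (labels, points, provenance, text values); rollback restores a past
# snapshot as a *new* version, so history is never rewritten. Snapshots are
# content-addressed with a SHA-1 so identical states are recognisable.

#' Commit a version of a series' annotations
#'
#' @inheritParams apply_edit
#' @param user author of the version.
#' @param note free-text note.
#' @return the new version entry, invisibly.
#' @export
commit_version <- function(project, series, user, note = "") {
  rec <- series_get(project, series)
  lv <- get_label_volume(project, series)
  snap <- labels_snapshot(lv)
  snap$text_values <- rec$text_values
  entries <- project$versions[[series]] %||% list()
  entry <- list(
    version_id = length(entries) + 1L,
    user = user,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    note = note,
    checksum = digest::digest(snap, algo = "sha1"),
    nonempty = labels_nonempty(lv) || length(rec$text_values) > 0,
    snapshot = snap
  )
  project$versions[[series]] <- c(entries, list(entry))
  invisible(entry)
}

#' Version history of a series
#'
#' @inheritParams apply_edit
#' @return data frame of version_id, user, timestamp, note, checksum in
#'   increasing version order.
#' @export
version_history <- function(project, series) {
  series_get(project, series)
  entries <- project$versions[[series]] %||% list()
  data.frame(
    version_id = vapply(entries, `[[`, 0L, "version_id"),
    user = vapply(entries, `[[`, "", "user"),
    timestamp = vapply(entries, `[[`, "", "timestamp"),
    note = vapply(entries, `[[`, "", "note"),
    checksum = vapply(entries, `[[`, "", "checksum"),
    row.names = NULL
  )
}

#' Roll a series back to a previous version
#'
#' The target snapshot is restored and committed as a new version; no history
#' entry is ever deleted.
#'
#' @inheritParams commit_version
#' @param version_id the version to restore.
#' @return the new version entry, invisibly.
#' @export
rollback_version <- function(project, series, version_id, user = "system") {
  entries <- project$versions[[series]] %||% list()
  ids <- vapply(entries, `[[`, 0L, "version_id")
  hit <- which(ids == version_id)
  if (!length(hit))
    va_stop("lookup", "no version ", version_id, " for series '", series, "'")
  snap <- entries[[hit]]$snapshot
  lv <- get_label_volume(project, series)
  lv <- labels_restore(lv, snap)
  set_label_volume(project, series, lv)
  rec <- project$series[[series]]
  rec$text_values <- snap$text_values %||% list()
  project$series[[series]] <- rec
  commit_version(project, series, user,
                 note = paste0("rollback to v", version_id))
}
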