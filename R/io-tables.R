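# Tabular exports (per-ROI descriptive statistics, per-series text
# annotations) as CSV or XLSX, and attachment of secondary per-series
# metadata from a CSV. The XLSX writer below emits a minimal Office Open XML
# workbook (stored-entry ZIP, inline strings) so spreadsheet export needs no
# external tooling.

#' Export project tables
#'
#' `what = "stats"` writes one row per (series, area ROI) with the volume-
#' scope descriptive statistics; `what = "text"` one row per series with one
#' column per defined text field.
#'
#' @inheritParams define_roi
#' @param what `"stats"` or `"text"`.
#' @param path output file.
#' @param format `"csv"` or `"xlsx"` (default follows the file extension).
#' @return the exported data frame, invisibly.
#' @export
export_tables <- function(project, what = c("stats", "text"), path,
                          format = NULL) {
  what <- match.arg(what)
  if (!length(project$series)) va_stop("precondition", "project has no series")
  format <- format %||%
    (if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv")
  if (what == "stats") {
    tab <- roi_table(project)
    tab <- tab[tab$kind == "area", , drop = FALSE]
    rows <- list()
    for (sid in names(project$series)) {
      for (i in seq_len(nrow(tab))) {
        st <- roi_statistics(project, sid, tab$name[i], scope = "volume")
        rows[[length(rows) + 1L]] <- data.frame(
          series_id = sid, roi = tab$name[i], voxel_count = st$voxel_count,
          physical_volume = st$physical_volume,
          mean = st$mean %||% NA_real_, std = st$std, min = st$min,
          max = st$max)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(series_id = character(), roi = character())
  } else {
    df <- list_series(project, columns = names(project$text_fields))
  }
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else write_minimal_xlsx(df, path)
  invisible(df)
}

#' Attach secondary per-series metadata from a CSV
#'
#' NIfTI carries little of the metadata a DICOM series would; a secondary CSV
#' keyed by `series_id` supplies it. Matched columns become read-only columns
#' available to [list_series()].
#'
#' @inheritParams define_roi
#' @param csv_path CSV file with a `series_id` column.
#' @return invisibly, a list with `matched` and `unmatched` series ids.
#' @export
attach_metadata_csv <- function(project, csv_path) {
  md <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(md) == 0) {
    va_warn("io", "metadata CSV is empty; nothing attached")
    return(invisible(list(matched = character(), unmatched = character())))
  }
  if (!"series_id" %in% names(md))
    va_stop("validation", "metadata CSV lacks a series_id column")
  dup <- md$series_id[duplicated(md$series_id)]
  if (length(dup))
    va_stop("validation", "duplicate series_id in metadata CSV: ",
            paste(unique(dup), collapse = ", "))
  known <- md$series_id %in% names(project$series)
  project$extra_metadata <- md[known, , drop = FALSE]
  invisible(list(matched = md$series_id[known],
                 unmatched = md$series_id[!known]))
}

# ---- minimal XLSX writer -----------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_sheet_xml <- function(df) {
  col_letter <- function(j) {
    s <- ""
    while (j > 0) { r <- (j - 1) %% 26; s <- paste0(LETTERS[r + 1], s)
      j <- (j - 1) %/% 26 }
    s
  }
  cell <- function(v, r, j) {
    ref <- paste0(col_letter(j), r)
    if (is.numeric(v) && !is.na(v))
      sprintf('<c r="%s"><v>%s</v></c>', ref,
              format(v, digits = 15, scientific = FALSE))
    else if (is.na(v)) sprintf('<c r="%s"/>', ref)
    else sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                 xml_escape(as.character(v)))
  }
  rows <- character(nrow(df) + 1L)
  rows[1] <- paste0('<row r="1">',
                    paste0(mapply(cell, names(df), 1L, seq_along(df)),
                           collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    rows[i + 1L] <- paste0(sprintf('<row r="%d">', i + 1L),
                           paste0(mapply(function(j) cell(df[i, j], i + 1L, j),
                                         seq_along(df)), collapse = ""),
                           "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste0(rows, collapse = ""), "</sheetData></worksheet>")
}

# Stored-entry (uncompressed) ZIP container; CRC-32 via digest.
zip_store <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- character(length(entries))
  sizes <- integer(length(entries))
  pos <- 0L
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) {   # accepts unsigned 32-bit values given as doubles
    x <- as.numeric(x)
    if (x > 2^31 - 1) x <- x - 2^32
    writeBin(as.integer(x), con, size = 4, endian = "little")
  }
  hex32 <- function(h) as.numeric(paste0("0x", h))
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- charToRaw(entries[[i]])
    crc <- digest::digest(data, algo = "crc32", serialize = FALSE)
    offsets[i] <- pos; crcs[i] <- crc; sizes[i] <- length(data)
    w32(0x04034b50); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(hex32(crc)); w32(length(data)); w32(length(data))
    w16(nchar(nm)); w16(0)
    writeBin(charToRaw(nm), con)
    writeBin(data, con)
    pos <- pos + 30L + nchar(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    w32(0x02014b50); w16(20); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(hex32(crcs[i])); w32(sizes[i]); w32(sizes[i])
    w16(nchar(nm)); w16(0); w16(0); w16(0); w16(0); w32(0); w32(offsets[i])
    writeBin(charToRaw(nm), con)
    pos <- pos + 46L + nchar(nm)
  }
  w32(0x06054b50); w16(0); w16(0); w16(length(entries)); w16(length(entries))
  w32(pos - cd_start); w32(cd_start); w16(0)
  invisible(path)
}

# Read one stored entry back out of a ZIP written by zip_store (used to
# verify workbook contents without a spreadsheet reader).
unzip_entry <- function(path, entry) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  repeat {
    sig <- r32()
    if (length(sig) == 0 || sig != 0x04034b50) break
    r16(); r16(); r16(); r16(); r16(); r32()
    csize <- r32(); r32()
    nlen <- r16(); elen <- r16()
    nm <- rawToChar(readBin(con, "raw", nlen))
    if (elen > 0) readBin(con, "raw", elen)
    data <- readBin(con, "raw", csize)
    if (nm == entry) return(data)
  }
  va_stop("lookup", "no such zip entry: ", entry)
}

write_minimal_xlsx <- function(df, path) {
  ns <- "http://schemas.openxmlformats.org/"
  entries <- list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="', ns, 'package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.',
      'openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.',
      'openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.',
      'worksheet+xml"/></Types>'),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="', ns, 'package/2006/relationships">',
      '<Relationship Id="rId1" Type="', ns, 'officeDocument/2006/',
      'relationships/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="', ns, 'spreadsheetml/2006/main" xmlns:r="', ns,
      'officeDocument/2006/relationships"><sheets>',
      '<sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="', ns, 'package/2006/relationships">',
      '<Relationship Id="rId1" Type="', ns, 'officeDocument/2006/',
      'relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      '</Relationships>'),
    "xl/worksheets/sheet1.xml" = xlsx_sheet_xml(df)
  )
  zip_store(path, entries)
}
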