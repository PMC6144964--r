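#' Read an otolith measurement table
#'
#' Reads the canonical wide format: one row per fish x zone, metadata
#' columns then one column per element. Column names can be remapped via
#' `schema` for instrument exports that use different headers. A long
#' format (one row per fish x zone x element, with `element` and `value`
#' columns) is accepted with `format = "long"`.
#'
#' Rows violating the typed invariants (non-numeric or non-positive element
#' values, unknown zones, missing required fields) are rejected with
#' row-indexed diagnostics rather than silently dropped.
#'
#' @param path path to a delimited text file with a header row.
#' @param elements character vector of element columns; defaults to the
#'   four-element panel Mg, Mn, Sr, Ba.
#' @param units measurement units recorded on the panel.
#' @param schema optional named character vector mapping canonical names to
#'   file column names, e.g. `c(site = "station")`.
#' @param delim field delimiter, default comma.
#' @param format `"wide"` (default) or `"long"`.
#' @param provenance free-text source note; defaults to the file path.
#' @return an `otolith_dataset`.
#' @export
read_measurements <- function(path, elements = c("Mg", "Mn", "Sr", "Ba"),
                              units = "ratio_to_ca", schema = NULL,
                              delim = ",", format = c("wide", "long"),
                              provenance = NULL) {
  format <- match.arg(format)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema column '", src, "' not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  meta <- c("fish_id", "life_stage", "zone", "site", "lat", "lon",
            "year_class", "batch")
  if (format == "long") {
    need <- c(meta, "element", "value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop("missing columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    wide <- stats::reshape(
      raw[, need], direction = "wide", idvar = meta,
      timevar = "element", v.names = "value")
    names(wide) <- sub("^value\\.", "", names(wide))
    raw <- wide
  }
  missing_cols <- setdiff(c(meta, elements), names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (el in elements) {
    v <- suppressWarnings(as.numeric(raw[[el]]))
    bad <- which(is.na(v) & !is.na(raw[[el]]))
    if (length(bad))
      stop("non-numeric values for ", el, " in rows ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    raw[[el]] <- v
  }
  otolith_dataset(raw, element_panel(elements, units = units),
                  provenance = provenance %||% path)
}

#' Write an otolith measurement table
#'
#' Writes the canonical wide CSV (UTF-8, `.` decimal separator). A dataset
#' written and read back reproduces every record up to float round-off.
#'
#' @param ds an `otolith_dataset`.
#' @param path output file path.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(ds, path, delim = ",") {
  utils::write.table(as.data.frame(ds), path, sep = delim,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
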