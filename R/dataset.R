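#' Otolith measurement dataset
#'
#' The canonical container for element:Ca (or concentration) measurements.
#' One row per fish x otolith zone; metadata columns first, then one column
#' per panel element. Juveniles carry `near_core`, `edge` or `whole` zones;
#' adults carry the `milled_core` zone (material micro-drilled from the
#' juvenile-growth region of the adult otolith).
#'
#' @param data data.frame with columns `fish_id`, `life_stage`, `zone`,
#'   `site`, `lat`, `lon`, `year_class`, `batch` and one numeric column per
#'   panel element. `site` may be `NA` for adults of unknown origin.
#' @param panel an [element_panel()]; every panel element must be a column.
#' @param provenance free-text source note.
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return an object of class `otolith_dataset`: the data.frame with
#'   `panel` and `provenance` attributes.
#' @export
otolith_dataset <- function(data, panel, provenance = "",
                            validate = TRUE) {
  stopifnot(is.data.frame(data), inherits(panel, "element_panel"))
  data <- as.data.frame(data)
  meta <- c("fish_id", "life_stage", "zone", "site", "lat", "lon",
            "year_class", "batch")
  missing_meta <- setdiff(meta, names(data))
  if (length(missing_meta))
    stop("missing metadata columns: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  missing_el <- setdiff(panel$elements, names(data))
  if (length(missing_el))
    stop("missing element columns: ", paste(missing_el, collapse = ", "),
         call. = FALSE)
  data <- data[, c(meta, panel$elements)]
  data$fish_id <- as.character(data$fish_id)
  data$site <- as.character(data$site)
  data$zone <- as.character(data$zone)
  data$life_stage <- as.character(data$life_stage)
  rownames(data) <- NULL
  ds <- structure(data, panel = panel, provenance = provenance,
                  class = c("otolith_dataset", "data.frame"))
  if (validate) validate_dataset(ds)
  ds
}

.zones_juvenile <- c("near_core", "edge", "whole")
.zones_adult <- "milled_core"

#' Validate an otolith dataset
#'
#' Checks the typed invariants: known life stages and zones, stage-zone
#' consistency (juvenile zones vs. adult `milled_core`), strictly positive
#' finite element values, and uniqueness of fish x zone. Violations are
#' reported with the offending row indices; nothing is silently dropped.
#'
#' @param ds an `otolith_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error listing rows.
#' @export
validate_dataset <- function(ds) {
  panel <- attr(ds, "panel")
  probs <- character(0)
  row_err <- function(rows, what) {
    if (length(rows))
      sprintf("%s (rows %s)", what,
              paste(utils::head(rows, 10L), collapse = ", "))
    else character(0)
  }
  bad_stage <- which(!ds$life_stage %in% c("juvenile", "adult"))
  probs <- c(probs, row_err(bad_stage, "unknown life_stage"))
  bad_zone <- which(!ds$zone %in% c(.zones_juvenile, .zones_adult))
  probs <- c(probs, row_err(bad_zone, "unknown zone"))
  juv_bad <- which(ds$life_stage == "juvenile" &
                     !ds$zone %in% .zones_juvenile)
  probs <- c(probs, row_err(juv_bad, "juvenile record with adult zone"))
  ad_bad <- which(ds$life_stage == "adult" & !ds$zone %in% .zones_adult)
  probs <- c(probs, row_err(ad_bad, "adult record with non-milled_core zone"))
  for (el in panel$elements) {
    v <- ds[[el]]
    if (!is.numeric(v)) {
      probs <- c(probs, sprintf("element column %s is not numeric", el))
      next
    }
    bad <- which(!is.finite(v) | v <= 0)
    probs <- c(probs, row_err(bad, sprintf("non-positive or missing %s", el)))
  }
  key <- paste(ds$fish_id, ds$zone, sep = "\r")
  dup <- which(duplicated(key))
  probs <- c(probs, row_err(dup, "duplicate fish_id x zone"))
  if (length(probs))
    stop("invalid otolith dataset:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  invisible(ds)
}

#' @export
print.otolith_dataset <- function(x, ...) {
  panel <- attr(x, "panel")
  cat(sprintf("<otolith_dataset> %d records, %d fish, elements %s [%s]\n",
              nrow(x), length(unique(x$fish_id)),
              paste(panel$elements, collapse = ","), panel$units))
  zt <- table(x$zone)
  cat("  zones: ", paste(names(zt), zt, sep = "=", collapse = "  "), "\n")
  if (nzchar(attr(x, "provenance")))
    cat("  provenance: ", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Subset a dataset by otolith zone
#'
#' @param ds an `otolith_dataset`.
#' @param zone one of `"near_core"`, `"edge"`, `"whole"`, `"milled_core"`.
#' @return an `otolith_dataset` with only that zone's records, preserving
#'   panel and provenance; empty subsets are allowed with a warning.
#' @export
split_by_zone <- function(ds, zone) {
  if (!(length(zone) == 1L && zone %in% c(.zones_juvenile, .zones_adult)))
    stop("unknown zone: ", paste(zone, collapse = ","), call. = FALSE)
  keep <- ds$zone == zone
  if (!any(keep)) warning("no records in zone '", zone, "'", call. = FALSE)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, panel = attr(ds, "panel"),
            provenance = attr(ds, "provenance"),
            class = class(ds))
}

#' Fish with both near-core and edge ablation records
#'
#' Core-edge comparisons (matched-pair tests) need both laser pits for a
#' fish; this returns the paired fish and reports how many were dropped.
#'
#' @param ds an `otolith_dataset` containing juvenile ablation records.
#' @return data.frame with columns `fish_id` and `site` for every fish with
#'   both zones; attribute `n_dropped` counts fish having only one.
#' @export
paired_zone_fish <- function(ds) {
  core <- unique(ds$fish_id[ds$zone == "near_core"])
  edge <- unique(ds$fish_id[ds$zone == "edge"])
  both <- intersect(core, edge)
  dropped <- length(union(core, edge)) - length(both)
  if (dropped > 0)
    message(dropped, " fish lack one of the near_core/edge zones and are dropped")
  idx <- match(both, ds$fish_id)
  out <- data.frame(fish_id = both,
                    site = ds$site[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Extract the element matrix for one zone
#'
#' @param ds an `otolith_dataset`.
#' @param zone zone label.
#' @return numeric matrix (fish x elements) with `fish_id` rownames;
#'   attributes `site` (character vector) and `lat` carry the metadata.
#' @export
zone_matrix <- function(ds, zone) {
  sub <- split_by_zone(ds, zone)
  panel <- attr(ds, "panel")
  X <- as.matrix(as.data.frame(sub)[, panel$elements, drop = FALSE])
  rownames(X) <- sub$fish_id
  attr(X, "site") <- sub$site
  attr(X, "lat") <- sub$lat
  X
}
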