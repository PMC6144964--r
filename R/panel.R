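#' Element panel
#'
#' An ordered set of measured elements with their isotope mass numbers and
#' the unit all measurements in a dataset share. Calcium is the internal
#' normalizer and may never be a panel member: element values are either
#' already expressed relative to Ca (`"ratio_to_ca"`) or are concentrations
#' (`"ug_g"`) awaiting normalization.
#'
#' @param elements character vector of element symbols, e.g. `c("Mg", "Mn",
#'   "Sr", "Ba")`. Must be unique and must not contain `"Ca"`.
#' @param isotopes optional integer vector of mass numbers, parallel to
#'   `elements` (e.g. `c(26, 55, 88, 138)`).
#' @param units one of `"ratio_to_ca"` or `"ug_g"`. Units are metadata only;
#'   nothing converts them implicitly and mixing them in one dataset is an
#'   error.
#' @return an object of class `element_panel`.
#' @examples
#' element_panel(c("Mg", "Mn", "Sr", "Ba"))
#' @export
element_panel <- function(elements,
                          isotopes = NULL,
                          units = c("ratio_to_ca", "ug_g")) {
  units <- match.arg(units)
  elements <- as.character(elements)
  if (anyDuplicated(elements))
    stop("panel elements must be unique", call. = FALSE)
  if ("Ca" %in% elements)
    stop("Ca is the normalizer and cannot be a panel element", call. = FALSE)
  if (length(elements) < 1L)
    stop("panel must contain at least one element", call. = FALSE)
  if (!is.null(isotopes)) {
    if (length(isotopes) != length(elements))
      stop("isotopes must be parallel to elements", call. = FALSE)
    isotopes <- as.integer(isotopes)
  }
  structure(
    list(elements = elements, isotopes = isotopes, units = units),
    class = "element_panel"
  )
}

#' @export
print.element_panel <- function(x, ...) {
  lab <- if (is.null(x$isotopes)) x$elements else paste0(x$elements, "-", x$isotopes)
  cat("<element_panel> ", paste(lab, collapse = ", "),
      " [", x$units, "]\n", sep = "")
  invisible(x)
}

#' Default element panel
#'
#' The four elements carried through all statistics: Mg, Mn, Sr, Ba
#' (isotopes 26, 55, 88, 138).
#'
#' @param units measurement units, see [element_panel()].
#' @return an `element_panel`.
#' @export
default_panel <- function(units = "ratio_to_ca") {
  element_panel(c("Mg", "Mn", "Sr", "Ba"),
                isotopes = c(26L, 55L, 88L, 138L),
                units = units)
}

#' Site-to-region map
#'
#' Maps nursery site codes onto broader regions used for regional fallback
#' in assignment and for aggregating classification tables.
#'
#' @param sites character vector of site codes.
#' @param regions character vector of region labels, parallel to `sites`.
#' @return a named character vector (names = sites, values = regions) of
#'   class `region_map`.
#' @examples
#' region_map(c("SH", "FB", "SB"), c("Northern", "Northern", "Southern"))
#' @export
region_map <- function(sites, regions) {
  sites <- as.character(sites)
  regions <- as.character(regions)
  if (length(sites) != length(regions))
    stop("sites and regions must have equal length", call. = FALSE)
  if (anyDuplicated(sites))
    stop("each site must map to exactly one region", call. = FALSE)
  structure(stats::setNames(regions, sites), class = "region_map")
}

#' Default North Sea region map
#'
#' The ten default nursery sites (Southern Bight, German Bight, German
#' coast, Danish coast, Tay, Buchan, eastern Skagerrak, northern Skagerrak,
#' Fisher Bank, Shetland) grouped into four regions.
#'
#' @return a `region_map` over the default site vocabulary.
#' @export
default_region_map <- function() {
  region_map(
    sites   = c("SH", "FB", "NS", "ES", "BU", "TA", "DA", "GB", "GC", "SB"),
    regions = c("Northern", "Northern", "Skagerrak", "Skagerrak",
                "EastCoast", "EastCoast", "Southern", "Southern",
                "Southern", "Southern")
  )
}

#' Look up regions for site codes
#'
#' @param rm a `region_map`.
#' @param sites character vector of site codes; every site must be mapped.
#' @return character vector of region labels.
#' @export
region_of <- function(rm, sites) {
  sites <- as.character(sites)
  miss <- setdiff(unique(sites), names(rm))
  if (length(miss))
    stop("sites not in region map: ", paste(miss, collapse = ", "),
         call. = FALSE)
  unname(unclass(rm)[sites])
}
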