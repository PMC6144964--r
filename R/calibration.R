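#' Certified reference values for a calibration standard
#'
#' Describes the glass standard bracketing each ablation run: certified
#' trace-element concentrations, the Ca isotope used as internal standard,
#' and the Ca mass fraction assumed for otolith aragonite.
#'
#' @param certified named numeric vector of certified concentrations
#'   (ug/g), which must include the internal-standard element `"Ca"`.
#' @param internal_standard isotope label used as internal standard in the
#'   count tables (default `"Ca43"`; configurable because runs may monitor
#'   different Ca isotopes).
#' @param assumed_ca_sample Ca mass fraction assumed for the otolith matrix,
#'   in ug/g. Default 388000 (38.8 wt%, aragonite stoichiometry).
#' @return object of class `standard_reference`.
#' @export
standard_reference <- function(certified,
                               internal_standard = "Ca43",
                               assumed_ca_sample = 388000) {
  if (is.null(names(certified)) || any(!nzchar(names(certified))))
    stop("certified must be a named vector", call. = FALSE)
  if (any(certified <= 0))
    stop("certified concentrations must be > 0", call. = FALSE)
  if (!"Ca" %in% names(certified))
    stop("certified must include Ca", call. = FALSE)
  if (assumed_ca_sample <= 0)
    stop("assumed_ca_sample must be > 0", call. = FALSE)
  structure(list(certified = certified,
                 internal_standard = internal_standard,
                 assumed_ca_sample = assumed_ca_sample),
            class = "standard_reference")
}

#' NIST 612 reference glass
#'
#' Nominal concentrations (ug/g) for the elements monitored here; values
#' are the commonly used preferred values for this glass and are
#' configuration defaults, overridable via [standard_reference()].
#'
#' @param assumed_ca_sample see [standard_reference()].
#' @return a `standard_reference` for NIST 612.
#' @export
nist612 <- function(assumed_ca_sample = 388000) {
  standard_reference(
    certified = c(Mg = 68, Mn = 38.7, Cu = 37.8, Zn = 39.1,
                  Sr = 78.4, Ba = 39.7, Ca = 85263),
    assumed_ca_sample = assumed_ca_sample
  )
}

.check_run <- function(run, isotopes) {
  need <- c("kind", "run_order", isotopes)
  missing_cols <- setdiff(need, names(run))
  if (length(missing_cols))
    stop("run table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(run$kind %in% c("gas_blank", "standard", "sample")))
    stop("kind must be gas_blank/standard/sample", call. = FALSE)
  if (is.unsorted(run$run_order, strictly = TRUE))
    stop("run_order must be strictly increasing", call. = FALSE)
  invisible(run)
}

#' Blank-subtract and drift-correct an ablation run
#'
#' The experimental run alternates gas blanks and reference-glass standards
#' with otolith ablations. Each sample has the nearest preceding gas blank
#' subtracted (floored at zero, with a flag when clipping occurs), then its
#' counts are rescaled for instrument drift: per isotope, the standard's
#' blank-corrected sensitivity is interpolated linearly in run order
#' between the bracketing standards, and the sample is divided by the
#' interpolated sensitivity relative to the run's first standard.
#'
#' @param run data.frame with columns `kind` (`gas_blank`/`standard`/
#'   `sample`), `run_order` (strictly increasing integers) and one
#'   counts-per-second column per isotope.
#' @param isotopes character vector of isotope columns; defaults to every
#'   column other than `kind`/`run_order`.
#' @return the run with sample and standard rows blank-subtracted and
#'   sample rows drift-corrected; logical column `clipped` marks rows where
#'   any isotope was floored at zero.
#' @export
blank_drift_correct <- function(run, isotopes = NULL) {
  if (is.null(isotopes))
    isotopes <- setdiff(names(run), c("kind", "run_order"))
  .check_run(run, isotopes)
  blanks <- which(run$kind == "gas_blank")
  stds <- which(run$kind == "standard")
  samples <- which(run$kind == "sample")
  if (length(blanks) < 1L)
    stop("run must contain at least one gas blank", call. = FALSE)
  if (length(stds) < 2L)
    stop("run must contain at least two standards", call. = FALSE)
  if (length(samples) &&
      (min(stds) > min(samples) || max(stds) < max(samples)))
    stop("samples must be bracketed by standards", call. = FALSE)

  out <- run
  out$clipped <- FALSE
  # blank subtraction: nearest preceding blank, applied to standards and
  # samples alike (standard sensitivities must be blank-corrected too)
  for (i in c(stds, samples)) {
    prev <- blanks[blanks < i]
    if (!length(prev)) prev <- blanks  # leading blank missing: use nearest
    b <- unlist(run[max(prev), isotopes])
    v <- unlist(run[i, isotopes]) - b
    if (any(v <= 0)) {        # blank at or above signal: flag and floor
      out$clipped[i] <- TRUE
      v <- pmax(v, 0)
    }
    out[i, isotopes] <- as.list(v)
  }
  # drift: per isotope linear interpolation of standard sensitivity
  std_ord <- run$run_order[stds]
  ref <- unlist(out[stds[1L], isotopes])
  for (i in samples) {
    t <- run$run_order[i]
    for (iso in isotopes) {
      sens <- stats::approx(std_ord, out[stds, iso], xout = t, rule = 2)$y
      if (ref[[iso]] > 0 && sens > 0)
        out[i, iso] <- out[i, iso] / (sens / ref[[iso]])
    }
  }
  out
}

#' Internal standardization of ablation counts
#'
#' Converts blank/drift-corrected counts to concentrations (ug/g) by the
#' classic internal-standardization relation: the sample/standard count
#' ratio of each analyte is scaled by the certified standard concentration
#' and corrected for ablation yield via the internal-standard (Ca) counts
#' and the assumed Ca content of the otolith matrix:
#'
#' \deqn{C_i^{smp} = C_i^{std} \frac{n_i^{smp}}{n_i^{std}}
#'       \frac{n_{IS}^{std}}{n_{IS}^{smp}}
#'       \frac{C_{Ca}^{smp}}{C_{Ca}^{std}}}
#'
#' @param sample_counts named numeric vector of corrected sample counts,
#'   including the internal-standard isotope.
#' @param standard_counts corrected counts for a standard block.
#' @param std a [standard_reference()].
#' @param elements analytes to convert; default every certified element
#'   except Ca present in the counts. Isotope columns named like `"Mn55"`
#'   are matched to elements by their leading symbol.
#' @return named numeric vector of concentrations (ug/g).
#' @export
internal_standardize <- function(sample_counts, standard_counts, std,
                                 elements = NULL) {
  is_iso <- std$internal_standard
  if (!is_iso %in% names(sample_counts) ||
      !is_iso %in% names(standard_counts))
    stop("internal standard '", is_iso, "' missing from counts",
         call. = FALSE)
  if (sample_counts[[is_iso]] <= 0 || standard_counts[[is_iso]] <= 0)
    stop("internal-standard counts must be > 0", call. = FALSE)
  iso_names <- setdiff(names(sample_counts), is_iso)
  sym <- sub("[0-9]+$", "", iso_names)
  if (is.null(elements)) {
    keep <- sym %in% setdiff(names(std$certified), "Ca")
    iso_names <- iso_names[keep]
    sym <- sym[keep]
  } else {
    idx <- match(elements, sym)
    if (anyNA(idx))
      stop("no counts for elements: ",
           paste(elements[is.na(idx)], collapse = ", "), call. = FALSE)
    iso_names <- iso_names[idx]
    sym <- elements
  }
  yield <- standard_counts[[is_iso]] / sample_counts[[is_iso]]
  ca_term <- std$assumed_ca_sample / std$certified[["Ca"]]
  conc <- vapply(seq_along(iso_names), function(j) {
    n_smp <- sample_counts[[iso_names[j]]]
    n_std <- standard_counts[[iso_names[j]]]
    if (n_std <= 0)
      stop("standard counts for ", iso_names[j], " must be > 0",
           call. = FALSE)
    std$certified[[sym[j]]] * (n_smp / n_std) * yield * ca_term
  }, numeric(1))
  stats::setNames(conc, sym)
}

#' Normalize concentrations to calcium ratios
#'
#' Divides each analyte concentration by the Ca value, compensating for
#' ablation-yield and matrix variation between samples and standards.
#'
#' @param concentrations named numeric vector of concentrations (ug/g).
#' @param ca Ca concentration (ug/g); default the aragonite assumption of
#'   388000 ug/g.
#' @return named numeric vector of element:Ca ratios.
#' @export
to_ca_ratio <- function(concentrations, ca = 388000) {
  if (!is.finite(ca) || ca <= 0)
    stop("Ca concentration must be > 0", call. = FALSE)
  concentrations / ca
}

#' Calibrate a full ablation run to Ca ratios
#'
#' Convenience wrapper: [blank_drift_correct()], then per sample
#' [internal_standardize()] against the mean of the corrected standard
#' blocks, then [to_ca_ratio()].
#'
#' @inheritParams blank_drift_correct
#' @param std a [standard_reference()].
#' @return data.frame of element:Ca ratios, one row per sample block, with
#'   `run_order` and `clipped` columns.
#' @export
calibrate_run <- function(run, std, isotopes = NULL) {
  if (is.null(isotopes))
    isotopes <- setdiff(names(run), c("kind", "run_order"))
  corr <- blank_drift_correct(run, isotopes)
  stds <- which(corr$kind == "standard")
  std_counts <- colMeans(corr[stds, isotopes, drop = FALSE])
  samples <- which(corr$kind == "sample")
  rows <- lapply(samples, function(i) {
    conc <- internal_standardize(unlist(corr[i, isotopes]), std_counts, std)
    to_ca_ratio(conc, ca = std$assumed_ca_sample)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$run_order <- corr$run_order[samples]
  out$clipped <- corr$clipped[samples]
  out
}
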