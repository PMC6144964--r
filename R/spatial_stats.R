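#' Kruskal-Wallis test across sites
#'
#' Omnibus rank test for geographic variation of one element across
#' sampling sites; midranks with tie correction, chi-square approximation
#' with k - 1 degrees of freedom.
#'
#' @param values numeric vector of measurements.
#' @param groups group (site) labels, parallel to `values`.
#' @return object of class `oto_test` with `statistic` (H), `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (length(values) < 3L)
    stop("need at least three observations", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("degenerate data: all values identical", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  structure(list(method = "Kruskal-Wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = unname(kt$p.value)),
            class = "oto_test")
}

#' @export
print.oto_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f", x$method, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$pairs)) {
    cat(sprintf("  %d pairwise comparisons (%s-adjusted)\n",
                nrow(x$pairs), x$adjust))
    if (!is.null(x$letters))
      cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                              collapse = " "), "\n")
  }
  invisible(x)
}

#' Dunn post hoc multiple comparisons
#'
#' Pairwise z statistics on the pooled midranks after a significant
#' Kruskal-Wallis test, with the tie correction
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 -
#' \sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)}}, two-sided p-values from the
#' standard normal, and a compact letter display in which two groups share
#' a letter exactly when their adjusted p-value is at least `alpha`.
#'
#' @inheritParams kruskal_wallis
#' @param adjust p-value adjustment: `"bonferroni"` (default), `"holm"`,
#'   or `"none"`.
#' @param alpha significance level for the letter display.
#' @return `oto_test` with a `pairs` data.frame (`group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`) and a `letters` named character vector.
#' @export
dunn_posthoc <- function(values, groups,
                         adjust = c("bonferroni", "holm", "none"),
                         alpha = 0.05) {
  adjust <- match.arg(adjust)
  omnibus <- kruskal_wallis(values, groups)
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  cmb <- utils::combn(length(lev), 2)
  z <- p <- numeric(ncol(cmb))
  for (q in seq_len(ncol(cmb))) {
    i <- cmb[1, q]; j <- cmb[2, q]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[q] <- (rbar[i] - rbar[j]) / se
    p[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  pairs <- data.frame(group1 = lev[cmb[1, ]], group2 = lev[cmb[2, ]],
                      z = z, p_value = p, p_adjusted = p_adj,
                      stringsAsFactors = FALSE)
  structure(list(method = "Dunn post hoc", statistic = omnibus$statistic,
                 df = omnibus$df, p_value = omnibus$p_value,
                 pairs = pairs, adjust = adjust,
                 letters = letter_display(pairs, lev, alpha = alpha)),
            class = "oto_test")
}

#' Compact letter display from pairwise comparisons
#'
#' Greedy insert-and-absorb: groups sharing a letter are exactly the pairs
#' whose adjusted p-value is >= `alpha`. Displays are not unique; any
#' assignment satisfying that pairwise contract is valid.
#'
#' @param pairs data.frame with `group1`, `group2`, `p_adjusted`.
#' @param levels group labels in display order.
#' @param alpha significance level.
#' @return named character vector of letter strings per group.
#' @export
letter_display <- function(pairs, levels, alpha = 0.05) {
  k <- length(levels)
  same <- matrix(TRUE, k, k, dimnames = list(levels, levels))
  for (q in seq_len(nrow(pairs))) {
    if (pairs$p_adjusted[q] < alpha) {
      same[pairs$group1[q], pairs$group2[q]] <- FALSE
      same[pairs$group2[q], pairs$group1[q]] <- FALSE
    }
  }
  sets <- list()  # each set: groups allowed to share one letter
  for (g in seq_len(k)) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(same[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb sets contained in others, then ensure every non-significant
  # pair shares some set (insert pair sets where greediness missed one)
  for (q in seq_len(nrow(pairs))) {
    i <- match(pairs$group1[q], levels); j <- match(pairs$group2[q], levels)
    if (same[i, j] && !any(vapply(sets, function(s) all(c(i, j) %in% s),
                                  logical(1))))
      sets[[length(sets) + 1L]] <- c(i, j)
  }
  keep <- rep(TRUE, length(sets))
  for (s in seq_along(sets)) for (t in seq_along(sets)) {
    if (s != t && keep[t] &&
        all(sets[[s]] %in% sets[[t]]) &&
        (length(sets[[s]]) < length(sets[[t]]) || s > t))
      keep[s] <- FALSE
  }
  sets <- sets[keep]
  out <- stats::setNames(rep("", k), levels)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' Spearman rank correlation trend test
#'
#' Rank correlation of an elemental value against latitude (or any
#' covariate), on midranks, with the t-approximation p-value.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return `oto_test` with `statistic` (rho) and `p_value`.
#' @export
spearman_trend <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate data: zero variance", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(method = "Spearman rank correlation",
                 statistic = unname(ct$estimate), df = NULL,
                 p_value = unname(ct$p.value), n = length(x)),
            class = "oto_test")
}

#' Wilcoxon matched-pair tests of near-core vs edge chemistry, by site
#'
#' For each site, pairs every fish's near-core and edge value of one
#' element and runs the signed-rank test. Zero differences are dropped
#' (their count is reported); the exact null distribution is used for
#' n <= 25 pairs without ties, otherwise the normal approximation with
#' tie correction.
#'
#' @param ds an `otolith_dataset` with juvenile ablation records.
#' @param element panel element to test.
#' @return data.frame with one row per site: `site`, `n_pairs`,
#'   `n_zero_dropped`, `statistic` (V), `p_value`, `method`.
#' @export
wilcoxon_paired_zones <- function(ds, element) {
  panel <- attr(ds, "panel")
  if (!element %in% panel$elements)
    stop("element not in panel: ", element, call. = FALSE)
  paired <- paired_zone_fish(ds)
  core <- split_by_zone(ds, "near_core")
  edge <- split_by_zone(ds, "edge")
  out <- lapply(split(paired$fish_id, paired$site), function(ids) {
    x <- core[[element]][match(ids, core$fish_id)]
    y <- edge[[element]][match(ids, edge$fish_id)]
    d <- x - y
    nz <- sum(d == 0)
    d <- d[d != 0]
    if (!length(d))
      stop("degenerate data: all core-edge differences zero", call. = FALSE)
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = !exact))
    data.frame(n_pairs = length(ids), n_zero_dropped = nz,
               statistic = unname(wt$statistic),
               p_value = unname(wt$p.value),
               method = if (exact) "exact" else "normal approximation",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(site = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Per-element spatial statistics table
#'
#' Runs [kruskal_wallis()] and [dunn_posthoc()] for each panel element of
#' one zone, plus the latitudinal [spearman_trend()] on per-fish values.
#'
#' @param ds an `otolith_dataset`.
#' @param zone zone to analyze.
#' @param adjust post hoc adjustment method.
#' @return list with `omnibus` (data.frame element, H, df, p), `posthoc`
#'   (named list of `oto_test`), `trend` (data.frame element, rho, p).
#' @export
spatial_stats_table <- function(ds, zone = "edge", adjust = "bonferroni") {
  X <- zone_matrix(ds, zone)
  site <- attr(X, "site"); lat <- attr(X, "lat")
  posthoc <- lapply(colnames(X), function(el)
    dunn_posthoc(X[, el], site, adjust = adjust))
  names(posthoc) <- colnames(X)
  omnibus <- do.call(rbind, lapply(colnames(X), function(el) {
    t <- posthoc[[el]]
    data.frame(element = el, H = t$statistic, df = t$df,
               p_value = t$p_value, stringsAsFactors = FALSE)
  }))
  trend <- do.call(rbind, lapply(colnames(X), function(el) {
    t <- spearman_trend(X[, el], lat)
    data.frame(element = el, rho = t$statistic, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  list(omnibus = omnibus, posthoc = posthoc, trend = trend)
}
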