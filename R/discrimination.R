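#' Repeat-averaged out-of-bag confusion table
#'
#' Fits `n_repeats` independent random forests to site labels and averages
#' the row-normalized out-of-bag confusion matrices: each fish is predicted
#' only by the trees in whose bootstrap sample it did not appear, giving a
#' built-in cross-validation of site discrimination. When `balance` is set,
#' each repeat first draws a balanced subsample of `balance` fish split
#' equally across sites (mirroring repeated balanced subsampling protocols
#' for unequal site sizes).
#'
#' @param ds an `otolith_dataset`.
#' @param zone zone whose records are classified.
#' @param n_trees trees per forest (default 500).
#' @param n_repeats forests averaged (default 100).
#' @param seed integer seed; fixed seed gives an identical table.
#' @param balance optional total subsample size per repeat, divided equally
#'   across sites.
#' @return object of class `confusion_table`: list with `prob` (site x
#'   site row-stochastic matrix of classification probabilities),
#'   `accuracy` (per-site diagonal), `overall` accuracy, `n_repeats`,
#'   `seed`.
#' @export
rf_site_confusion <- function(ds, zone = "edge", n_trees = 500,
                              n_repeats = 100, seed = 1, balance = NULL) {
  X <- zone_matrix(ds, zone)
  y <- factor(attr(X, "site"))
  if (nlevels(y) < 2L) stop("need at least two sites", call. = FALSE)
  if (any(table(y) < 2L)) stop("every site needs >= 2 fish", call. = FALSE)
  set.seed(seed)
  lev <- levels(y)
  acc <- matrix(0, nlevels(y), nlevels(y), dimnames = list(lev, lev))
  counts <- prop <- acc
  for (r in seq_len(n_repeats)) {
    if (!is.null(balance)) {
      per <- floor(balance / nlevels(y))
      idx <- unlist(lapply(lev, function(l)
        sample(which(y == l), min(per, sum(y == l)))))
    } else idx <- seq_along(y)
    fit <- randomForest::randomForest(X[idx, , drop = FALSE], y[idx],
                                      ntree = n_trees)
    pred <- fit$predicted  # OOB-only predictions
    ok <- !is.na(pred)
    tab <- table(true = y[idx][ok], predicted = pred[ok])
    prop <- prop + tab / pmax(rowSums(tab), 1)
  }
  prob <- prop / n_repeats
  prob <- prob / rowSums(prob)  # guards repeats with empty rows
  structure(list(prob = unclass(prob),
                 accuracy = diag(unclass(prob)),
                 overall = sum(diag(unclass(prob)) * table(y) / length(y)),
                 n_repeats = n_repeats, seed = seed),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> %d sites, %d repeats, overall accuracy %.3f\n",
              nrow(x$prob), x$n_repeats, x$overall))
  print(round(x$prob, 2))
  invisible(x)
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For each element, the out-of-bag classification accuracy lost when that
#' element's values are permuted, averaged over all trees of `n_repeats`
#' forests and expressed in percentage points. Positive values mean the
#' element carries discriminatory signal; noise elements scatter around
#' zero and are reported as-is.
#'
#' @inheritParams rf_site_confusion
#' @return data.frame with `element`, `mean_decrease_accuracy` (percentage
#'   points) and `sd` across repeats, ordered by importance.
#' @export
rf_importance <- function(ds, zone = "edge", n_trees = 500,
                          n_repeats = 10, seed = 1) {
  X <- zone_matrix(ds, zone)
  y <- factor(attr(X, "site"))
  set.seed(seed)
  imp <- replicate(n_repeats, {
    fit <- randomForest::randomForest(X, y, ntree = n_trees,
                                      importance = TRUE)
    randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  })
  out <- data.frame(element = colnames(X),
                    mean_decrease_accuracy = 100 * rowMeans(imp),
                    sd = 100 * apply(imp, 1, stats::sd),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_decrease_accuracy), ]
}

#' Aggregate a confusion table into regions
#'
#' Sums each site row's classification probability over the member sites
#' of every region and reports the row's own-region sum (the probability
#' of classifying a fish to the correct region). Row mass is conserved
#' exactly.
#'
#' @param ct a `confusion_table` (or bare row-stochastic matrix).
#' @param rm a [region_map()] covering all sites.
#' @return data.frame: one row per site with one column per region plus
#'   `region_sum`, the mass assigned into the site's own region.
#' @export
region_aggregate <- function(ct, rm) {
  prob <- if (inherits(ct, "confusion_table")) ct$prob else as.matrix(ct)
  sites <- rownames(prob)
  regions <- region_of(rm, sites)
  reg_lev <- unique(regions)
  agg <- sapply(reg_lev, function(r)
    rowSums(prob[, regions == r, drop = FALSE]))
  out <- as.data.frame(agg)
  out <- cbind(site = sites, region = regions, out,
               region_sum = agg[cbind(seq_along(sites),
                                      match(regions, reg_lev))])
  rownames(out) <- NULL
  out
}
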