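#' Synthetic reference sample for unsupervised random forests
#'
#' Draws the no-structure reference against which the observed data are
#' contrasted: each column is an independent with-replacement resample of
#' the corresponding observed column, i.e. a sample from the product of
#' the empirical marginal distributions. Any dependence between elements
#' present in the data is destroyed by construction.
#'
#' @param X numeric matrix or data.frame (fish x elements), no missing
#'   values.
#' @param seed integer seed.
#' @return matrix of the same dimension as `X`.
#' @export
synthetic_reference <- function(X, seed = 1) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("X needs at least 2 rows and 2 columns", call. = FALSE)
  set.seed(seed)
  apply(X, 2, sample, size = nrow(X), replace = TRUE)
}

#' Random-forest proximity matrix
#'
#' Trains a forest to separate the observed rows from a synthetic
#' reference (the two-class unsupervised trick) and returns, for the
#' observed rows, the fraction of trees in which two fish land in the same
#' terminal node. The proximity counts all trees, and the diagonal is 1.
#'
#' @param X standardized feature matrix (fish x elements).
#' @param n_trees trees in the forest (default 2000; below 50 proximities
#'   are unstable and a warning is issued).
#' @param seed integer seed.
#' @param X_synth optional pre-built synthetic reference; defaults to
#'   [synthetic_reference()] of `X` under the same seed.
#' @return object of class `proximity_matrix`: symmetric matrix in [0, 1]
#'   with unit diagonal; attributes `n_trees` and `seed`.
#' @export
rf_proximity <- function(X, n_trees = 2000, seed = 1, X_synth = NULL) {
  X <- as.matrix(X)
  if (is.null(X_synth)) X_synth <- synthetic_reference(X, seed = seed)
  if (!identical(ncol(X), ncol(X_synth)))
    stop("X and X_synth must share columns", call. = FALSE)
  if (n_trees < 50)
    warning("fewer than 50 trees gives unstable proximities", call. = FALSE)
  ratio <- nrow(X) / nrow(X_synth)
  if (ratio > 2 || ratio < 0.5)
    warning("observed/synthetic class imbalance beyond 2:1", call. = FALSE)
  set.seed(seed)
  all <- rbind(X, X_synth)
  y <- factor(rep(c("observed", "synthetic"),
                  c(nrow(X), nrow(X_synth))))
  fit <- randomForest::randomForest(all, y, ntree = n_trees,
                                    proximity = TRUE)
  S <- fit$proximity[seq_len(nrow(X)), seq_len(nrow(X)), drop = FALSE]
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  structure(S, n_trees = n_trees, seed = seed,
            class = c("proximity_matrix", "matrix"))
}

#' Proximity-to-dissimilarity transform
#'
#' \eqn{d_{ij} = \sqrt{1 - s_{ij}}}: zero diagonal, symmetric, entries in
#' [0, 1].
#'
#' @param S proximity matrix with entries in [0, 1].
#' @return dissimilarity matrix of class `dissimilarity_matrix`.
#' @export
to_dissimilarity <- function(S) {
  S <- unclass(as.matrix(S))
  if (any(S < -1e-12) || any(S > 1 + 1e-12))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  D <- sqrt(pmax(1 - S, 0))
  diag(D) <- 0
  structure(D, class = c("dissimilarity_matrix", "matrix"))
}

#' Partitioning around medoids (BUILD + SWAP, exact on small instances)
#'
#' k-medoids on a precomputed dissimilarity matrix. When the number of
#' candidate medoid sets `choose(n, k)` is at most `exact_limit` the
#' optimum is found by direct enumeration (cheap at these sizes and
#' guaranteed globally optimal, which BUILD + SWAP is not). Otherwise the
#' classic heuristic runs: BUILD seeds the medoids greedily (first the
#' point minimizing total dissimilarity, then repeatedly the point
#' yielding the largest decrease), SWAP exchanges a medoid and a
#' non-medoid as long as some single swap lowers the objective (the sum
#' over points of the dissimilarity to the nearest medoid). Each point is
#' labelled by its nearest medoid, ties broken toward the lowest medoid
#' index, so the procedure is fully deterministic.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @param exact_limit enumerate all medoid sets when `choose(n, k)` does
#'   not exceed this (default 1000); set 0 to force the heuristic.
#' @return object of class `cluster_solution`: list with `k`, `medoids`
#'   (indices), `labels`, `objective`, `method` (`"exact"` or
#'   `"build_swap"`), and the objective `trace` over SWAP iterations
#'   (non-increasing by construction).
#' @export
pam_partition <- function(D, k, exact_limit = 1000) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (!(k >= 2 && k < n)) stop("need 2 <= k < n", call. = FALSE)
  if (choose(n, k) <= exact_limit) {
    best <- Inf; best_med <- NULL
    for (med in utils::combn(n, k, simplify = FALSE)) {
      o <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (o < best - 1e-15) { best <- o; best_med <- med }
    }
    labels <- apply(D[, best_med, drop = FALSE], 1, which.min)
    return(structure(list(k = k, medoids = best_med, labels = labels,
                          objective = best, trace = best,
                          method = "exact"),
                     class = "cluster_solution"))
  }
  # BUILD
  medoids <- which.min(rowSums(D))
  while (length(medoids) < k) {
    dn <- apply(D[, medoids, drop = FALSE], 1, min)  # dist to nearest medoid
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% medoids) return(-Inf)
      sum(pmax(dn - D[, c], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }
  objective <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  obj <- objective(medoids)
  trace <- obj
  repeat {
    best <- obj; best_swap <- NULL
    for (m in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[m] <- h
        o <- objective(cand)
        if (o < best - 1e-12) { best <- o; best_swap <- cand }
      }
    }
    if (is.null(best_swap)) break
    medoids <- best_swap; obj <- best; trace <- c(trace, obj)
  }
  medoids <- sort(medoids)
  labels <- apply(D[, medoids, drop = FALSE], 1, which.min)
  structure(list(k = k, medoids = medoids, labels = labels,
                 objective = obj, trace = trace, method = "build_swap"),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, objective = %.4f, sizes: %s\n",
              x$k, x$objective,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  if (!is.null(x$dunn)) cat(sprintf("  Dunn index = %.3f\n", x$dunn))
  if (!is.null(x$profile)) {
    cat("  Dunn profile:\n")
    print(x$profile, row.names = FALSE)
  }
  invisible(x)
}

#' Dunn cluster-validity index
#'
#' Minimum between-cluster separation (smallest pairwise distance across
#' any two clusters) divided by the maximum within-cluster diameter
#' (largest pairwise distance within any cluster). Larger is better. If
#' every cluster is a singleton all diameters are zero and `Inf` is
#' returned with a warning.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return non-negative scalar (possibly `Inf`).
#' @export
dunn_index <- function(D, labels) {
  D <- unclass(as.matrix(D))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least two clusters", call. = FALSE)
  diam <- max(vapply(seq_len(k), function(c) {
    idx <- which(labels == c)
    if (length(idx) < 2) 0 else max(D[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(utils::combn(k, 2, simplify = FALSE), function(pr) {
    min(D[labels == pr[1], labels == pr[2]])
  }, numeric(1)))
  if (diam == 0) {
    warning("all clusters are zero-diameter; Dunn index is infinite",
            call. = FALSE)
    return(Inf)
  }
  sep / diam
}

#' Select the number of natal clusters by the Dunn index
#'
#' Runs [pam_partition()] and [dunn_index()] over a range of k and returns
#' the solution maximizing the Dunn index (ties to the smallest k),
#' together with the full profile. An explicit `override` returns that k's
#' solution while keeping the profile, for the common situation where
#' external evidence (e.g. the number of chemically similar regions) fixes
#' the cluster count.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param k_range candidate cluster counts within `[2, n - 1]`.
#' @param override optional k to return regardless of the profile argmax.
#' @return `cluster_solution` with extra fields `dunn`, `profile`
#'   (data.frame `k`, `dunn`, `objective`) and `k_selected`.
#' @export
choose_k <- function(D, k_range = 2:8, override = NULL) {
  if (!length(k_range)) stop("empty k range", call. = FALSE)
  sols <- lapply(k_range, function(k) {
    s <- pam_partition(D, k)
    s$dunn <- dunn_index(D, s$labels)
    s
  })
  profile <- data.frame(k = k_range,
                        dunn = vapply(sols, `[[`, numeric(1), "dunn"),
                        objective = vapply(sols, `[[`, numeric(1),
                                           "objective"))
  pick <- if (is.null(override)) which.max(profile$dunn)
          else match(override, k_range)
  if (is.na(pick)) stop("override k not in k_range", call. = FALSE)
  out <- sols[[pick]]
  out$profile <- profile
  out$k_selected <- k_range[pick]
  out$override <- override
  out
}

#' Cluster composition and signature summaries
#'
#' Per-cluster mean and SD of each element on the raw measurement scale,
#' and the per-site proportions of fish over clusters (each site's
#' proportions sum to 1) -- the natal-source contribution table.
#'
#' @param X_raw matrix of raw (unstandardized) element values, rows
#'   aligned with `labels`.
#' @param labels cluster labels per fish.
#' @param sites site code per fish.
#' @return list with `signature` (data.frame cluster x element mean/sd)
#'   and `contribution` (matrix site x cluster of proportions).
#' @export
cluster_summary <- function(X_raw, labels, sites) {
  X_raw <- as.matrix(X_raw)
  if (nrow(X_raw) != length(labels) || length(labels) != length(sites))
    stop("labels and sites must align with X_raw rows", call. = FALSE)
  lab <- factor(labels)
  signature <- do.call(rbind, lapply(levels(lab), function(l) {
    sub <- X_raw[lab == l, , drop = FALSE]
    data.frame(cluster = l, element = colnames(X_raw),
               mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
               n = nrow(sub), stringsAsFactors = FALSE, row.names = NULL)
  }))
  tab <- table(site = sites, cluster = lab)
  contribution <- unclass(tab / rowSums(tab))
  list(signature = signature, contribution = contribution)
}

#' Standardize a feature matrix
#'
#' Column-wise center/scale to zero mean and unit variance, the input
#' expected by the proximity forest.
#'
#' @param X numeric matrix.
#' @return standardized matrix.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  scale(X, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' End-to-end natal clustering of near-core chemistry
#'
#' The full unsupervised stage: standardize the near-core element matrix,
#' build the synthetic reference, fit the observed-vs-synthetic proximity
#' forest, transform to dissimilarities, scan k by PAM + Dunn index, and
#' summarize cluster signatures and per-site contributions on the raw
#' scale.
#'
#' @param ds an `otolith_dataset` containing near-core records.
#' @param k_range candidate numbers of clusters.
#' @param n_trees proximity-forest size.
#' @param seed integer seed.
#' @param override optional fixed number of clusters (see [choose_k()]).
#' @return list with `solution` (a `cluster_solution`), `dissimilarity`,
#'   `proximity`, `summary` (see [cluster_summary()]), and the `fish_id` /
#'   `site` vectors aligned with the labels.
#' @export
natal_clustering <- function(ds, k_range = 2:8, n_trees = 2000, seed = 1,
                             override = NULL) {
  X <- zone_matrix(ds, "near_core")
  S <- rf_proximity(standardize(X), n_trees = n_trees, seed = seed)
  D <- to_dissimilarity(S)
  sol <- choose_k(D, k_range = k_range, override = override)
  summ <- cluster_summary(X, sol$labels, attr(X, "site"))
  list(solution = sol, dissimilarity = D, proximity = S, summary = summ,
       fish_id = rownames(X), site = attr(X, "site"))
}
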