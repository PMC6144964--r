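#' MCMC convergence diagnostics for mixture-proportion draws
#'
#' Rank-normalized split potential scale reduction (R-hat) and bulk
#' effective sample size for each monitored site proportion. Draws are
#' pooled across chains, rank-normalized through the inverse normal CDF,
#' each chain is split in half, and the classic between/within variance
#' ratio and Geyer initial-monotone autocorrelation sum are computed on
#' the normalized draws. R-hat above 1.05 triggers a warning.
#'
#' @param ar an `assignment_result` (its `pi_draws` array is used) or a
#'   draws x quantities x chains array.
#' @return data.frame with `quantity`, `rhat` (NA for a single chain),
#'   `ess`.
#' @export
mcmc_diagnostics <- function(ar) {
  draws <- if (inherits(ar, "assignment_result")) ar$pi_draws else ar
  stopifnot(length(dim(draws)) == 3L)
  qn <- dimnames(draws)[[2]] %||% paste0("q", seq_len(dim(draws)[2]))
  out <- do.call(rbind, lapply(seq_len(dim(draws)[2]), function(j) {
    x <- draws[, j, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    data.frame(quantity = qn[j],
               rhat = .split_rhat(x), ess = .bulk_ess(x),
               stringsAsFactors = FALSE)
  }))
  bad <- out$quantity[!is.na(out$rhat) & out$rhat > 1.05]
  if (length(bad))
    warning("R-hat > 1.05 for: ", paste(bad, collapse = ", "),
            call. = FALSE)
  out
}

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  matrix(stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4)), nrow(x), ncol(x))
}

.split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1, n), , drop = FALSE])
}

.split_rhat <- function(x) {
  if (ncol(x) < 2L) return(NA_real_)
  z <- .split_chains(.rank_normalize(x))
  n <- nrow(z); m <- ncol(z)
  if (n < 3L) return(NA_real_)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.bulk_ess <- function(x) {
  z <- .split_chains(.rank_normalize(x))
  n <- nrow(z); m <- ncol(z)
  if (n < 4L) return(NA_real_)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  var_hat <- (n - 1) / n * W +
    (if (m > 1) n * stats::var(colMeans(z)) / n else 0)
  if (var_hat == 0) return(NA_real_)
  acov <- sapply(seq_len(m), function(c)
    stats::acf(z[, c], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_hat  # lags 1..n-1
  # Geyer: sum consecutive pairs while positive and monotone
  npair <- floor(length(rho) / 2)
  if (npair == 0) return(m * n)
  P <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  k <- which(P <= 0)[1]
  if (!is.na(k)) P <- P[seq_len(k - 1)]
  if (length(P) > 1) P <- cummin(P)
  tau <- 1 + 2 * sum(P)
  min(m * n / max(tau, 1e-8), m * n)
}
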