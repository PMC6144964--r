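#' Baseline model priors for mixed-stock assignment
#'
#' The assignment model is a finite mixture of multivariate normal site
#' distributions with conjugate Normal-Inverse-Wishart priors on each
#' site's (mean, covariance) and a Dirichlet prior on the mixture
#' proportions. Because the site parameters are drawn afresh from their
#' posterior at every sweep, baseline sampling uncertainty propagates into
#' the assignment probabilities, relaxing the strict multivariate-normality
#' and common-covariance assumptions of classical parametric assignment.
#'
#' Defaults are weakly informative and data-scaled: prior mean = grand mean
#' of the (transformed) baseline, `kappa0 = 0.01`, `nu0 = p + 2`, and
#' `Lambda0` = pooled within-site covariance times `nu0 - p - 1` (so the
#' prior expectation of each site covariance is the pooled covariance).
#'
#' @param baseline an `otolith_dataset` of juvenile `whole` records (the
#'   reference of known-origin signatures).
#' @param log_transform log-transform element values before modelling
#'   (default `TRUE`: ratios are positive and right-skewed).
#' @param kappa0 prior strength on the mean (pseudo-observations).
#' @param nu0 inverse-Wishart degrees of freedom; must exceed `p - 1`.
#' @param Lambda0 inverse-Wishart scale matrix (p x p SPD).
#' @param mu0 prior mean vector.
#' @param alpha Dirichlet concentration for the mixture proportions
#'   (default 1, uniform on the simplex).
#' @return object of class `baseline_model` holding per-site posterior
#'   Normal-Inverse-Wishart parameters and the raw site data.
#' @export
baseline_model <- function(baseline, log_transform = TRUE,
                           kappa0 = 0.01, nu0 = NULL, Lambda0 = NULL,
                           mu0 = NULL, alpha = 1) {
  X <- zone_matrix(baseline, "whole")
  site <- attr(X, "site")
  if (log_transform) X <- log(X)
  p <- ncol(X)
  sites <- sort(unique(site))
  if (length(sites) < 2L) stop("need >= 2 baseline sites", call. = FALSE)
  ns <- table(factor(site, sites))
  if (any(ns < 3L)) stop("every baseline site needs n >= 3", call. = FALSE)
  if (is.null(nu0)) nu0 <- p + 2
  if (nu0 <= p - 1) stop("nu0 must exceed p - 1", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (is.null(mu0)) mu0 <- colMeans(X)
  if (is.null(Lambda0)) {
    pooled <- Reduce(`+`, lapply(sites, function(s) {
      sub <- X[site == s, , drop = FALSE]
      stats::cov(sub) * (nrow(sub) - 1)
    })) / (nrow(X) - length(sites))
    Lambda0 <- pooled * max(nu0 - p - 1, 1)
  }
  if (any(abs(Lambda0 - t(Lambda0)) > 1e-8) ||
      any(eigen(Lambda0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Lambda0 must be symmetric positive definite", call. = FALSE)
  post <- lapply(sites, function(s) {
    Y <- X[site == s, , drop = FALSE]
    n <- nrow(Y); ybar <- colMeans(Y)
    S <- stats::cov(Y) * (n - 1)
    kn <- kappa0 + n
    dev <- ybar - mu0
    Ln <- Lambda0 + S + (kappa0 * n / kn) * tcrossprod(dev)
    if (rcond(Ln) < 1e-12)
      stop("singular baseline covariance for site ", s,
           "; use a stronger prior or fewer elements", call. = FALSE)
    list(site = s, n = n,
         mu_n = (kappa0 * mu0 + n * ybar) / kn,
         kappa_n = kn, nu_n = nu0 + n, Lambda_n = Ln,
         Lambda_n_inv = solve(Ln))
  })
  names(post) <- sites
  structure(list(sites = sites, p = p, post = post, alpha = alpha,
                 log_transform = log_transform,
                 prior = list(kappa0 = kappa0, nu0 = nu0,
                              Lambda0 = Lambda0, mu0 = mu0),
                 data = X, site = site,
                 elements = colnames(X)),
            class = "baseline_model")
}

# one draw of (mu_j, Sigma_j) from a Normal-Inverse-Wishart posterior
.draw_niw <- function(pp) {
  W <- stats::rWishart(1, pp$nu_n, pp$Lambda_n_inv)[, , 1]
  Sigma <- chol2inv(chol(W))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(mvtnorm::rmvnorm(1, pp$mu_n, Sigma / pp$kappa_n))
  list(mu = mu, Sigma = Sigma)
}

#' Bayesian mixed-stock assignment of adults to the juvenile baseline
#'
#' Gibbs sampler over (i) latent origins `z_i` given the mixture
#' proportions and the current site parameters via multivariate-normal
#' likelihoods, (ii) proportions `pi` given `z` via a Dirichlet update,
#' and (iii) per-site `(mu_j, Sigma_j)` from their Normal-Inverse-Wishart
#' posterior. In the default `"conditioned"` mode the site parameters are
#' informed by baseline data only (redrawn each sweep, so baseline
#' uncertainty still propagates); `"full"` mode also lets the currently
#' assigned adults update the site parameters.
#'
#' @param bm a [baseline_model()].
#' @param adults an `otolith_dataset` of `milled_core` records sharing the
#'   baseline's element panel.
#' @param chains number of chains (default 4).
#' @param iters sweeps per chain (default 5000).
#' @param burn burn-in sweeps discarded (default 2000).
#' @param thin thinning interval for stored draws (default 5).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param update `"conditioned"` (default) or `"full"`.
#' @return object of class `assignment_result`: `prob` (adults x sites
#'   posterior origin probabilities, rows summing to 1), `pi` (summary of
#'   mixture-proportion draws: mean, sd, 2.5%/97.5%), `pi_draws` (kept
#'   draws x sites x chains array), `fish_id`, `area` (the adults'
#'   sampling areas), `settings`.
#' @export
fit_mixed_stock <- function(bm, adults, chains = 4, iters = 5000,
                            burn = 2000, thin = 5, seed = 1,
                            update = c("conditioned", "full")) {
  update <- match.arg(update)
  stopifnot(inherits(bm, "baseline_model"))
  A <- zone_matrix(adults, "milled_core")
  if (!identical(colnames(A), bm$elements))
    stop("adult panel does not match baseline panel", call. = FALSE)
  if (bm$log_transform) A <- log(A)
  if (any(!is.finite(A))) {
    bad <- rownames(A)[which(!is.finite(A), arr.ind = TRUE)[, 1]]
    stop("non-finite likelihood input for fish ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  n <- nrow(A); J <- length(bm$sites)
  keep <- seq(burn + thin, iters, by = thin)
  z_counts <- matrix(0, n, J, dimnames = list(rownames(A), bm$sites))
  pi_draws <- array(NA_real_, c(length(keep), J, chains),
                    dimnames = list(NULL, bm$sites, NULL))
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    pi <- rep(1 / J, J)
    z <- sample.int(J, n, replace = TRUE)
    ki <- 0L
    for (it in seq_len(iters)) {
      pars <- lapply(bm$sites, function(s) {
        pp <- bm$post[[s]]
        if (update == "full") {
          Ya <- A[z == match(s, bm$sites), , drop = FALSE]
          if (nrow(Ya)) pp <- .niw_augment(pp, Ya, bm$prior)
        }
        .draw_niw(pp)
      })
      logL <- vapply(pars, function(th)
        mvtnorm::dmvnorm(A, th$mu, th$Sigma, log = TRUE), numeric(n))
      logL <- matrix(logL, n, J)
      logw <- sweep(logL, 2, log(pi), `+`)
      logw <- logw - apply(logw, 1, max)
      w <- exp(logw)
      w <- w / rowSums(w)
      # inverse-cdf categorical draw (vectorized over adults)
      u <- stats::runif(n)
      cw <- t(apply(w, 1, cumsum))
      z <- rowSums(cw < u) + 1L
      cnt <- tabulate(z, J)
      pi <- .rdirichlet1(bm$alpha + cnt)
      if (it %in% keep) {
        ki <- ki + 1L
        pi_draws[ki, , ch] <- pi
        z_counts[cbind(seq_len(n), z)] <-
          z_counts[cbind(seq_len(n), z)] + 1
      }
    }
  }
  prob <- z_counts / (length(keep) * chains)
  pim <- apply(pi_draws, 2, mean)
  pi_summary <- data.frame(
    site = bm$sites, mean = pim,
    sd = apply(pi_draws, 2, stats::sd),
    lower = apply(pi_draws, 2, stats::quantile, 0.025),
    upper = apply(pi_draws, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(prob = prob, pi = pi_summary, pi_draws = pi_draws,
                 fish_id = rownames(A),
                 area = attr(A, "site"),
                 settings = list(chains = chains, iters = iters,
                                 burn = burn, thin = thin, seed = seed,
                                 update = update)),
            class = "assignment_result")
}

.rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a)
  g / sum(g)
}

# augment a NIW posterior with extra observations (full-update mode)
.niw_augment <- function(pp, Y, prior) {
  n0 <- pp$n; n1 <- nrow(Y)
  # recombine from sufficient statistics of baseline posterior + new data
  ybar1 <- colMeans(Y)
  kn <- pp$kappa_n + n1
  mu_n <- (pp$kappa_n * pp$mu_n + n1 * ybar1) / kn
  S1 <- if (n1 > 1) stats::cov(Y) * (n1 - 1) else matrix(0, ncol(Y), ncol(Y))
  dev <- ybar1 - pp$mu_n
  Ln <- pp$Lambda_n + S1 + (pp$kappa_n * n1 / kn) * tcrossprod(dev)
  list(site = pp$site, n = n0 + n1, mu_n = mu_n, kappa_n = kn,
       nu_n = pp$nu_n + n1, Lambda_n = Ln, Lambda_n_inv = solve(Ln))
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %d adults x %d sites (%d chains x %d iters)\n",
              nrow(x$prob), ncol(x$prob), x$settings$chains,
              x$settings$iters))
  cat("posterior mixture proportions:\n")
  print(transform(x$pi, mean = round(mean, 3), sd = round(sd, 3),
                  lower = round(lower, 3), upper = round(upper, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Threshold classification of assignment probabilities
#'
#' An adult is assigned to the single site with the highest posterior
#' probability if that probability exceeds `tau`; failing that, to a
#' region whose member sites' summed probability exceeds `tau`; failing
#' both, it is left unassigned (an outlier relative to the baseline).
#'
#' @param ar an `assignment_result` (or bare row-stochastic matrix).
#' @param rm a [region_map()] covering the baseline sites.
#' @param tau probability threshold in (0, 1); default 0.5.
#' @return object of class `assignment_decisions`: data.frame with
#'   `fish_id`, `area`, `decision` (`"site"`, `"region"`, `"unassigned"`),
#'   `assigned_to`, `probability`; attribute `summary` gives the three
#'   fractions.
#' @export
threshold_classify <- function(ar, rm, tau = 0.5) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0 && tau < 1))
    stop("tau must lie in (0, 1)", call. = FALSE)
  prob <- if (inherits(ar, "assignment_result")) ar$prob else as.matrix(ar)
  sites <- colnames(prob)
  regions <- region_of(rm, sites)
  reg_lev <- unique(regions)
  reg_prob <- sapply(reg_lev, function(r)
    rowSums(prob[, regions == r, drop = FALSE]))
  reg_prob <- matrix(reg_prob, nrow(prob), length(reg_lev),
                     dimnames = list(rownames(prob), reg_lev))
  n <- nrow(prob)
  decision <- character(n); assigned <- character(n); pr <- numeric(n)
  for (i in seq_len(n)) {
    bs <- which.max(prob[i, ])
    br <- which.max(reg_prob[i, ])
    if (prob[i, bs] > tau) {
      decision[i] <- "site"; assigned[i] <- sites[bs]; pr[i] <- prob[i, bs]
    } else if (reg_prob[i, br] > tau) {
      decision[i] <- "region"; assigned[i] <- reg_lev[br]
      pr[i] <- reg_prob[i, br]
    } else {
      decision[i] <- "unassigned"; assigned[i] <- NA_character_
      pr[i] <- prob[i, bs]
    }
  }
  out <- data.frame(
    fish_id = if (inherits(ar, "assignment_result")) ar$fish_id
              else rownames(prob) %||% as.character(seq_len(n)),
    area = if (inherits(ar, "assignment_result")) ar$area else NA_character_,
    decision = decision, assigned_to = assigned, probability = pr,
    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(site = mean(decision == "site"),
                            region = mean(decision == "region"),
                            unassigned = mean(decision == "unassigned"))
  attr(out, "tau") <- tau
  class(out) <- c("assignment_decisions", "data.frame")
  out
}

#' Per-area origin-composition summary
#'
#' Tabulates, for each adult sampling area, the counts and proportions of
#' adults by assigned origin (site, region or unassigned) -- the
#' contribution of each juvenile ground to each spawning aggregation.
#'
#' @param decisions an `assignment_decisions` table (must carry `area`).
#' @return data.frame with `area`, `assigned_to` (site/region label or
#'   `"unassigned"`), `n`, `proportion` (summing to 1 within each area).
#' @export
contribution_summary <- function(decisions) {
  lab <- ifelse(decisions$decision == "unassigned", "unassigned",
                decisions$assigned_to)
  tab <- table(area = decisions$area, assigned_to = lab)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  tot <- stats::ave(df$n, df$area, FUN = sum)
  df$proportion <- ifelse(tot > 0, df$n / tot, 0)
  df[df$n > 0 | TRUE, ][order(df$area, -df$n), ]
}

#' Per-area posterior origin contributions
#'
#' The model-based counterpart of [contribution_summary()]: averages the
#' posterior origin-probability rows of the adults within each sampling
#' area, giving each area's estimated origin mixture without thresholding.
#'
#' @param ar an `assignment_result`.
#' @return matrix (origin site x area) of mean posterior probabilities;
#'   columns sum to 1.
#' @export
posterior_contributions <- function(ar) {
  areas <- sort(unique(ar$area))
  out <- sapply(areas, function(a)
    colMeans(ar$prob[ar$area == a, , drop = FALSE]))
  matrix(out, ncol(ar$prob), length(areas),
         dimnames = list(colnames(ar$prob), areas))
}
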