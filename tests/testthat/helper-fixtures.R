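# shared fixture builders and independent oracles

.elements <- c("Mg", "Mn", "Ba", "Sr")

# dataset of log-normal site groups: mus = list of log-mean vectors (length 4)
make_site_dataset <- function(n_per_site, mus, sdlog = 0.3,
                              zone = "whole", stage = "juvenile",
                              sites = names(mus) %||% paste0("S", seq_along(mus)),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- lapply(seq_along(mus), function(i) {
    X <- exp(sapply(seq_along(.elements), function(j)
      stats::rnorm(n_per_site, mus[[i]][j], sdlog)))
    colnames(X) <- .elements
    cbind(data.frame(
      fish_id = sprintf("%s-%s-%03d", zone, sites[i], seq_len(n_per_site)),
      life_stage = stage, zone = zone, site = sites[i],
      lat = 50 + i, lon = 0, year_class = 2007L, batch = "b",
      stringsAsFactors = FALSE), X)
  })
  otolith_dataset(do.call(rbind, recs),
                  element_panel(.elements, units = "ug_g"))
}

make_adult_dataset <- function(X, area = "AREA") {
  colnames(X) <- .elements
  otolith_dataset(cbind(data.frame(
    fish_id = sprintf("ad-%03d", seq_len(nrow(X))),
    life_stage = "adult", zone = "milled_core", site = area,
    lat = NA_real_, lon = NA_real_, year_class = 2007L, batch = "b",
    stringsAsFactors = FALSE), X),
    element_panel(.elements, units = "ug_g"))
}

# --- independent oracles -------------------------------------------------

# Kruskal-Wallis H via the direct rank formula with tie correction
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair, computed from scratch
dunn_z_oracle <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  sigma2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
    (1 / sum(groups == g1) + 1 / sum(groups == g2))
  (mean(r[groups == g1]) - mean(r[groups == g2])) / sqrt(sigma2)
}

# Wilcoxon signed-rank exact p by full enumeration of sign assignments
wilcox_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- signs %*% r
  EV <- n * (n + 1) / 4
  mean(abs(V_all - EV) >= abs(V_obs - EV) - 1e-9)
}

# PAM exhaustive optimum
pam_oracle <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    o <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (o < best) best <- o
  }
  best
}

# adjusted Rand index from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2)); e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

rand_dissimilarity <- function(n) {
  M <- matrix(stats::runif(n * n), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a
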