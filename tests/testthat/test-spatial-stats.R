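test_that("Kruskal-Wallis H matches the direct rank-formula oracle", {
  set.seed(20)
  for (rep in 1:50) {
    g <- rep(1:3, each = 8)
    v <- round(stats::rnorm(24), 1)  # rounding forces ties
    if (length(unique(v)) == 1) next
    got <- kruskal_wallis(v, g)
    expect_equal(got$statistic, kw_oracle(v, g), tolerance = 1e-10)
    expect_equal(got$df, 2)
    expect_gte(got$p_value, 0); expect_lte(got$p_value, 1)
  }
  expect_equal(kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                              rep(1:3, each = 2))$statistic,
               kw_oracle(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2)),
               tolerance = 1e-10)
})

test_that("interleaved identical groups give a small H and large p", {
  v <- c(1, 3, 5, 7, 2, 4, 6, 8)
  g <- rep(c("a", "b"), each = 4)
  res <- kruskal_wallis(v, g)
  expect_gt(res$p_value, 0.5)
})

test_that("degenerate inputs raise errors", {
  expect_error(kruskal_wallis(rep(1, 6), rep(1:2, 3)), "identical")
  expect_error(kruskal_wallis(1:6, rep(1, 6)), "two groups")
  expect_error(spearman_trend(rep(1, 5), 1:5), "zero variance")
})

test_that("Dunn z values match an independently coded formula on tied data", {
  set.seed(21)
  for (rep in 1:50) {
    k <- sample(3:5, 1)
    g <- rep(letters[1:k], times = sample(4:8, k, replace = TRUE))
    v <- round(stats::rnorm(length(g)), 1)
    if (length(unique(v)) < 2) next
    res <- dunn_posthoc(v, g, adjust = "none")
    for (q in seq_len(nrow(res$pairs))) {
      expect_equal(res$pairs$z[q],
                   dunn_z_oracle(v, g, res$pairs$group1[q],
                                 res$pairs$group2[q]),
                   tolerance = 1e-9)
    }
    expect_equal(res$pairs$p_value,
                 2 * stats::pnorm(-abs(res$pairs$z)), tolerance = 1e-12)
  }
})

test_that("fully separated groups get distinct letters, null groups share one", {
  v <- c(1:15, 101:115, 1001:1015)
  g <- rep(c("a", "b", "c"), each = 15)
  res <- dunn_posthoc(v, g, adjust = "bonferroni")
  expect_true(all(res$pairs$p_adjusted < 0.05))
  expect_equal(length(unique(res$letters)), 3)
  expect_equal(unname(sort(nchar(res$letters))), c(1, 1, 1))
})

test_that("letter display shares a letter exactly for non-significant pairs", {
  set.seed(22)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    g <- rep(letters[1:k], each = 6)
    v <- stats::rnorm(length(g), mean = sample(0:3, k, TRUE)[as.integer(factor(g))])
    res <- dunn_posthoc(v, g, adjust = "holm")
    share <- function(a, b) {
      la <- strsplit(res$letters[[a]], "")[[1]]
      lb <- strsplit(res$letters[[b]], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (q in seq_len(nrow(res$pairs))) {
      expect_equal(share(res$pairs$group1[q], res$pairs$group2[q]),
                   res$pairs$p_adjusted[q] >= 0.05,
                   info = sprintf("rep %d pair %s-%s", rep,
                                  res$pairs$group1[q], res$pairs$group2[q]))
    }
  }
})

test_that("Spearman statistic equals the midrank correlation", {
  expect_equal(spearman_trend(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_trend(1:8, -(1:8)^3)$statistic, -1)
  set.seed(23)
  for (rep in 1:20) {
    x <- round(stats::rnorm(15), 1); y <- round(stats::rnorm(15), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_trend(x, y)$statistic,
                 stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("rank statistics are invariant to strictly monotone transforms", {
  set.seed(24)
  v <- stats::rlnorm(30); g <- rep(1:3, each = 10)
  for (f in list(log, sqrt, function(x) x^3)) {
    expect_equal(kruskal_wallis(f(v), g)$statistic,
                 kruskal_wallis(v, g)$statistic, tolerance = 1e-10)
  }
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  expect_equal(spearman_trend(exp(x), y)$statistic,
               spearman_trend(x, y)$statistic, tolerance = 1e-12)
})

test_that("matched-pair test: exact branch equals full sign enumeration", {
  set.seed(25)
  mus <- list(log(c(70, 5, 3, 1800)))
  for (rep in 1:10) {
    core <- make_site_dataset(8, mus, zone = "near_core")
    edge <- make_site_dataset(8, mus, zone = "edge")
    df <- rbind(as.data.frame(core), as.data.frame(edge))
    df$fish_id <- sub("^(near_core|edge)", "J", df$fish_id)
    ds <- otolith_dataset(df, attr(core, "panel"))
    res <- wilcoxon_paired_zones(ds, "Mn")
    expect_equal(res$method, "exact")
    d <- core$Mn - edge$Mn
    expect_equal(res$p_value, wilcox_exact_oracle(d), tolerance = 1e-10)
  }
})

test_that("a constant shift between zones is detected", {
  mus <- list(log(c(70, 5, 3, 1800)))
  core <- make_site_dataset(10, mus, zone = "near_core", seed = 26)
  df_e <- as.data.frame(core)
  df_e$zone <- "edge"
  df_e$Mn <- df_e$Mn + 1
  df <- rbind(as.data.frame(core), df_e)
  ds <- otolith_dataset(df, attr(core, "panel"))
  res <- wilcoxon_paired_zones(ds, "Mn")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$statistic, 0)  # core - edge all negative
  # all-zero differences are degenerate
  df_z <- df_e; df_z$Mn <- core$Mn
  dz <- otolith_dataset(rbind(as.data.frame(core), df_z),
                        attr(core, "panel"))
  expect_error(wilcoxon_paired_zones(dz, "Mn"), "degenerate")
})

test_that("spatial stats table reports every element with correct trend signs", {
  cfg <- scenario_preset("study_default")
  juv <- generate_juveniles(cfg, seed = 27)
  st <- spatial_stats_table(juv, zone = "edge")
  expect_setequal(st$omnibus$element, cfg$elements)
  expect_true(all(st$omnibus$p_value < 0.01))
  expect_lt(st$trend$rho[st$trend$element == "Mn"], 0)
  expect_gt(st$trend$rho[st$trend$element == "Ba"], 0)
})
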