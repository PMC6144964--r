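# small baselines used throughout: 4 log-normal elements per site
.mu0 <- log(c(70, 5, 3, 1800))

make_baseline <- function(n, shifts, sdlog = 0.3, seed = 1) {
  mus <- lapply(shifts, function(s) .mu0 + s)
  make_site_dataset(n, mus, sdlog = sdlog, zone = "whole", seed = seed)
}

test_that("identical baseline sites give near-uniform posteriors and few site calls", {
  # literally the same records at every site: the model is exactly
  # exchangeable over sites, so posteriors must be uniform up to MC error
  set.seed(60)
  Y <- exp(matrix(stats::rnorm(50 * 4, .mu0, 0.3), 50, 4, byrow = TRUE))
  recs <- do.call(rbind, lapply(1:4, function(i) {
    cbind(data.frame(fish_id = sprintf("S%d-%02d", i, 1:50),
                     life_stage = "juvenile", zone = "whole",
                     site = paste0("S", i), lat = 55, lon = 0,
                     year_class = 2007L, batch = "b"),
          as.data.frame(`colnames<-`(Y, .elements)))
  }))
  ds <- otolith_dataset(recs, element_panel(.elements, units = "ug_g"))
  set.seed(61)
  A <- exp(matrix(stats::rnorm(40 * 4, .mu0, 0.3), 40, 4, byrow = TRUE))
  adults <- make_adult_dataset(A)
  bm <- baseline_model(ds)
  ar <- fit_mixed_stock(bm, adults, chains = 2, iters = 1200, burn = 400,
                        thin = 2, seed = 62)
  expect_lt(max(abs(ar$prob - 0.25)), 0.1)
  expect_equal(unname(rowSums(ar$prob)), rep(1, 40), tolerance = 1e-9)
  rm <- region_map(colnames(ar$prob), paste0("R", 1:4))
  dec <- threshold_classify(ar, rm, tau = 0.5)
  expect_lt(attr(dec, "summary")[["site"]], 0.05)
})

test_that("adults from one well-separated site are assigned to it", {
  ds <- make_baseline(40, list(0, 5 * 0.3, 10 * 0.3), seed = 63)
  set.seed(64)
  A <- exp(matrix(stats::rnorm(30 * 4, .mu0 + 5 * 0.3, 0.3), 30, 4,
                  byrow = TRUE))
  adults <- make_adult_dataset(A)
  bm <- baseline_model(ds)
  ar <- fit_mixed_stock(bm, adults, chains = 2, iters = 1200, burn = 400,
                        thin = 2, seed = 65)
  expect_gte(mean(ar$prob[, 2]), 0.95)
})

test_that("posterior mixture recovers a known composition", {
  sep <- 2 * 0.3  # 2 pooled-SD spacing between neighbouring sites
  ds <- make_baseline(50, list(0, sep, 2 * sep), seed = 66)
  set.seed(67)
  pi_true <- c(0.6, 0.3, 0.1)
  org <- sample(1:3, 150, TRUE, pi_true)
  A <- exp(t(vapply(org, function(o)
    stats::rnorm(4, .mu0 + (o - 1) * sep, 0.3), numeric(4))))
  adults <- make_adult_dataset(A)
  bm <- baseline_model(ds)
  ar <- fit_mixed_stock(bm, adults, chains = 2, iters = 1500, burn = 500,
                        thin = 2, seed = 68)
  emp <- tabulate(org, 3) / 150
  expect_lt(max(abs(ar$pi$mean - emp)), 0.07)
  # reproducibility under the seed
  ar2 <- fit_mixed_stock(bm, adults, chains = 2, iters = 1500, burn = 500,
                         thin = 2, seed = 68)
  expect_identical(ar$prob, ar2$prob)
})

test_that("Dirichlet prior strength barely moves the recovered mixture", {
  sep <- 2 * 0.3
  ds <- make_baseline(50, list(0, sep, 2 * sep), seed = 69)
  set.seed(70)
  org <- sample(1:3, 120, TRUE, c(0.6, 0.3, 0.1))
  A <- exp(t(vapply(org, function(o)
    stats::rnorm(4, .mu0 + (o - 1) * sep, 0.3), numeric(4))))
  adults <- make_adult_dataset(A)
  pi_a1 <- fit_mixed_stock(baseline_model(ds, alpha = 1), adults,
                           chains = 1, iters = 1200, burn = 400, thin = 2,
                           seed = 71)$pi$mean
  pi_a01 <- fit_mixed_stock(baseline_model(ds, alpha = 0.1), adults,
                            chains = 1, iters = 1200, burn = 400, thin = 2,
                            seed = 71)$pi$mean
  expect_lt(max(abs(pi_a1 - pi_a01)), 0.03)
})

test_that("baseline model validates its inputs", {
  ds <- make_baseline(50, list(0, 1), seed = 72)
  expect_error(baseline_model(ds, nu0 = 2), "nu0")
  expect_error(baseline_model(ds, alpha = 0), "alpha")
  small <- make_baseline(2, list(0, 1), seed = 73)
  expect_error(baseline_model(small), "n >= 3")
  bm <- baseline_model(ds)
  # panel mismatch
  A <- exp(matrix(stats::rnorm(20, .mu0, 0.3), 5, 4, byrow = TRUE))
  adults <- make_adult_dataset(A)
  bad <- adults; attr(bad, "panel") <- element_panel(c("X1", "X2"))
  expect_error({
    names(bad)[9:12] <- c("X1", "X2", "X3", "X4")
    fit_mixed_stock(bm, bad)
  })
})

test_that("threshold decisions follow the site/region/unassigned rule", {
  prob <- rbind(a = c(0.6, 0.2, 0.2),
                b = c(0.4, 0.35, 0.25),
                c = c(0.34, 0.33, 0.33))
  colnames(prob) <- c("S1", "S2", "S3")
  rm12 <- region_map(c("S1", "S2", "S3"), c("R1", "R1", "R2"))
  dec <- threshold_classify(prob, rm12, tau = 0.5)
  expect_equal(dec$decision, c("site", "region", "region"))
  expect_equal(dec$assigned_to[1], "S1")
  expect_equal(dec$assigned_to[2], "R1")  # 0.4 + 0.35 = 0.75 > 0.5
  rm_all <- region_map(c("S1", "S2", "S3"), c("R1", "R2", "R3"))
  dec2 <- threshold_classify(prob, rm_all, tau = 0.5)
  expect_equal(dec2$decision[3], "unassigned")
  expect_error(threshold_classify(prob, rm12, tau = 1.5), "tau")
  s <- attr(dec2, "summary")
  expect_equal(unname(sum(s)), 1)
})

test_that("contribution summaries tabulate decisions exactly", {
  set.seed(74)
  dec <- data.frame(
    fish_id = sprintf("f%03d", 1:60),
    area = rep(c("N", "S"), each = 30),
    decision = sample(c("site", "region", "unassigned"), 60, TRUE),
    assigned_to = sample(c("S1", "S2", "R1"), 60, TRUE),
    probability = stats::runif(60), stringsAsFactors = FALSE)
  dec$assigned_to[dec$decision == "unassigned"] <- NA
  cs <- contribution_summary(dec)
  for (a in c("N", "S")) {
    sub <- cs[cs$area == a, ]
    expect_equal(sum(sub$proportion), 1, tolerance = 1e-12)
    lab <- ifelse(dec$decision == "unassigned", "unassigned",
                  dec$assigned_to)[dec$area == a]
    for (i in seq_len(nrow(sub)))
      expect_equal(sub$n[i], sum(lab == sub$assigned_to[i]))
  }
})

test_that("posterior contributions are column-stochastic per area", {
  ds <- make_baseline(30, list(0, 1), seed = 75)
  set.seed(76)
  A <- exp(matrix(stats::rnorm(20 * 4, .mu0, 0.3), 20, 4, byrow = TRUE))
  adults <- make_adult_dataset(A)
  adults$site <- rep(c("N", "S"), each = 10)
  ar <- fit_mixed_stock(baseline_model(ds), adults, chains = 1,
                        iters = 600, burn = 200, thin = 2, seed = 77)
  pc <- posterior_contributions(ar)
  expect_equal(unname(colSums(pc)), c(1, 1), tolerance = 1e-9)
  expect_equal(colnames(pc), c("N", "S"))
})

test_that("diagnostics: calibrated on independent draws, alarmed on stuck chains", {
  set.seed(78)
  # independent Dirichlet draws injected as 4 chains
  draws <- array(NA_real_, c(500, 3, 4))
  for (ch in 1:4) {
    g <- matrix(stats::rgamma(500 * 3, c(2, 3, 5)), 500, 3, byrow = TRUE)
    draws[, , ch] <- g / rowSums(g)
  }
  dimnames(draws) <- list(NULL, c("a", "b", "c"), NULL)
  d <- mcmc_diagnostics(draws)
  expect_true(all(d$rhat > 0.99 & d$rhat < 1.02))
  expect_true(all(d$ess <= 4 * 500 + 1e-9))
  # two chains stuck at different constants
  stuck <- array(c(rep(0.2, 500), rep(0.8, 500)), c(500, 1, 2))
  stuck <- stuck + array(stats::rnorm(1000, 0, 1e-4), c(500, 1, 2))
  expect_warning(ds2 <- mcmc_diagnostics(stuck), "R-hat")
  expect_gt(ds2$rhat, 1.1)
  # single chain: rhat unavailable, ess still reported
  one <- array(stats::runif(400), c(400, 1, 1))
  d1 <- mcmc_diagnostics(one)
  expect_true(is.na(d1$rhat))
  expect_true(is.finite(d1$ess))
})
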