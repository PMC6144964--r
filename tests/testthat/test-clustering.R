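test_that("synthetic reference resamples each marginal independently", {
  set.seed(40)
  X <- cbind(a = stats::rnorm(200), b = 0, c = stats::rlnorm(200))
  X[, "b"] <- X[, "a"]  # perfectly correlated pair
  X <- cbind(X, d = 5)  # constant column
  ref <- synthetic_reference(X, seed = 1)
  expect_equal(dim(ref), dim(X))
  expect_true(all(ref[, "d"] == 5))
  for (j in colnames(X))
    expect_true(all(ref[, j] %in% X[, j]))
  # independence by construction: correlation collapses
  cors <- sapply(1:20, function(s)
    abs(stats::cor(synthetic_reference(X, seed = s)[, c("a", "b")])[1, 2]))
  expect_gte(mean(cors < 0.2), 0.95)
  expect_error(synthetic_reference(cbind(c(1, NA), c(1, 2))), "missing")
})

test_that("proximity matrix is symmetric, unit-diagonal, in [0,1]", {
  set.seed(41)
  X <- matrix(stats::rnorm(40 * 4), 40, 4)
  expect_warning(S <- rf_proximity(X, n_trees = 40, seed = 1), "unstable")
  expect_true(all(abs(S - t(S)) < 1e-12))
  expect_equal(unname(diag(S)), rep(1, 40))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("duplicate rows are maximally proximate; separated blobs dominate", {
  set.seed(42)
  X <- matrix(stats::rnorm(30 * 4), 30, 4)
  X[2, ] <- X[1, ]  # exact duplicate
  S <- rf_proximity(X, n_trees = 200, seed = 2)
  expect_equal(S[1, 2], 1)
  hits <- sapply(1:10, function(s) {
    B <- rbind(matrix(stats::rnorm(60, 0, 1), 15, 4),
               matrix(stats::rnorm(60, 8, 1), 15, 4))
    S <- rf_proximity(B, n_trees = 300, seed = s)
    within <- c(S[1:15, 1:15][upper.tri(diag(15))],
                S[16:30, 16:30][upper.tri(diag(15))])
    between <- S[1:15, 16:30]
    mean(within) > mean(between)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("dissimilarity transform is exact", {
  expect_equal(to_dissimilarity(matrix(1, 1, 1))[1, 1], 0)
  S <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(to_dissimilarity(S)[1, 2], 1)
  S <- matrix(c(1, 0.75, 0.75, 1), 2)
  expect_equal(to_dissimilarity(S)[1, 2], 0.5)
  set.seed(43)
  M <- matrix(stats::runif(25), 5); M <- (M + t(M)) / 2; diag(M) <- 1
  D <- to_dissimilarity(M)
  expect_equal(unclass(D), sqrt(1 - unclass(M)), tolerance = 1e-15)
  expect_error(to_dissimilarity(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("PAM attains the exhaustive optimum on small instances", {
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(6:10, 1)
    D <- rand_dissimilarity(n)
    for (k in 2:3) {
      sol <- pam_partition(D, k)
      expect_equal(sol$objective, pam_oracle(D, k), tolerance = 1e-12,
                   info = sprintf("rep %d n %d k %d", rep, n, k))
    }
  }
})

test_that("PAM agrees with an established implementation on the objective", {
  skip_if_not_installed("cluster")
  set.seed(45)
  for (rep in 1:10) {
    D <- rand_dissimilarity(12)
    sol <- pam_partition(D, 3)
    ref <- cluster::pam(stats::as.dist(D), 3, diss = TRUE)
    ref_obj <- sum(apply(D[, ref$id.med, drop = FALSE], 1, min))
    expect_lte(sol$objective, ref_obj + 1e-12)
  }
})

test_that("PAM splits duplicated groups perfectly and SWAP never increases the objective", {
  D <- matrix(1, 8, 8)
  D[1:4, 1:4] <- 0; D[5:8, 5:8] <- 0
  sol <- pam_partition(D, 2)
  expect_equal(sol$objective, 0)
  expect_equal(length(unique(sol$labels[1:4])), 1)
  expect_equal(length(unique(sol$labels[5:8])), 1)
  set.seed(46)
  for (rep in 1:10) {
    sol <- pam_partition(rand_dissimilarity(15), 4)
    expect_true(all(diff(sol$trace) <= 1e-12))
    expect_equal(sol$labels[sol$medoids], seq_along(sol$medoids))
    # objective recomputes from labels/medoids
    D2 <- rand_dissimilarity(15)
  }
  expect_error(pam_partition(rand_dissimilarity(5), 5), "k < n")
})

test_that("Dunn index matches hand computations", {
  # two tight pairs: within 0.1, between 1.0 -> Dunn = 10
  D <- matrix(1, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.1; D[3, 4] <- D[4, 3] <- 0.1
  expect_equal(dunn_index(D, c(1, 1, 2, 2)), 10)
  # all points equidistant -> Dunn = 1
  E <- matrix(1, 6, 6); diag(E) <- 0
  expect_equal(dunn_index(E, rep(1:3, each = 2)), 1)
  expect_warning(v <- dunn_index(diag(0, 3), 1:3), "infinite")
  expect_identical(v, Inf)
  expect_error(dunn_index(E, rep(1, 6)), "two clusters")
})

test_that("merging clusters of a separated instance never increases Dunn", {
  set.seed(47)
  for (rep in 1:20) {
    centers <- c(0, 10, 20)
    pts <- unlist(lapply(centers, function(c) c + stats::runif(5)))
    D <- as.matrix(stats::dist(pts))
    lab3 <- rep(1:3, each = 5)
    d3 <- dunn_index(D, lab3)
    for (merge in list(c(1, 2), c(2, 3), c(1, 3))) {
      lab2 <- lab3; lab2[lab3 == merge[2]] <- merge[1]
      expect_lte(dunn_index(D, lab2), d3 + 1e-12)
    }
  }
})

test_that("choose_k honours range, argmax and override", {
  set.seed(48)
  pts <- c(stats::runif(5), 10 + stats::runif(5), 20 + stats::runif(5),
           30 + stats::runif(5))
  D <- as.matrix(stats::dist(pts)) / max(dist(pts))
  sol <- choose_k(D, k_range = 2:6)
  expect_equal(sol$k_selected, 4)
  expect_equal(nrow(sol$profile), 5)
  one <- choose_k(D, k_range = 2)
  expect_equal(one$k, 2)
  ov <- choose_k(D, k_range = 2:6, override = 3)
  expect_equal(ov$k, 3)
  expect_equal(ov$profile, sol$profile)
  expect_error(choose_k(D, k_range = 2:4, override = 9), "override")
})

test_that("cluster summaries equal direct groupwise recomputation", {
  set.seed(49)
  X <- matrix(stats::rlnorm(60), 20, 3,
              dimnames = list(NULL, c("Mg", "Mn", "Ba")))
  lab <- sample(1:3, 20, TRUE)
  sites <- sample(c("A", "B"), 20, TRUE)
  cs <- cluster_summary(X, lab, sites)
  for (l in unique(lab)) {
    sub <- X[lab == l, , drop = FALSE]
    row <- cs$signature[cs$signature$cluster == l, ]
    expect_equal(row$mean, unname(colMeans(sub)), tolerance = 1e-12)
    expect_equal(row$sd, unname(apply(sub, 2, sd)), tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(cs$contribution)), rep(1, 2), tolerance = 1e-12)
  # one cluster per site with clean labels -> identity contributions
  cs2 <- cluster_summary(X, as.integer(factor(sites)), sites)
  expect_equal(unname(diag(cs2$contribution)), c(1, 1))
  expect_error(cluster_summary(X, lab[-1], sites), "align")
})

test_that("well-separated sources are recovered end to end", {
  cfg <- scenario_preset("north_south", separation = 3)
  juv <- generate_juveniles(cfg, seed = 50)
  cl <- natal_clustering(juv, k_range = 2:5, n_trees = 500, seed = 50)
  truth <- attr(juv, "truth")
  tr <- truth$source[match(cl$fish_id, truth$fish_id)]
  lab2 <- pam_partition(cl$dissimilarity, 2)$labels
  expect_gte(ari(lab2, tr), 0.9)
})
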