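test_that("PC1 initialization splits each batch at its own median", {
  # one batch, scores [-2, -1, 1, 2]: median 0 separates pairs
  fake_pca <- list(scores = cbind(c(-2, -1, 1, 2)))
  train <- list(profile_batch = factor(rep("b1", 4)))
  expect_identical(initialize_clusters_pc1(train, fake_pca),
                   c(1L, 1L, 2L, 2L))

  # two batches offset by +/-100: both clusters must contain both batches
  fake_pca2 <- list(scores = cbind(c(-102, -101, -99, -98,
                                     98, 99, 101, 102)))
  train2 <- list(profile_batch = factor(rep(c("b1", "b2"), each = 4)))
  lab <- initialize_clusters_pc1(train2, fake_pca2)
  expect_identical(lab, c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L))
  for (cl in 1:2) {
    expect_setequal(unique(as.character(train2$profile_batch[lab == cl])),
                    c("b1", "b2"))
  }

  # all-equal scores: everything <= median goes to cluster 1
  fake_pca3 <- list(scores = cbind(rep(1, 5)))
  train3 <- list(profile_batch = factor(rep("b1", 5)))
  expect_identical(initialize_clusters_pc1(train3, fake_pca3),
                   rep(1L, 5))
})

test_that("split_clusters thresholds at the batch-wise median", {
  # single batch, p_max = [0.9, 0.8, 0.6, 0.5], median 0.7
  p <- cbind(c(0.9, 0.8, 0.6, 0.5), c(0.1, 0.2, 0.4, 0.5))
  lab <- split_clusters(rep(1L, 4), p, factor(rep("b", 4)))
  expect_identical(lab, c(2L, 2L, 1L, 1L))

  # singleton cluster: the member ties with its own median -> low side
  p1 <- cbind(0.8, 0.2)
  expect_identical(split_clusters(1L, p1, factor("b")), 1L)

  # two batches with disjoint probability ranges split internally
  p2 <- cbind(c(0.95, 0.9, 0.85, 0.8, 0.65, 0.6, 0.55, 0.5))
  p2 <- cbind(p2, 1 - p2)
  batches <- factor(rep(c("b1", "b2"), each = 4))
  lab2 <- split_clusters(rep(1L, 8), p2, batches)
  # per batch, the two highest go high: brute-force expectation
  expect_identical(lab2, c(2L, 2L, 1L, 1L, 2L, 2L, 1L, 1L))

  # labels are 2j-1 / 2j per source cluster j
  p3 <- cbind(c(0.9, 0.6, 0.8, 0.5), c(0.1, 0.4, 0.2, 0.5))
  lab3 <- split_clusters(c(1L, 1L, 2L, 2L), p3, factor(rep("b", 4)))
  expect_identical(lab3, c(2L, 1L, 4L, 3L))
})

test_that("training-subset sizes follow the floor(prop*|C|/B) rule", {
  set.seed(31)
  # cluster of 100 items, 3 batches, prop 0.3 -> 10 neighbours per rep
  n <- 100
  x <- matrix(rnorm(n * 4), n, 4)
  batches <- factor(rep(c("b1", "b2", "b3"), length.out = n))
  p <- cbind(runif(n))
  sub <- refine_training_subset(rep(1L, n), p, batches,
                                x = x, prop = 0.3)
  # 3 representatives + up to 10 neighbours each, overlaps allowed
  expect_lte(length(sub), 3 * 11)
  expect_gte(length(sub), 11)

  # |C| = 10, B = 4: floor(0.75) = 0 clamped to 1 neighbour
  n2 <- 10
  x2 <- matrix(rnorm(n2 * 3), n2, 3)
  b2 <- factor(rep(c("b1", "b2", "b3", "b4"), length.out = n2))
  sub2 <- refine_training_subset(rep(1L, n2), cbind(runif(n2)), b2,
                                 x = x2, prop = 0.3)
  expect_lte(length(sub2), 8)  # 4 reps + 4 single neighbours
})

test_that("training subset matches an exhaustive distance-sort oracle", {
  set.seed(32)
  n <- 24
  x <- matrix(rnorm(n * 3), n, 3)
  batches <- factor(rep(c("b1", "b2"), each = 12))
  assignments <- rep(1:2, times = 12)
  p <- matrix(runif(n * 2), n, 2)
  sub <- refine_training_subset(assignments, p, batches, x = x,
                                prop = 0.3)
  # oracle: per (cluster, batch) pick argmax prob, then its k nearest by
  # full distance sort
  expected <- integer(0)
  B <- 2
  for (j in 1:2) {
    members_j <- which(assignments == j)
    n_nb <- max(1L, floor(0.3 * length(members_j) / B))
    for (b in c("b1", "b2")) {
      idx <- members_j[batches[members_j] == b]
      if (!length(idx)) next
      rep_i <- idx[which.max(p[idx, j])]
      d <- sqrt(colSums((t(x) - x[rep_i, ])^2))
      d[rep_i] <- Inf
      expected <- c(expected, rep_i, order(d)[seq_len(n_nb)])
    }
  }
  expect_identical(sub, sort(unique(expected)))
})

test_that("divisive runs have doubling k, rows summing to one", {
  fx <- make_tiny_expression("balanced", seed = 41)
  params <- divisive_params(K = 4, L = 2,
                            icp = icp_params(seed = 41),
                            n_hvgs = 120, n_groups = 40, n_pcs = 10)
  res <- run_divisive_icp(fx$x, fx$meta, params)
  expect_s3_class(res, "multi_run_result")
  for (l in seq_along(res$runs)) {
    ks <- vapply(res$runs[[l]], function(rr) rr$state$k, integer(1))
    expect_true(all(diff(ks) >= 0))  # never decreases across rounds
    for (rr in res$runs[[l]]) {
      expect_lte(rr$state$k, 2^rr$q)
      expect_lt(max(abs(rowSums(rr$cell_probs) - 1)), 1e-8)
      expect_lt(max(abs(rowSums(rr$train_probs) - 1)), 1e-8)
    }
  }
})

test_that("the divisive ensemble is reproducible for a fixed seed", {
  fx <- make_tiny_expression("balanced", seed = 42)
  params <- divisive_params(K = 4, L = 2, icp = icp_params(seed = 7),
                            n_hvgs = 100, n_groups = 30, n_pcs = 8)
  r1 <- run_divisive_icp(fx$x, fx$meta, params)
  r2 <- run_divisive_icp(fx$x, fx$meta, params)
  expect_identical(r1$rng_seeds, r2$rng_seeds)
  expect_identical(r1$kept_runs, r2$kept_runs)
  for (l in seq_along(r1$runs)) {
    for (q in seq_along(r1$runs[[l]])) {
      expect_identical(r1$runs[[l]][[q]]$cell_probs,
                       r2$runs[[l]][[q]]$cell_probs)
      expect_identical(r1$runs[[l]][[q]]$state,
                       r2$runs[[l]][[q]]$state)
    }
  }
})

test_that("runs differ from one another and invalid K is rejected", {
  fx <- make_tiny_expression("balanced", seed = 43)
  params <- divisive_params(K = 4, L = 2, icp = icp_params(seed = 9),
                            n_hvgs = 100, n_groups = 30, n_pcs = 8)
  res <- run_divisive_icp(fx$x, fx$meta, params)
  p1 <- res$runs[[1]][[length(res$runs[[1]])]]$cell_probs
  p2 <- res$runs[[2]][[length(res$runs[[2]])]]$cell_probs
  expect_false(isTRUE(all.equal(p1, p2)))  # independent runs
  expect_error(divisive_params(K = 6), "power of two")
  expect_error(divisive_params(K = 1), "power of two")
})

test_that("median assignment probability does not rise across rounds", {
  fx <- make_tiny_expression("balanced", seed = 44)
  params <- divisive_params(K = 8, L = 2, icp = icp_params(seed = 3),
                            n_hvgs = 120, n_groups = 40, n_pcs = 10)
  res <- run_divisive_icp(fx$x, fx$meta, params)
  for (l in res$kept_runs) {
    med <- vapply(res$runs[[l]], function(rr) {
      stats::median(apply(rr$cell_probs, 1, max))
    }, numeric(1))
    if (length(med) > 1) {
      expect_true(all(diff(med) <= 0.05))
    }
  }
})

test_that("batch-free mode runs without using batch labels", {
  fx <- make_tiny_expression("trajectory", seed = 45)
  params <- divisive_params(K = 4, L = 2, icp = icp_params(seed = 5),
                            divisive_method = "cluster",
                            n_hvgs = 100, n_groups = 30, n_pcs = 8)
  res <- run_divisive_icp(fx$x, fx$meta, params)
  expect_gte(length(res$kept_runs), 1)
  final <- res$runs[[res$kept_runs[1]]]
  expect_equal(final[[length(final)]]$q, 2L)
})
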