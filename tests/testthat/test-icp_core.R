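test_that("adjusted Rand index matches hand computations", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "b", "a"), c(5, 2, 5)), 1)
  # classic anti-correlated 2x2 case: ARI = -0.5 from the contingency
  # formula: (0 - 2/3) / (2 - 2/3)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI equals independent implementations on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    a <- sample(1:sample(2:6, 1), n, replace = TRUE)
    b <- sample(1:sample(2:6, 1), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("separable blobs are classified perfectly by the L1 OVR fit", {
  blobs <- make_blobs(25, d = 4, sep = 8, seed = 2)
  model <- fit_ovr_l1(blobs$x, blobs$labels, icp_params(cost = 1))
  p <- predict_probabilities(model, blobs$x)
  expect_equal(project_clustering(p), blobs$labels)
  expect_equal(dim(model$coefficients), c(2L, 5L))
})

test_that("an all-zero feature gets an exactly zero L1 coefficient", {
  blobs <- make_blobs(20, d = 3, seed = 3)
  x <- cbind(blobs$x, dead = 0)
  model <- fit_ovr_l1(x, blobs$labels, icp_params(cost = 0.5))
  expect_identical(unname(model$coefficients[, "dead"]), c(0, 0))
})

test_that("an overwhelming penalty shrinks all coefficients to zero", {
  blobs <- make_blobs(20, d = 4, seed = 4)
  model <- fit_ovr_l1(blobs$x, blobs$labels, icp_params(cost = 1e-6))
  expect_true(all(model$coefficients[, -1] == 0))
  # predictions then reflect class priors only: uniform rows here
  p <- predict_probabilities(model, blobs$x)
  expect_lt(max(abs(p - 0.5)), 1e-6)
})

test_that("the L1 solution satisfies the KKT subgradient condition", {
  blobs <- make_blobs(30, d = 6, sep = 3, seed = 8)
  params <- icp_params(cost = 0.3)
  model <- fit_ovr_l1(blobs$x, blobs$labels, params)
  lambda <- 1 / params$cost  # penalty weight on the sum-loss scale
  for (j in 1:2) {
    w <- model$coefficients[j, -1]
    b0 <- model$coefficients[j, 1]
    y <- as.integer(blobs$labels == j)
    mu <- 1 / (1 + exp(-(blobs$x %*% w + b0)))
    grad <- drop(crossprod(blobs$x, mu - y))  # d(sum log-loss)/dw
    at_zero <- w == 0
    expect_true(all(abs(grad[at_zero]) <= lambda + 1e-4))
    if (any(!at_zero)) {
      expect_equal(unname(grad[!at_zero]),
                   unname(-lambda * sign(w[!at_zero])), tolerance = 1e-2)
    }
  }
})

test_that("cluster collapse in training labels raises a structured error", {
  blobs <- make_blobs(10, d = 3, seed = 5)
  expect_error(fit_ovr_l1(blobs$x, rep(1L, 20), icp_params()),
               "cluster collapse")
  expect_error(fit_ovr_l1(blobs$x, rep(c(1L, 3L), each = 10),
                          icp_params()),
               "cluster collapse")
})

test_that("probability rows sum to one and argmax matches a brute scan", {
  set.seed(6)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    m <- sample(3:8, 1)
    model <- structure(list(
      coefficients = matrix(rnorm(k * (m + 1)), k, m + 1,
                            dimnames = list(NULL,
                                            c("(Intercept)",
                                              paste0("f", 1:m)))),
      cost = 1, penalty = "L1", feature_ids = paste0("f", 1:m),
      classes = 1:k), class = "ovr_logistic")
    x <- matrix(rnorm(12 * m), 12, m,
                dimnames = list(NULL, paste0("f", 1:m)))
    p <- predict_probabilities(model, x)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-8)
    raw <- 1 / (1 + exp(-cbind(1, x) %*% t(model$coefficients)))
    for (i in 1:12) {
      expect_equal(project_clustering(p)[i], which.max(raw[i, ]))
    }
  }
})

test_that("mirror-symmetric two-class model reduces to a single sigmoid", {
  w <- c(1, -2, 0.5)
  model <- structure(list(
    coefficients = rbind(c(0, w), c(0, -w)),
    cost = 1, penalty = "L1", feature_ids = paste0("f", 1:3),
    classes = 1:2), class = "ovr_logistic")
  colnames(model$coefficients) <- c("(Intercept)", paste0("f", 1:3))
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("f", 1:3)))
  p <- predict_probabilities(model, x)
  # sigma(eta) + sigma(-eta) = 1, so the normalized row is just sigma(eta)
  eta <- drop(x %*% w)
  expect_equal(p[, 1], stats::plogis(eta), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  # x = 0 with zero intercepts: uniform row
  p0 <- predict_probabilities(model, matrix(0, 1, 3,
    dimnames = list(NULL, paste0("f", 1:3))))
  expect_equal(drop(p0), c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("argmax ties break to the lowest cluster index", {
  p <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.3, 0.3))
  expect_identical(project_clustering(p), c(2L, 1L, 1L))
})

test_that("icp_iterate converges on well-separated blobs", {
  blobs <- make_blobs(30, d = 5, sep = 7, seed = 9)
  res <- icp_iterate(blobs$x, factor(rep("b", 60)), blobs$labels,
                     icp_params(cost = 1, seed = 1))
  expect_s3_class(res$state, "clustering_state")
  expect_gte(utils::tail(res$state$ari_history, 1), 0.99)
  expect_equal(adjusted_rand_index(res$state$assignments, blobs$labels), 1)
  expect_lt(max(abs(rowSums(res$probs) - 1)), 1e-8)
})

test_that("identical items exhaust the reiteration budget and keep init", {
  x <- matrix(1, 12, 3, dimnames = list(NULL, paste0("f", 1:3)))
  init <- rep(1:2, each = 6)
  res <- icp_iterate(x, factor(rep("b", 12)), init,
                     icp_params(r = 3, cost = 1))
  expect_identical(res$state$assignments, init)
  expect_length(res$state$ari_history, 0)
  expect_equal(res$state$reiterations_used, 3L)
  expect_null(res$model)
})

test_that("max_iter = 1 performs exactly one fit/project cycle", {
  blobs <- make_blobs(15, d = 4, sep = 6, seed = 10)
  res <- icp_iterate(blobs$x, factor(rep("b", 30)), blobs$labels,
                     icp_params(max_iter = 1, cost = 1))
  expect_equal(res$state$epoch, 1L)
  expect_lte(length(res$state$ari_history), 1L)
})

test_that("accepted-epoch ARI history is strictly increasing and bounded", {
  fx <- make_tiny_expression("balanced", seed = 21)
  hv <- select_hvgs(fx$x, 80)
  ts <- build_training_set(fx$x, fx$meta, hv, n_groups = 30, n_pcs = 8,
                           seed = 2)
  pca <- compute_pca(ts$profiles, n_pcs = 2)
  init <- initialize_clusters_pc1(ts, pca)
  res <- icp_iterate(ts$profiles, ts$profile_batch, init,
                     icp_params(seed = 2))
  h <- res$state$ari_history
  expect_gt(length(h), 0)
  expect_true(all(diff(h) > 0))
  expect_true(all(h <= 1 + 1e-12))
  expect_lte(res$state$epoch, 200L)
})

test_that("icp_iterate is reproducible for a fixed seed", {
  fx <- make_tiny_expression("balanced", seed = 22)
  hv <- select_hvgs(fx$x, 60)
  ts <- build_training_set(fx$x, fx$meta, hv, n_groups = 20, n_pcs = 6,
                           seed = 4)
  pca <- compute_pca(ts$profiles, n_pcs = 2)
  init <- initialize_clusters_pc1(ts, pca)
  r1 <- icp_iterate(ts$profiles, ts$profile_batch, init, icp_params())
  r2 <- icp_iterate(ts$profiles, ts$profile_batch, init, icp_params())
  expect_identical(r1$state, r2$state)
  expect_identical(r1$model$coefficients, r2$model$coefficients)
})
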