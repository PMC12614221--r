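#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the
#' two label vectors: 1 for identical partitions (up to relabeling),
#' around 0 for independent random labels.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single numeric in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors differ in length (", length(a), " vs ",
         length(b), ")")
  }
  if (length(a) < 2L) stop("need at least 2 items")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(as.numeric(tab)))
  sum_a <- sum(comb2(as.numeric(rowSums(tab))))
  sum_b <- sum(comb2(as.numeric(colSums(tab))))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' ICP parameter set
#'
#' @param r Maximum reiterations without ARI improvement before a round
#'   stops (default 5).
#' @param max_iter Hard cap on epochs per round (default 200).
#' @param cost Inverse regularization strength of the L1 logistic fits
#'   (liblinear-style `C`; larger = weaker penalty).  Default 0.3.
#' @param train_knn_prop Proportionality constant for the batch-balanced
#'   training-subset size (default 0.3).
#' @param ari_cutoff Runs whose terminal-round ARI falls below this are
#'   excluded from downstream concatenation (default 0.3).
#' @param allow_free_k Drop clusters that lose all members instead of
#'   rejecting the epoch (default TRUE).
#' @param penalty `"L1"` (default) or `"L2"`.
#' @param seed Integer seed.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(r = 5, max_iter = 200, cost = 0.3,
                       train_knn_prop = 0.3, ari_cutoff = 0.3,
                       allow_free_k = TRUE, penalty = c("L1", "L2"),
                       seed = 1L) {
  penalty <- match.arg(penalty)
  stopifnot(r >= 1, max_iter >= 1, cost > 0,
            train_knn_prop > 0, train_knn_prop < 1)
  structure(list(r = as.integer(r), max_iter = as.integer(max_iter),
                 cost = cost, train_knn_prop = train_knn_prop,
                 ari_cutoff = ari_cutoff, allow_free_k = allow_free_k,
                 penalty = penalty, seed = as.integer(seed)),
            class = "icp_params")
}

#' Fit one-vs-rest regularized logistic models
#'
#' One binary L1- (or L2-) penalized logistic regression per cluster,
#' fitted sequentially.  The penalty is parameterized by the
#' liblinear-style cost `C`; the elastic-net solver's per-observation
#' penalty weight is `1 / (C * n_train)` so the optimized objective is
#' equivalent to `sum log-loss + (1/C) * ||w||_1`.
#'
#' @param x_train Items x features numeric matrix.
#' @param y_train Integer cluster labels in `1..k`.
#' @param params An [icp_params()].
#' @return A list of class `ovr_logistic`: `coefficients` (k x (m+1),
#'   intercept first), `cost`, `penalty`, `feature_ids`, `classes`.
#' @export
fit_ovr_l1 <- function(x_train, y_train, params = icp_params()) {
  x_train <- as.matrix(x_train)
  classes <- sort(unique(y_train))
  if (length(classes) < 2L) {
    stop("cluster collapse: fewer than 2 classes present in training labels")
  }
  k <- max(classes)
  if (!setequal(classes, seq_len(k))) {
    stop("cluster collapse: classes ",
         paste(setdiff(seq_len(k), classes), collapse = ", "),
         " vanished from training labels")
  }
  n <- nrow(x_train)
  lambda_target <- 1 / (params$cost * n)
  # short warm-start path down to the target improves convergence stability
  lambda_path <- lambda_target * c(64, 16, 4, 1)
  alpha <- if (params$penalty == "L1") 1 else 0
  coefs <- matrix(0, k, ncol(x_train) + 1L)
  for (j in seq_len(k)) {
    y <- as.integer(y_train == j)
    fit <- withCallingHandlers(
      glmnet::glmnet(x_train, y, family = "binomial", alpha = alpha,
                     lambda = lambda_path, standardize = FALSE,
                     thresh = 1e-7, maxit = 50000),
      warning = function(w) {
        # small one-vs-rest classes are routine for balanced subsets, and
        # a truncated lambda path still yields a usable deterministic fit
        if (grepl("fewer than 8|lambda value not reached",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    beta <- stats::coef(fit, s = lambda_target, exact = FALSE)
    coefs[j, ] <- as.numeric(beta)
  }
  colnames(coefs) <- c("(Intercept)", colnames(x_train))
  structure(list(coefficients = coefs, cost = params$cost,
                 penalty = params$penalty,
                 feature_ids = colnames(x_train),
                 classes = seq_len(k)),
            class = "ovr_logistic")
}

#' Predict cluster assignment probabilities
#'
#' Per-class sigmoid scores of the one-vs-rest models, normalized per item
#' to sum to one.
#'
#' @param model An `ovr_logistic` from [fit_ovr_l1()].
#' @param x Items x features matrix whose columns cover the model's
#'   `feature_ids` (matched by name).
#' @return Items x k probability matrix; rows sum to 1.
#' @export
predict_probabilities <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model$feature_ids, colnames(x))
  if (length(missing)) {
    stop("features required by the model are absent: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- x[, model$feature_ids, drop = FALSE]
  eta <- cbind(1, x) %*% t(model$coefficients)
  p <- 1 / (1 + exp(-eta))
  p <- p / rowSums(p)
  rownames(p) <- rownames(x)
  colnames(p) <- paste0("cluster", seq_len(ncol(p)))
  p
}

#' Assign items to their highest-probability cluster
#'
#' Row-wise argmax with exact ties broken towards the lowest cluster
#' index.
#'
#' @param p Items x k probability matrix.
#' @return Integer label vector in `1..k`.
#' @export
project_clustering <- function(p) {
  max.col(p, ties.method = "first")
}

#' Run the ICP inner loop on a working set
#'
#' Alternates fitting one-vs-rest logistic models on the current cluster
#' labels with re-labelling the working set by the models' predictions.
#' An epoch is accepted when the adjusted Rand index between the current
#' clustering and its projection strictly exceeds the best accepted value
#' so far (initialized at 0); otherwise the same clustering is retried, up
#' to `params$r` consecutive failures or `params$max_iter` total epochs.
#'
#' @param x_work Items x features working matrix (the objects being
#'   clustered, typically averaged training profiles).
#' @param work_batches Factor of batch labels per working item.
#' @param init Integer initial labels over `x_work` rows (k >= 2 distinct).
#' @param params An [icp_params()].
#' @param subset_fn Optional callback `function(assignments, probs)`
#'   returning the training-item indices for epochs `t > 1`; epoch 1
#'   always trains on the full working set.  `NULL` trains on everything.
#' @return A list: `state` (class `clustering_state`: `assignments`, `k`,
#'   `epoch`, `ari_history`, `reiterations_used`), `model` (accepted
#'   `ovr_logistic` or NULL if no epoch was accepted), `probs` (accepted
#'   probability matrix or NULL).
#' @export
icp_iterate <- function(x_work, work_batches, init, params = icp_params(),
                        subset_fn = NULL) {
  n <- nrow(x_work)
  stopifnot(length(init) == n)
  assignments <- .compact_labels(as.integer(init))
  if (length(unique(assignments)) < 2L) {
    stop("initial clustering must contain at least 2 clusters")
  }
  best_ari <- 0
  ari_history <- numeric(0)
  best_model <- NULL
  best_probs <- NULL
  best_assign <- assignments
  reiter <- 0L
  epoch <- 0L
  cur_probs <- NULL
  while (epoch < params$max_iter && reiter < params$r) {
    epoch <- epoch + 1L
    if (epoch > 1L && !is.null(subset_fn) && !is.null(cur_probs)) {
      subset <- subset_fn(assignments, cur_probs)
    } else {
      subset <- seq_len(n)
    }
    model <- tryCatch(
      fit_ovr_l1(x_work[subset, , drop = FALSE], assignments[subset],
                 params),
      error = function(e) e)
    if (inherits(model, "error")) {
      reiter <- reiter + 1L
      next
    }
    probs <- predict_probabilities(model, x_work)
    proj <- project_clustering(probs)
    k_now <- max(assignments)
    missing <- setdiff(seq_len(k_now), unique(proj))
    if (length(missing) && !params$allow_free_k) {
      reiter <- reiter + 1L
      next
    }
    ari <- adjusted_rand_index(assignments, proj)
    if (ari > best_ari) {
      best_ari <- ari
      ari_history <- c(ari_history, ari)
      u <- sort(unique(proj))
      assignments <- match(proj, u)
      best_assign <- assignments
      best_model <- model
      best_probs <- probs
      # columns re-aligned to the compacted labels for the subset callback
      cur_probs <- probs[, u, drop = FALSE]
      reiter <- 0L
      if (length(unique(assignments)) < 2L) break  # collapsed to one cluster
    } else {
      reiter <- reiter + 1L
      cur_probs <- probs
    }
  }
  state <- structure(list(assignments = best_assign,
                          k = max(best_assign),
                          epoch = epoch,
                          ari_history = ari_history,
                          reiterations_used = reiter),
                     class = "clustering_state")
  list(state = state, model = best_model, probs = best_probs)
}

# Relabel to consecutive integers 1..k preserving order of first appearance
# of the sorted original labels.
.compact_labels <- function(labels) {
  u <- sort(unique(labels))
  match(labels, u)
}
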