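#' Parameters of the divisive ICP ensemble
#'
#' @param K Target number of clusters; must be a power of two (default 16).
#' @param L Number of independent ICP runs (default 50).
#' @param icp An [icp_params()] controlling each inner loop.
#' @param divisive_method `"pc1_batch"` computes initialization and
#'   splitting medians batch-wise; `"cluster"` computes them globally
#'   (single-batch / batch-free mode).
#' @param n_hvgs Highly variable features used throughout (default 2000).
#' @param n_groups Training groups per batch (default 500).
#' @param n_pcs Principal components for the grouping space (default 30).
#' @param n_threads Reserved for parallel execution of runs; runs are
#'   seeded independently and order-independent (default 1).
#' @return A list of class `divisive_params`.
#' @export
divisive_params <- function(K = 16, L = 50, icp = icp_params(),
                            divisive_method = c("pc1_batch", "cluster"),
                            n_hvgs = 2000, n_groups = 500, n_pcs = 30,
                            n_threads = 1) {
  divisive_method <- match.arg(divisive_method)
  Q <- log2(K)
  if (K < 2 || Q != round(Q)) {
    stop("`K` must be a power of two >= 2, got ", K)
  }
  stopifnot(L >= 1)
  structure(list(K = as.integer(K), Q = as.integer(Q), L = as.integer(L),
                 icp = icp, divisive_method = divisive_method,
                 n_hvgs = as.integer(n_hvgs),
                 n_groups = as.integer(n_groups),
                 n_pcs = as.integer(n_pcs),
                 n_threads = as.integer(n_threads)),
            class = "divisive_params")
}

#' Initialize two clusters from batch-wise PC1 medians
#'
#' Profiles at or below their batch's median PC1 score form cluster 1,
#' the rest cluster 2.  A deliberately rough but meaningful starting
#' partition that the ICP loop then refines.
#'
#' @param train A `training_set` (or any object with `$profiles` and
#'   `$profile_batch`).
#' @param pca A `pca_model` fitted on the profiles (standardized); only
#'   PC1 scores are used.
#' @param batches Optional batch factor overriding `train$profile_batch`
#'   (use a single level for batch-free initialization).
#' @return Integer vector of 1/2 labels per profile.
#' @export
initialize_clusters_pc1 <- function(train, pca, batches = NULL) {
  if (is.null(batches)) batches <- train$profile_batch
  s <- pca$scores[, 1L]
  labels <- integer(length(s))
  for (b in unique(batches)) {
    idx <- which(batches == b)
    eta <- stats::median(s[idx])
    labels[idx] <- ifelse(s[idx] <= eta, 1L, 2L)
  }
  labels
}

#' Split every cluster at batch-wise medians of assignment probability
#'
#' For each cluster `j` and batch `b`, the batch-specific median of the
#' members' maximum assignment probabilities is the threshold: members at
#' or below it go to the low child (`2j - 1`), the rest to the high child
#' (`2j`).  Degenerate clusters (all members on one side in every batch)
#' pass through as a single child.
#'
#' @param assignments Integer cluster labels per item (or a
#'   `clustering_state`).
#' @param p Items x k probability matrix; row maxima are the assignment
#'   probabilities.
#' @param batches Batch factor per item (single level for global
#'   splitting).
#' @return Integer label vector with values in `{2j-1, 2j}`; not
#'   compacted, so callers see which children are empty.
#' @export
split_clusters <- function(assignments, p, batches) {
  if (inherits(assignments, "clustering_state")) {
    assignments <- assignments$assignments
  }
  pmax_i <- apply(p, 1L, max)
  out <- integer(length(assignments))
  for (j in sort(unique(assignments))) {
    members_j <- which(assignments == j)
    for (b in unique(batches[members_j])) {
      idx <- members_j[batches[members_j] == b]
      tau <- stats::median(pmax_i[idx])
      out[idx] <- ifelse(pmax_i[idx] <= tau, 2L * j - 1L, 2L * j)
    }
  }
  out
}

#' Select the batch-balanced training subset for one epoch
#'
#' For every (cluster, batch) pair with members, the member with the
#' highest assignment probability for that cluster is the representative;
#' its `max(1, floor(prop * |C_j| / B))` nearest neighbours among all
#' items (Euclidean, full feature space, cross-batch by design) join it.
#' The returned subset is the union of representatives and neighbours.
#'
#' @param assignments Integer cluster labels (or a `clustering_state`).
#' @param p Items x k probability matrix aligned with `assignments`
#'   (column `j` is the probability of cluster `j`).
#' @param batches Batch factor per item.
#' @param x Items x features matrix for the neighbour search (ignored if
#'   `dist2` is given).
#' @param prop Proportionality constant (default 0.3).
#' @param dist2 Optional precomputed items x items squared-distance
#'   matrix.
#' @return Sorted integer vector of item indices.
#' @export
refine_training_subset <- function(assignments, p, batches, x = NULL,
                                   prop = 0.3, dist2 = NULL) {
  if (inherits(assignments, "clustering_state")) {
    assignments <- assignments$assignments
  }
  if (is.null(dist2)) {
    if (is.null(x)) stop("either `x` or `dist2` is required")
    dist2 <- .pairwise_sqdist(as.matrix(x))
  }
  B <- nlevels(factor(batches))
  selected <- integer(0)
  for (j in sort(unique(assignments))) {
    members_j <- which(assignments == j)
    n_nb <- max(1L, floor(prop * length(members_j) / B))
    for (b in unique(batches[members_j])) {
      idx <- members_j[batches[members_j] == b]
      pj <- if (j <= ncol(p)) p[idx, j] else apply(p[idx, , drop = FALSE],
                                                  1L, max)
      rep_i <- idx[which.max(pj)]
      d <- dist2[rep_i, ]
      d[rep_i] <- Inf
      nb <- order(d)[seq_len(min(n_nb, length(d) - 1L))]
      selected <- c(selected, rep_i, nb)
    }
  }
  sort(unique(selected))
}

.pairwise_sqdist <- function(x) {
  sq <- rowSums(x^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0
  d
}

#' Run the full divisive ICP ensemble
#'
#' Builds the batch-balanced training set of averaged profiles, then runs
#' `L` independently seeded divisive ICP runs.  Each run starts from a
#' batch-wise PC1 median split and proceeds through `log2(K)` rounds,
#' doubling the cluster count by splitting at batch-wise probability
#' medians, with the inner loop retraining on batch-balanced subsets.
#' After the rounds, every cell is scored against every round's model.
#'
#' @param x An [expression_matrix()] (log-normalized).
#' @param meta A [cell_metadata()] for the cells of `x`.  Ignored batch
#'   structure in `divisive_method = "cluster"` mode.
#' @param params A [divisive_params()].
#' @return A list of class `multi_run_result`: `runs` (list of runs, each
#'   a list of per-round lists with `q`, `model`, `train_probs`,
#'   `cell_probs`, `state`), `params`, `kept_runs`, `terminal_ari`,
#'   `rng_seeds`, `feature_ids`, `cell_ids`, `training` (the
#'   `training_set`).
#' @export
run_divisive_icp <- function(x, meta, params = divisive_params()) {
  meta <- align_metadata(x, meta)
  meta$batch <- droplevels(meta$batch)  # stale levels after subsetting
  if (params$divisive_method == "pc1_batch" &&
      nlevels(meta$batch) < 1L) {
    stop("batch labels required for divisive_method = 'pc1_batch'")
  }
  seed <- params$icp$seed
  n_hvgs <- min(params$n_hvgs, ncol(x))
  hvgs <- select_hvgs(x, n = n_hvgs)
  x_cells <- unclass(x)[, hvgs$feature_id, drop = FALSE]
  # the cell-space PCA for grouping is deterministic and shared; the
  # k-means++ grouping itself is redrawn per run, which is what makes the
  # L runs independent
  cell_pca <- compute_pca(x_cells, n_pcs = params$n_pcs,
                          standardize = TRUE)
  prop <- params$icp$train_knn_prop
  rng_seeds <- vapply(seq_len(params$L),
                      function(l) .derive_seed(seed, 100000L + l),
                      integer(1))
  runs <- vector("list", params$L)
  terminal_ari <- numeric(params$L)
  train_first <- NULL
  for (l in seq_len(params$L)) {
    train <- .group_profiles(x_cells, meta, cell_pca$scores,
                             params$n_groups, rng_seeds[l])
    if (is.null(train_first)) train_first <- train
    x_work <- train$profiles
    work_batches <- if (params$divisive_method == "cluster") {
      factor(rep("all", nrow(x_work)))
    } else {
      train$profile_batch
    }
    pca_prof <- compute_pca(x_work, n_pcs = min(2L, nrow(x_work) - 1L),
                            standardize = TRUE)
    dist2 <- .pairwise_sqdist(x_work)
    subset_fn <- function(assignments, probs) {
      refine_training_subset(assignments, probs, work_batches,
                             prop = prop, dist2 = dist2)
    }
    set.seed(rng_seeds[l])
    rounds <- list()
    init <- initialize_clusters_pc1(train, pca_prof,
                                    batches = work_batches)
    for (q in seq_len(params$Q)) {
      res <- icp_iterate(x_work, work_batches, init, params$icp,
                         subset_fn = subset_fn)
      if (is.null(res$model)) break  # no epoch accepted; run ends here
      rounds[[q]] <- list(q = q, model = res$model,
                          train_probs = res$probs,
                          cell_probs = NULL,
                          state = res$state)
      if (q < params$Q) {
        init <- split_clusters(res$state$assignments, res$probs,
                               work_batches)
        if (length(unique(init)) < 2L) break
      }
    }
    if (length(rounds)) {
      last <- rounds[[length(rounds)]]
      terminal_ari[l] <- if (length(last$state$ari_history)) {
        utils::tail(last$state$ari_history, 1L)
      } else 0
      for (q in seq_along(rounds)) {
        rounds[[q]]$cell_probs <-
          predict_probabilities(rounds[[q]]$model, x_cells)
      }
    }
    runs[[l]] <- rounds
  }
  complete <- vapply(runs, length, integer(1)) == params$Q
  kept <- which(complete & terminal_ari >= params$icp$ari_cutoff)
  if (!length(kept)) {
    # never drop everything silently: fall back to the completed runs, or
    # all runs with any accepted round
    kept <- which(complete)
    if (!length(kept)) kept <- which(vapply(runs, length, integer(1)) > 0L)
    if (!length(kept)) stop("no ICP run accepted a single epoch")
    warning("all runs fell below ari_cutoff = ", params$icp$ari_cutoff,
            "; keeping ", length(kept), " completed run(s) instead")
  }
  structure(list(runs = runs, params = params, kept_runs = kept,
                 terminal_ari = terminal_ari, rng_seeds = rng_seeds,
                 feature_ids = hvgs$feature_id,
                 cell_ids = rownames(x), training = train_first),
            class = "multi_run_result")
}
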