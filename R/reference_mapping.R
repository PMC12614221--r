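#' Build an annotated reference model for label transfer
#'
#' Runs the divisive ICP ensemble on a labelled reference dataset,
#' concatenates the cluster probability tables and fits the integrated
#' embedding, retaining everything needed to project query cells into the
#' same space: the per-round models, the probability column statistics
#' and loadings, and the reference labels and scores.
#'
#' @param x_ref Reference [expression_matrix()] (log-normalized).
#' @param meta Reference [cell_metadata()]; the `label` column is
#'   mandatory.  With a single batch level the divisive method falls back
#'   to `"cluster"` automatically.
#' @param params A [divisive_params()].
#' @param rounds Which rounds feed the embedding (see
#'   [concatenate_probabilities()]).
#' @param d Embedding dimension (default 30).
#' @param k_nn Neighbours used at transfer time (default 10).
#' @return A list of class `reference_model`: `icp` (the
#'   `multi_run_result`), `embedding`, `ref_labels`, `ref_scores`,
#'   `rounds`, `k_nn`.
#' @export
build_reference <- function(x_ref, meta, params = divisive_params(),
                            rounds = "last", d = 30, k_nn = 10) {
  meta <- align_metadata(x_ref, meta)
  if (is.null(meta$label) || anyNA(meta$label)) {
    stop("reference metadata must carry a complete `label` column")
  }
  if (nlevels(meta$batch) < 2L &&
      params$divisive_method == "pc1_batch") {
    params$divisive_method <- "cluster"
  }
  res <- run_divisive_icp(x_ref, meta, params)
  conc <- concatenate_probabilities(res, rounds = rounds)
  emb <- embed_probabilities(conc, d = min(d, dim(conc)))
  structure(list(icp = res, embedding = emb,
                 ref_labels = meta$label,
                 ref_scores = emb$scores,
                 rounds = rounds, k_nn = as.integer(k_nn)),
            class = "reference_model")
}

#' Project query cells into a reference embedding
#'
#' Scores every query cell with every kept (run, round) model of the
#' reference, concatenates the probabilities in the reference column
#' order, applies the reference column statistics, and multiplies by the
#' reference loadings.  Features are aligned by id: model features absent
#' from the query are zero-filled (no expression), extra query features
#' are ignored.
#'
#' @param ref A `reference_model`.
#' @param x_query Query [expression_matrix()].
#' @param min_overlap Minimum fraction of model features the query must
#'   provide (default 0.5).
#' @return Query cells x d score matrix; attributes `n_zero_filled` and
#'   `n_extra` record the feature bookkeeping.
#' @export
project_query <- function(ref, x_query, min_overlap = 0.5) {
  feats <- ref$icp$feature_ids
  present <- intersect(feats, colnames(x_query))
  overlap <- length(present) / length(feats)
  if (overlap < min_overlap) {
    stop(sprintf(paste0("query provides only %.1f%% of the %d model ",
                        "features (floor %.0f%%)"),
                 100 * overlap, length(feats), 100 * min_overlap))
  }
  xq <- matrix(0, nrow(x_query), length(feats),
               dimnames = list(rownames(x_query), feats))
  xq[, present] <- unclass(x_query)[, present, drop = FALSE]
  res <- ref$icp
  blocks <- list()
  for (l in res$kept_runs) {
    run <- res$runs[[l]]
    qs <- if (identical(ref$rounds, "last")) {
      length(run)
    } else if (identical(ref$rounds, "all")) {
      seq_along(run)
    } else {
      intersect(as.integer(ref$rounds), seq_along(run))
    }
    for (q in qs) {
      blocks[[length(blocks) + 1L]] <-
        predict_probabilities(run[[q]]$model, xq)
    }
  }
  conc <- do.call(cbind, blocks)
  emb <- ref$embedding
  z <- sweep(sweep(conc, 2L, emb$col_means), 2L, emb$col_sds, "/")
  scores <- z %*% emb$loadings
  rownames(scores) <- rownames(x_query)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  attr(scores, "n_zero_filled") <- length(feats) - length(present)
  attr(scores, "n_extra") <- ncol(x_query) - length(present)
  scores
}

#' Transfer labels by k-nearest-neighbour majority vote
#'
#' Each query cell takes the modal label of its `k_nn` Euclidean nearest
#' reference cells in the embedding.  Vote ties are broken by the smaller
#' mean neighbour distance, then lexicographically.  The confidence score
#' is the fraction of neighbours supporting the winner.
#'
#' @param ref A `reference_model`.
#' @param query_scores Query cells x d matrix from [project_query()].
#' @param k_nn Number of neighbours (default: the model's `k_nn`).
#' @return A list of class `mapping_result`: `predicted` (factor),
#'   `confidence` (numeric in `(0, 1]`), `query_scores`.
#' @export
knn_transfer <- function(ref, query_scores, k_nn = ref$k_nn) {
  n_ref <- nrow(ref$ref_scores)
  if (k_nn > n_ref) {
    stop("`k_nn` (", k_nn, ") exceeds the number of reference cells (",
         n_ref, ")")
  }
  labs <- as.character(ref$ref_labels)
  rs <- ref$ref_scores
  qs <- as.matrix(query_scores)
  # squared distances query x reference
  d2 <- outer(rowSums(qs^2), rowSums(rs^2), "+") - 2 * tcrossprod(qs, rs)
  pred <- character(nrow(qs))
  conf <- numeric(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    nb <- order(d2[i, ])[seq_len(k_nn)]
    votes <- table(labs[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(lb) {
        mean(d2[i, nb[labs[nb] == lb]])
      }, numeric(1))
      top <- top[mean_d == min(mean_d)]
      top <- sort(top)[1L]
    }
    pred[i] <- top
    conf[i] <- max(votes) / k_nn
  }
  structure(list(predicted = factor(pred, levels = levels(ref$ref_labels)),
                 confidence = conf,
                 query_scores = qs),
            class = "mapping_result")
}

#' Overall accuracy of transferred labels
#'
#' Fraction of query cells whose predicted label equals the truth
#' (multiclass micro accuracy), with the full confusion table.
#'
#' @param pred Predicted labels.
#' @param truth Ground-truth labels of equal length.
#' @return A list: `accuracy` (numeric), `confusion` (table, truth in
#'   rows, prediction in columns).
#' @export
mapping_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` differ in length")
  }
  lv <- union(as.character(unique(truth)), as.character(unique(pred)))
  pred <- factor(as.character(pred), levels = lv)
  truth <- factor(as.character(truth), levels = lv)
  conf <- table(truth = truth, predicted = pred)
  list(accuracy = mean(as.character(pred) == as.character(truth)),
       confusion = conf)
}

#' Per-label model coefficients via majority voting
#'
#' For each run, cells are assigned to their argmax final-round cluster;
#' each label's best-matching cluster is the one holding the plurality of
#' that label's cells, and that cluster's coefficient vector is
#' retrieved.  The across-run mean coefficient per feature is returned
#' alongside the per-run vectors.
#'
#' @param res A `multi_run_result`.
#' @param labels Cell labels aligned with `res$cell_ids`.
#' @return A list per label level: `mean` (named numeric, intercept
#'   excluded), `per_run` (runs x features matrix), `clusters` (chosen
#'   cluster per run).
#' @export
majority_voting_features <- function(res, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != length(res$cell_ids)) {
    stop("`labels` length does not match the number of cells")
  }
  if (any(table(labels) == 0L)) {
    stop("label level with zero cells: ",
         paste(levels(labels)[table(labels) == 0L], collapse = ", "))
  }
  out <- list()
  for (lv in levels(labels)) {
    per_run <- list()
    clusters <- integer(0)
    for (l in res$kept_runs) {
      run <- res$runs[[l]]
      final <- run[[length(run)]]
      assign <- project_clustering(final$cell_probs)
      members <- assign[labels == lv]
      best <- as.integer(names(which.max(table(members))))
      coefs <- final$model$coefficients[best, -1L]
      per_run[[length(per_run) + 1L]] <- coefs
      clusters <- c(clusters, best)
    }
    pr <- do.call(rbind, per_run)
    out[[lv]] <- list(mean = colMeans(pr), per_run = pr,
                      clusters = clusters)
  }
  out
}
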