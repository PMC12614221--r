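#' Concatenate per-run cluster probability matrices
#'
#' Binds the per-cell probability blocks of the kept runs column-wise,
#' ordered by (run, round, cluster).  Column names encode provenance as
#' `run<l>:round<q>:cluster<j>` so blocks can be extracted later.
#'
#' @param res A `multi_run_result`.
#' @param rounds `"last"` (default) uses each run's final round; `"all"`
#'   uses every round; an integer vector selects specific rounds `q`.
#' @return Cells x (sum of k) numeric matrix.
#' @export
concatenate_probabilities <- function(res, rounds = "last") {
  if (!length(res$kept_runs)) stop("no kept runs to concatenate")
  blocks <- list()
  for (l in res$kept_runs) {
    run <- res$runs[[l]]
    qs <- if (identical(rounds, "last")) {
      length(run)
    } else if (identical(rounds, "all")) {
      seq_along(run)
    } else {
      intersect(as.integer(rounds), seq_along(run))
    }
    for (q in qs) {
      p <- run[[q]]$cell_probs
      colnames(p) <- sprintf("run%d:round%d:cluster%d", l, q,
                             seq_len(ncol(p)))
      blocks[[length(blocks) + 1L]] <- p
    }
  }
  do.call(cbind, blocks)
}

#' Integrated linear embedding of concatenated probabilities
#'
#' Columns are z-scored (zero-variance columns get a unit-sd sentinel so
#' they contribute 0 after centering) and decomposed by PCA with the
#' package's fixed sign convention.  The returned model retains the
#' column statistics and loadings so query data can be projected into the
#' same space.
#'
#' @param m Cells x columns concatenated probability matrix.
#' @param d Number of components (default 30, capped by the data).
#' @return A list of class `prob_embedding`: `col_means`, `col_sds`,
#'   `loadings`, `scores` (cells x d), `sdev`, `d`, `col_names`.
#' @export
embed_probabilities <- function(m, d = 30) {
  m <- as.matrix(m)
  if (d > min(nrow(m), ncol(m))) {
    stop("`d` = ", d, " too large for a ", nrow(m), " x ", ncol(m),
         " matrix")
  }
  d <- min(d, nrow(m) - 1L, ncol(m))
  mu <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  sds[sds == 0] <- 1  # sentinel: centered column is all-zero anyway
  z <- sweep(sweep(m, 2L, mu), 2L, sds, "/")
  sv <- svd(z, nu = 0, nv = d)
  loadings <- sv$v
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    lj <- loadings[, j]
    sign(lj[which.max(abs(lj))])
  }, numeric(1))
  loadings <- sweep(loadings, 2L, flip, "*")
  rownames(loadings) <- colnames(m)
  scores <- z %*% loadings
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(d))
  structure(list(col_means = mu, col_sds = sds, loadings = loadings,
                 scores = scores,
                 sdev = sv$d[seq_len(d)] / sqrt(max(1, nrow(m) - 1L)),
                 d = d, col_names = colnames(m)),
            class = "prob_embedding")
}

#' k-nearest-neighbour batch mixing score
#'
#' For each cell, the fraction of its `k` nearest neighbours sharing its
#' batch is compared with the fraction expected under perfect mixing.
#' The per-cell score is `1 - clip((observed - expected) / (1 - expected),
#' 0, 1)`, i.e. 1 when own-batch neighbours are at or below chance level
#' and 0 when all neighbours are own-batch.  Returns the mean over cells.
#'
#' @param scores Cells x d embedding matrix.
#' @param batches Batch factor per cell.
#' @param k Number of neighbours (default 30).
#' @return A single numeric in `[0, 1]`; defined as 1 for a single batch.
#' @export
knn_batch_mixing <- function(scores, batches, k = 30) {
  batches <- factor(batches)
  n <- nrow(scores)
  if (nlevels(batches) < 2L) return(1)
  if (k >= n) stop("`k` must be smaller than the number of cells")
  d2 <- .pairwise_sqdist(as.matrix(scores))
  diag(d2) <- Inf
  sizes <- table(batches)
  per_cell <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    obs <- mean(batches[nb] == batches[i])
    expd <- (sizes[[as.character(batches[i])]] - 1) / (n - 1)
    excess <- (obs - expd) / (1 - expd)
    1 - min(max(excess, 0), 1)
  }, numeric(1))
  mean(per_cell)
}
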