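#' Select highly variable features
#'
#' Ranks features by the residual of their variance over a smooth
#' mean-variance trend, estimated as a running median (31-point window) of
#' variance against mean on the log-normalized data.  Ties are resolved by
#' original feature order so selection is deterministic.
#'
#' @param x An [expression_matrix()].
#' @param n Number of features to keep (default 2000, capped at the
#'   number of available features).
#' @return A data.frame with columns `feature_id` and `score` (variance
#'   minus trend), ordered most to least variable.
#' @export
select_hvgs <- function(x, n = 2000) {
  m <- unclass(x)
  if (n > ncol(m)) stop("`n` (", n, ") exceeds number of features (",
                        ncol(m), ")")
  mu <- colMeans(m)
  v <- apply(m, 2L, stats::var)
  if (any(!is.finite(v))) stop("non-finite feature variances")
  ord <- order(mu)
  k <- min(31L, length(v) - (length(v) + 1L) %% 2L)  # odd, <= n features
  trend <- numeric(length(v))
  if (k >= 3L && length(v) >= 3L) {
    trend[ord] <- stats::runmed(v[ord], k, endrule = "median")
  } else {
    trend[] <- stats::median(v)
  }
  score <- v - trend
  sel <- order(-score)[seq_len(n)]
  sel <- sel[order(score[sel], decreasing = TRUE)]
  data.frame(feature_id = colnames(m)[sel], score = score[sel],
             stringsAsFactors = FALSE)
}

#' Principal component analysis with a fixed sign convention
#'
#' Computes PCA on (optionally) z-scored data.  Zero-variance features are
#' dropped from standardization and recorded.  Each loading column is
#' oriented so that its largest-magnitude entry is positive, making
#' results reproducible across platforms.
#'
#' @param x Numeric matrix, items x features.
#' @param n_pcs Number of components to retain (default 30, capped at
#'   `min(dim(x)) - ` rank constraints).
#' @param standardize Z-score features before decomposition (default TRUE).
#' @return A list of class `pca_model`: `means`, `sds`, `loadings`
#'   (features x n_pcs), `scores` (items x n_pcs), `sdev` (component
#'   standard deviations), `n_pcs`, `dropped_features`.
#' @export
compute_pca <- function(x, n_pcs = 30, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA requires at least 2 items")
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  dropped <- character(0)
  if (standardize) {
    keep <- sds > 0
    dropped <- colnames(x)[!keep]
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]
    sds <- sds[keep]
    xs <- sweep(sweep(x, 2L, mu), 2L, sds, "/")
  } else {
    sds <- rep(1, length(sds))
    xs <- sweep(x, 2L, mu)
  }
  n_pcs <- min(n_pcs, nrow(xs) - 1L, ncol(xs))
  if (n_pcs < 1L) stop("no principal components can be extracted")
  sv <- svd(xs, nu = 0, nv = n_pcs)
  loadings <- sv$v
  # sign convention: largest-magnitude loading entry positive
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    lj <- loadings[, j]
    sign(lj[which.max(abs(lj))])
  }, numeric(1))
  loadings <- sweep(loadings, 2L, flip, "*")
  rownames(loadings) <- colnames(xs)
  scores <- xs %*% loadings
  rownames(scores) <- rownames(x)
  structure(list(means = mu, sds = sds, loadings = loadings,
                 scores = scores,
                 sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(xs) - 1L)),
                 n_pcs = n_pcs, dropped_features = dropped),
            class = "pca_model")
}

#' Project new data onto a fitted PCA model
#'
#' @param pca A `pca_model`.
#' @param x Items x features matrix covering the model's features.
#' @return Items x n_pcs score matrix.
#' @export
project_pca <- function(pca, x) {
  x <- as.matrix(x)
  feats <- rownames(pca$loadings)
  if (!is.null(feats) && !is.null(colnames(x))) {
    x <- x[, feats, drop = FALSE]
  } else if (ncol(x) != nrow(pca$loadings)) {
    # unnamed input must already match the retained feature columns
    stop("`x` has ", ncol(x), " columns but the model retains ",
         nrow(pca$loadings), " features")
  }
  xs <- sweep(sweep(x, 2L, pca$means), 2L, pca$sds, "/")
  xs %*% pca$loadings
}

# k-means++ seeding followed by Lloyd iterations.  Deterministic given the
# RNG state; empty clusters are re-seeded once from the farthest points,
# then dropped.
.kmeanspp <- function(x, k, iter_max = 50L) {
  n <- nrow(x)
  k <- min(k, n)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) {
    for (j in 2L:k) {
      if (sum(d2) == 0) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  assign <- .nearest_center(x, centers)
  for (it in seq_len(iter_max)) {
    sizes <- tabulate(assign, k)
    if (any(sizes == 0L)) {
      # re-seed empty clusters once from the points farthest from their center
      dmin <- .min_center_dist(x, centers, assign)
      for (j in which(sizes == 0L)) {
        far <- which.max(dmin)
        centers[j, ] <- x[far, ]
        dmin[far] <- 0
      }
      assign <- .nearest_center(x, centers)
      sizes <- tabulate(assign, k)
    }
    for (j in which(sizes > 0L)) {
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    }
    new_assign <- .nearest_center(x, centers)
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  # drop clusters still empty and compact labels
  sizes <- tabulate(assign, k)
  keep <- which(sizes > 0L)
  relabel <- integer(k)
  relabel[keep] <- seq_along(keep)
  list(cluster = relabel[assign], k = length(keep))
}

.nearest_center <- function(x, centers) {
  # dist^2(i, j) = |x_i|^2 - 2 x_i . c_j + |c_j|^2; the |x|^2 term is
  # constant per row and can be ignored for the argmin
  cross <- x %*% t(centers)
  cn <- rowSums(centers^2)
  d <- sweep(-2 * cross, 2L, cn, "+")
  max.col(-d, ties.method = "first")
}

.min_center_dist <- function(x, centers, assign) {
  rowSums((x - centers[assign, , drop = FALSE])^2)
}

#' Build the batch-balanced training set of averaged profiles
#'
#' Cells are placed into a large number of small groups per batch by
#' k-means++ in a shared PCA space of the highly variable features (the
#' PCA is fitted once on all cells from all batches); each group's average
#' HVG expression profile becomes one training "cell".  Batch-wise group
#' sets are concatenated with their batch labels.
#'
#' @param x An [expression_matrix()] (log-normalized).
#' @param meta A [cell_metadata()] aligned to `x` (see [align_metadata()]).
#' @param hvgs Result of [select_hvgs()]; features used for grouping and
#'   profile averaging.
#' @param n_groups Target number of groups per batch (default 500, clipped
#'   to the batch's cell count).
#' @param n_pcs Principal components for the grouping space (default 30).
#' @param seed Integer seed; per-batch k-means++ draws are seeded by a
#'   deterministic function of `seed` and the batch index so results do
#'   not depend on cell order.
#' @return A list of class `training_set`: `profiles` (A x m_hvg matrix),
#'   `profile_batch` (factor), `membership` (list of cell-id vectors per
#'   profile), `source_features`.
#' @export
build_training_set <- function(x, meta, hvgs, n_groups = 500, n_pcs = 30,
                               seed = 1L) {
  meta <- align_metadata(x, meta)
  feats <- hvgs$feature_id
  xh <- unclass(x)[, feats, drop = FALSE]
  pca <- compute_pca(xh, n_pcs = n_pcs, standardize = TRUE)
  .group_profiles(xh, meta, pca$scores, n_groups, seed)
}

# Batch-wise k-means++ grouping of cells in a precomputed PCA space and
# averaging of their expression rows; the seeded, per-run part of
# training-set construction.
.group_profiles <- function(xh, meta, pca_scores, n_groups, seed) {
  feats <- colnames(xh)
  batches <- levels(meta$batch)
  if (any(table(meta$batch) == 0L)) {
    stop("empty batch level: ",
         paste(batches[table(meta$batch) == 0L], collapse = ", "))
  }
  profiles <- list()
  profile_batch <- character(0)
  membership <- list()
  for (bi in seq_along(batches)) {
    b <- batches[bi]
    idx <- which(meta$batch == b)
    # canonical within-batch order makes grouping invariant to cell order
    idx <- idx[order(rownames(xh)[idx])]
    k <- min(n_groups, length(idx))
    set.seed(.derive_seed(seed, bi))
    km <- .kmeanspp(pca_scores[idx, , drop = FALSE], k)
    for (j in seq_len(km$k)) {
      members <- idx[km$cluster == j]
      profiles[[length(profiles) + 1L]] <-
        colMeans(xh[members, , drop = FALSE])
      membership[[length(membership) + 1L]] <- rownames(xh)[members]
      profile_batch <- c(profile_batch, b)
    }
  }
  prof <- do.call(rbind, profiles)
  rownames(prof) <- paste0("profile_", seq_len(nrow(prof)))
  colnames(prof) <- feats
  names(membership) <- rownames(prof)
  structure(list(profiles = prof,
                 profile_batch = factor(profile_batch, levels = batches),
                 membership = membership,
                 source_features = feats),
            class = "training_set")
}

# Deterministic seed derivation, kept below 2^31.
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}
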