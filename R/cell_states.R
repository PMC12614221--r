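#' Per-cell state scores from cluster assignment probabilities
#'
#' For each cell, the mean over kept runs of the maximum (assigned-
#' cluster) probability of the selected round.  High scores mark
#' transcriptionally distinct, stable cell states; low scores mark
#' transient, in-between states.
#'
#' @param res A `multi_run_result`.
#' @param round Round to score, `"last"` (default) or an integer `q`.
#' @return A data.frame with columns `cell_id`, `mean_prob` and
#'   `scaled_prob` (min-max scaled to `[0, 1]`; constant scores scale
#'   to 0).
#' @export
state_scores <- function(res, round = "last") {
  if (!length(res$kept_runs)) stop("no kept runs")
  acc <- 0
  for (l in res$kept_runs) {
    run <- res$runs[[l]]
    q <- if (identical(round, "last")) length(run) else as.integer(round)
    if (q < 1L || q > length(run)) stop("round ", round, " not available")
    acc <- acc + apply(run[[q]]$cell_probs, 1L, max)
  }
  mean_prob <- acc / length(res$kept_runs)
  rng <- range(mean_prob)
  scaled <- if (diff(rng) > 0) (mean_prob - rng[1L]) / diff(rng) else
    rep(0, length(mean_prob))
  data.frame(cell_id = res$cell_ids, mean_prob = mean_prob,
             scaled_prob = scaled, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bin cells by state score within each label
#'
#' Cells of each label are sorted by `mean_prob` (ties broken by cell id)
#' and cut into `n_bins` contiguous equal-count bins; any remainder is
#' spread over the lowest bins so sizes differ by at most one cell.
#' Labels with fewer cells than `n_bins` get one singleton bin per cell.
#'
#' @param scores Data.frame from [state_scores()].
#' @param labels Cell labels aligned with `scores$cell_id`.
#' @param n_bins Number of bins per label (default 20).
#' @return A data.frame with one row per (label, bin): `label`, `bin`,
#'   `n_cells`, `mean_prob`, and a `cells` list-column of member ids.
#' @export
bin_by_probability <- function(scores, labels, n_bins = 20) {
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(scores))
  rows <- list()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    nb <- min(n_bins, length(idx))
    ord <- idx[order(scores$mean_prob[idx], scores$cell_id[idx])]
    base <- length(ord) %/% nb
    rem <- length(ord) %% nb
    sizes <- rep(base, nb) + c(rep(1L, rem), rep(0L, nb - rem))
    stop_at <- cumsum(sizes)
    start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
    for (b in seq_len(nb)) {
      members <- ord[start_at[b]:stop_at[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = lv, bin = b, n_cells = length(members),
        mean_prob = mean(scores$mean_prob[members]),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$cells <- list(scores$cell_id[members])
    }
  }
  do.call(rbind, rows)
}

#' Correlate gene expression with state score across bins
#'
#' Per label, the Pearson correlation between the bin-mean state
#' probabilities and the bin-mean expression of each gene.  Genes with
#' zero variance across bins, and labels with fewer than 3 bins, yield
#' `NA`.
#'
#' @param x An [expression_matrix()] covering the binned cells.
#' @param bins Data.frame from [bin_by_probability()].
#' @return A data.frame with columns `label`, `gene`, `r`, ordered by
#'   label then descending `r` (`NA` last).
#' @export
gene_state_correlation <- function(x, bins) {
  xm <- unclass(x)
  out <- list()
  for (lv in unique(bins$label)) {
    sub <- bins[bins$label == lv, , drop = FALSE]
    if (nrow(sub) < 3L) {
      out[[length(out) + 1L]] <- data.frame(
        label = lv, gene = colnames(xm), r = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    expr <- t(vapply(seq_len(nrow(sub)), function(b) {
      colMeans(xm[sub$cells[[b]], , drop = FALSE])
    }, numeric(ncol(xm))))
    p <- sub$mean_prob
    sd_e <- apply(expr, 2L, stats::sd)
    r <- rep(NA_real_, ncol(expr))
    ok <- sd_e > 0 & stats::sd(p) > 0
    if (any(ok)) {
      r[ok] <- as.numeric(stats::cor(p, expr[, ok, drop = FALSE]))
    }
    df <- data.frame(label = lv, gene = colnames(xm), r = r,
                     stringsAsFactors = FALSE)
    df <- df[order(is.na(df$r), -ifelse(is.na(df$r), 0, df$r)), ]
    out[[length(out) + 1L]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top correlated genes per label
#'
#' @param corr Data.frame from [gene_state_correlation()].
#' @param n Genes per direction (default 5).
#' @return Data.frame with `label`, `direction` (`"positive"` /
#'   `"negative"`), `gene`, `r`.
#' @export
top_state_genes <- function(corr, n = 5) {
  out <- list()
  for (lv in unique(corr$label)) {
    sub <- corr[corr$label == lv & !is.na(corr$r), , drop = FALSE]
    pos <- utils::head(sub[order(-sub$r), ], n)
    neg <- utils::head(sub[order(sub$r), ], n)
    if (nrow(pos)) {
      out[[length(out) + 1L]] <- data.frame(
        label = lv, direction = "positive", gene = pos$gene, r = pos$r,
        stringsAsFactors = FALSE)
    }
    if (nrow(neg)) {
      out[[length(out) + 1L]] <- data.frame(
        label = lv, direction = "negative", gene = neg$gene, r = neg$r,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
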