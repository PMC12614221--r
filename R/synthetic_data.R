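#' Design of a synthetic multi-batch single-cell experiment
#'
#' Describes a negative-binomial simulation with known ground truth:
#' cell types defined by planted differentially expressed (DE) gene sets,
#' batch effects as gene-subset log-fold shifts, optional transcriptional
#' similarity between type pairs (shared DE genes), optional cell-type
#' ablation/imbalance (zero or reduced counts in the cell matrix), and an
#' optional branching differentiation trajectory.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type_per_batch Integer matrix, types x batches; 0
#'   entries ablate a type from a batch.
#' @param m_genes Number of genes.
#' @param de_frac Fraction of genes differential per type (default 0.1).
#' @param de_lfc Log-scale shift on a type's DE genes (default 1).
#' @param similarity_pairs List of `list(pair = c(t1, t2), share = s)`;
#'   type `t2` reuses fraction `s` of `t1`'s DE genes.
#' @param batch_lfc Magnitude of batch shifts on affected genes
#'   (default 0.5).
#' @param batch_gene_frac Fraction of genes shifted per batch
#'   (default 0.2).
#' @param dispersion_range Gene-wise NB dispersion drawn uniformly from
#'   this range (default `c(0.1, 0.4)`).
#' @param trajectory `NULL`, or `list(progenitor = t, terminals = c(...),
#'   n_steps = s, early_noise_sd = 0.5)`: cells of the progenitor type
#'   sit early on a branching differentiation (pseudotime in `[0, 0.5]`,
#'   random branch), cells of each terminal type late on their branch
#'   (pseudotime in `(0.5, 1]`); gene means interpolate between
#'   progenitor and branch-terminal means, so the terminal DE genes rise
#'   monotonely with pseudotime.  `early_noise_sd` is the per-cell
#'   log-mean jitter at pseudotime 0, decaying linearly to 0 at
#'   pseudotime 1: uncommitted progenitors are transcriptionally noisier
#'   than terminally differentiated cells, as observed in real
#'   differentiation data.
#' @param lib_size_sdlog Log-normal sd of the per-cell library size
#'   factor (default 0.3).
#' @param seed Integer seed.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_types, cells_per_type_per_batch, m_genes,
                       de_frac = 0.1, de_lfc = 1,
                       similarity_pairs = list(),
                       batch_lfc = 0.5, batch_gene_frac = 0.2,
                       dispersion_range = c(0.1, 0.4),
                       trajectory = NULL, lib_size_sdlog = 0.3,
                       seed = 1L) {
  cells <- as.matrix(cells_per_type_per_batch)
  if (nrow(cells) != n_types) {
    stop("`cells_per_type_per_batch` must have one row per type")
  }
  if (any(cells < 0)) stop("cell counts must be >= 0")
  if (sum(cells) == 0) stop("design has no cells")
  stopifnot(de_frac >= 0, de_frac <= 1,
            batch_gene_frac >= 0, batch_gene_frac <= 1)
  structure(list(n_types = as.integer(n_types),
                 cells_per_type_per_batch = cells,
                 m_genes = as.integer(m_genes),
                 de_frac = de_frac, de_lfc = de_lfc,
                 similarity_pairs = similarity_pairs,
                 batch_lfc = batch_lfc,
                 batch_gene_frac = batch_gene_frac,
                 dispersion_range = dispersion_range,
                 trajectory = trajectory,
                 lib_size_sdlog = lib_size_sdlog,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate counts and ground truth from a design
#'
#' Gene baseline log-means are drawn once; type effects add `de_lfc` on
#' each type's DE gene set (similar pairs share the stated fraction of DE
#' genes); batch effects add signed `batch_lfc` shifts on a random gene
#' subset per batch; counts are negative-binomial with gene-wise
#' dispersion and log-normally varying library sizes.  In trajectory
#' mode the type log-means are interpolated along pseudotime.
#'
#' @param design A [sim_design()].
#' @return A list: `counts` (cells x genes integer matrix), `meta`
#'   (a [cell_metadata()] with `label`), `truth` (list with `de_genes`
#'   per type, `batch_genes` per batch, `pseudotime` per cell or NULL,
#'   `late_genes` per terminal type in trajectory mode).
#' @export
simulate_cells <- function(design) {
  set.seed(design$seed)
  m <- design$m_genes
  genes <- sprintf("gene%04d", seq_len(m))
  base_log <- stats::rnorm(m, mean = 0.5, sd = 0.75)
  disp <- stats::runif(m, design$dispersion_range[1L],
                       design$dispersion_range[2L])
  n_de <- round(design$de_frac * m)
  # DE gene sets; similar pairs reuse a fraction of the partner's set
  de_genes <- vector("list", design$n_types)
  shared_from <- rep(NA_integer_, design$n_types)
  share_frac <- rep(0, design$n_types)
  for (sp in design$similarity_pairs) {
    shared_from[sp$pair[2L]] <- sp$pair[1L]
    share_frac[sp$pair[2L]] <- sp$share
  }
  for (ty in seq_len(design$n_types)) {
    if (!is.na(shared_from[ty])) next
    de_genes[[ty]] <- sample.int(m, n_de)
  }
  for (ty in seq_len(design$n_types)) {
    if (is.na(shared_from[ty])) next
    src <- de_genes[[shared_from[ty]]]
    n_sh <- round(share_frac[ty] * n_de)
    shared <- if (n_sh > 0) sample(src, n_sh) else integer(0)
    pool <- setdiff(seq_len(m), src)
    own <- sample(pool, n_de - n_sh)
    de_genes[[ty]] <- c(shared, own)
  }
  type_log <- matrix(rep(base_log, design$n_types), nrow = design$n_types,
                     byrow = TRUE)
  for (ty in seq_len(design$n_types)) {
    type_log[ty, de_genes[[ty]]] <- type_log[ty, de_genes[[ty]]] +
      design$de_lfc
  }
  B <- ncol(design$cells_per_type_per_batch)
  batch_genes <- vector("list", B)
  batch_shift <- matrix(0, B, m)
  n_bg <- round(design$batch_gene_frac * m)
  for (b in seq_len(B)) {
    if (n_bg > 0 && design$batch_lfc != 0) {
      batch_genes[[b]] <- sample.int(m, n_bg)
      batch_shift[b, batch_genes[[b]]] <-
        design$batch_lfc * sample(c(-1, 1), n_bg, replace = TRUE)
    } else {
      batch_genes[[b]] <- integer(0)
    }
  }
  # lay out cells
  n <- sum(design$cells_per_type_per_batch)
  type_of <- integer(n)
  batch_of <- integer(n)
  pos <- 0L
  for (b in seq_len(B)) {
    for (ty in seq_len(design$n_types)) {
      cnt <- design$cells_per_type_per_batch[ty, b]
      if (cnt == 0) next
      idx <- pos + seq_len(cnt)
      type_of[idx] <- ty
      batch_of[idx] <- b
      pos <- pos + cnt
    }
  }
  pseudotime <- NULL
  branch_of <- NULL
  traj <- design$trajectory
  if (!is.null(traj)) {
    terms <- traj$terminals
    if (is.null(terms)) terms <- traj$terminal
    pseudotime <- rep(NA_real_, n)
    branch_of <- rep(NA_integer_, n)
    on_prog <- type_of == traj$progenitor
    pseudotime[on_prog] <- stats::runif(sum(on_prog), 0, 0.5)
    branch_of[on_prog] <- sample(seq_along(terms), sum(on_prog),
                                 replace = TRUE)
    for (bi in seq_along(terms)) {
      on_t <- type_of == terms[bi]
      # committed cells accumulate near their terminal state: density
      # increases towards pseudotime 1, as at a differentiation endpoint
      pseudotime[on_t] <- 1 - 0.5 * stats::runif(sum(on_t))^2
      branch_of[on_t] <- bi
    }
  }
  lib <- stats::rlnorm(n, 0, design$lib_size_sdlog)
  early_sd <- if (!is.null(traj)) {
    if (is.null(traj$early_noise_sd)) 0.5 else traj$early_noise_sd
  } else 0
  counts <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (!is.null(pseudotime) && !is.na(pseudotime[i])) {
      terms <- traj$terminals
      if (is.null(terms)) terms <- traj$terminal
      u <- pseudotime[i]
      lm <- (1 - u) * type_log[traj$progenitor, ] +
        u * type_log[terms[branch_of[i]], ]
      if (early_sd > 0) {
        lm <- lm + stats::rnorm(m, sd = early_sd * (1 - u))
      }
    } else {
      lm <- type_log[type_of[i], ]
    }
    mu <- lib[i] * exp(lm + batch_shift[batch_of[i], ])
    counts[i, ] <- stats::rnbinom(m, mu = mu, size = 1 / disp)
  }
  cell_ids <- sprintf("cell%05d", seq_len(n))
  dimnames(counts) <- list(cell_ids, genes)
  meta <- cell_metadata(cell_ids,
                        batch = paste0("batch", batch_of),
                        label = paste0("type", type_of))
  truth <- list(
    de_genes = lapply(de_genes, function(ix) genes[ix]),
    batch_genes = lapply(batch_genes, function(ix) genes[ix]),
    pseudotime = pseudotime,
    late_genes = if (!is.null(traj)) {
      terms <- traj$terminals
      if (is.null(terms)) terms <- traj$terminal
      stats::setNames(lapply(terms, function(ty) genes[de_genes[[ty]]]),
                      paste0("type", terms))
    } else NULL)
  list(counts = counts, meta = meta, truth = truth)
}

#' Frozen named simulation scenarios
#'
#' Reproducible designs covering the situations the integration engine is
#' meant to handle: balanced batches, cell-type imbalance (one type
#' downsampled to 5% in one batch), ablation (one type fully absent from
#' one batch), a transcriptionally similar type pair with one member
#' absent per batch, and a branching differentiation trajectory.
#'
#' @param name One of `"balanced"`, `"imbalanced"`, `"ablated"`,
#'   `"similar_pairs"`, `"trajectory"`.
#' @param scale `"tiny"` (fast fixtures) or `"small"` (property-test
#'   scale).
#' @param seed Integer seed.
#' @return A [sim_design()].
#' @export
make_scenario <- function(name = c("balanced", "imbalanced", "ablated",
                                   "similar_pairs", "trajectory"),
                          scale = c("tiny", "small"), seed = 1L) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  tiny <- scale == "tiny"
  switch(name,
    balanced = {
      per <- if (tiny) 40L else 150L
      m <- if (tiny) 200L else 600L
      sim_design(4, matrix(per, 4, 2), m, de_frac = 0.1, de_lfc = 1.2,
                 batch_lfc = 0.5, batch_gene_frac = 0.2, seed = seed)
    },
    imbalanced = {
      per <- if (tiny) 40L else 200L
      m <- if (tiny) 200L else 600L
      cells <- matrix(per, 4, 2)
      cells[1L, 2L] <- as.integer(round(0.05 * per))  # 5% downsampling
      sim_design(4, cells, m, de_frac = 0.1, de_lfc = 1.2,
                 batch_lfc = 0.5, batch_gene_frac = 0.2, seed = seed)
    },
    ablated = {
      per <- if (tiny) 40L else 200L
      m <- if (tiny) 200L else 600L
      cells <- matrix(per, 4, 2)
      cells[1L, 2L] <- 0L
      sim_design(4, cells, m, de_frac = 0.1, de_lfc = 1.2,
                 batch_lfc = 0.5, batch_gene_frac = 0.2, seed = seed)
    },
    similar_pairs = {
      per <- if (tiny) 70L else 350L
      pair_n <- if (tiny) 90L else 450L
      m <- if (tiny) 300L else 600L
      cells <- matrix(per, 5, 2)
      cells[4L, 2L] <- 0L   # one member of the similar pair per batch
      cells[5L, 1L] <- 0L
      cells[4L, 1L] <- pair_n
      cells[5L, 2L] <- pair_n
      # base types well separated; the pair shares 80% of its DE genes,
      # so only a fifth of each member's signature distinguishes them
      sim_design(5, cells, m, de_frac = 0.1, de_lfc = 2,
                 similarity_pairs = list(list(pair = c(4L, 5L),
                                              share = 0.8)),
                 batch_lfc = 0.5, batch_gene_frac = 0.2, seed = seed)
    },
    trajectory = {
      per <- if (tiny) 80L else 400L
      m <- if (tiny) 200L else 400L
      sim_design(3, matrix(per, 3, 1), m, de_frac = 0.12, de_lfc = 1.5,
                 batch_lfc = 0, batch_gene_frac = 0,
                 trajectory = list(progenitor = 1L, terminals = c(2L, 3L),
                                   n_steps = 100L),
                 seed = seed)
    })
}
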