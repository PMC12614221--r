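---
title: "Methods: divisive iterative clustering projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divisive iterative clustering projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Joint analysis of single-cell expression datasets collected in batches
(different donors, platforms, runs) requires removing systematic
technical shifts while preserving biological differences — including
subtle ones, such as transcriptionally similar cell types that are not
present in every batch. `divicp` addresses this with a self-supervised
clustering engine whose by-products (cluster assignment probabilities)
drive three downstream analyses: an integrated embedding, reference-based
label transfer, and cell-state scoring.

# The core loop: iterative clustering projection

Given a log-normalized expression matrix $X = \{x_1,\dots,x_n\}$,
$x_i \in \mathbb{R}^m$, and a working partition $\pi_k =
\{C_1,\dots,C_k\}$, one *epoch* of the inner loop:

1. selects a training subset (below),
2. fits one L1-regularized binary logistic regression per cluster
   (one-vs-rest), minimizing
   $\sum_i \log(1 + e^{-y_i w^\top x_i}) + \tfrac{1}{C}\lVert w \rVert_1$,
3. re-labels every working item by the cluster with the highest
   predicted probability (the *projection* $\tilde\pi_k$, with row
   probabilities normalized to sum to one), and
4. accepts the epoch iff the adjusted Rand index
   $\mathrm{ARI}(\pi_k, \tilde\pi_k)$ strictly exceeds the best accepted
   value so far (initialized at 0); on acceptance the projection becomes
   the working partition.

The loop stops after `r` consecutive non-improving epochs (default 5) or
`max_iter` epochs in total (default 200).  Because accepted ARI values
are strictly increasing and bounded by 1, termination is guaranteed.
The L1 penalty makes each cluster's model sparse, so its non-zero
coefficients double as marker features.

`cost` is the liblinear-style inverse regularization strength; the
elastic-net solver that performs the fits receives a per-observation
penalty weight of $1/(C\,n_{\mathrm{train}})$, which makes the two
objective conventions equivalent.  The default `cost = 0.3` is a
conservative sparsity level; `cost = 1` relaxes the penalty and, with
`allow_free_k = FALSE`, `train_knn_prop = 0.45` and `ari_cutoff = 0.1`,
reproduces the setting that forces all `K` clusters to be returned.

# What the loop actually clusters: averaged profiles

Rather than clustering raw cells, the engine builds a *training set* of
averaged profiles: per batch, cells are grouped into a large number of
small k-means++ groups (default 500 per batch) in the PCA space (default
30 components) of the highly variable features (default 2000, ranked by
variance above a running-median mean–variance trend), and each group's
mean expression becomes one working "cell".  This balances batches by
construction, denoises, and decouples training items from the cells
being scored.  Profile averaging uses the HVG subset only; the whole
engine therefore models the HVG space.

The k-means++ grouping is redrawn with a fresh seed in every ensemble
run — this is what makes the `L` runs (default 50; scaled down in the
package's tests) genuinely independent, since the remaining steps are
deterministic given the training set.  Within each batch the cells are
processed in canonical id order, so results do not depend on input row
order.

# The divisive outer loop

Round $q$ clusters the profiles into $k = 2^q$ clusters up to the target
`K` (default 16, a power of two):

* **Round 1 initialization.**  Profiles are standardized, PCA is taken,
  and each batch is split at its own median PC1 score.  Batch-wise
  medians mean both starting clusters contain every batch — a rough but
  batch-balanced seed partition the loop then refines.
* **Splitting.**  After a round converges, each cluster is split in two
  at the batch-specific median of its members' maximum assignment
  probabilities $p^{\max}_i$: per batch, members at or below the median
  go to the low child, the rest to the high child.  Cells that the
  models are less sure about are exactly the ones worth re-examining at
  finer resolution.
* **Batch-balanced refinement.**  From the second epoch of each round,
  training is restricted to, per (cluster $j$, batch $b$), the member
  with the highest assignment probability plus its
  $\max(1, \lfloor 0.3\,|C_j|/B \rfloor)$ nearest neighbours among *all*
  profiles (Euclidean, HVG space).  Cross-batch neighbours are allowed
  deliberately: they pull the training set towards cells that look alike
  across batches.
* **Cluster dropping.**  With `allow_free_k = TRUE` (default) a cluster
  that loses all members is removed and indices are compacted; with
  `FALSE` such an epoch counts as a failed reiteration, which combined
  with relaxed parameters enforces exactly `K` final clusters.

In batch-free mode (`divisive_method = "cluster"`, used automatically
for single-batch references) all medians are computed globally.

The ensemble repeats this `L` times with independently derived seeds
(deterministic function of the global seed and the run index, kept below
$2^{31}$), then scores every real cell with every round's models.  Runs
whose terminal-round ARI falls below `ari_cutoff` (default 0.3) are
excluded from downstream concatenation; if that would exclude every run,
the completed runs are kept with a warning rather than failing silently.

# Embedding, label transfer, cell states

**Embedding.**  The per-run, final-round (configurable) cell-probability
matrices of the kept runs are concatenated column-wise, z-scored per
column (zero-variance columns are given a unit-sd sentinel and
contribute nothing), and decomposed by PCA (default 30 components).
Column statistics and loadings are retained so query data can be
projected later.  Sign convention everywhere: each loading column's
largest-magnitude entry is positive, making results platform-stable.

**Label transfer.**  A reference model is a frozen ensemble plus the
embedding and the reference labels.  Query cells are scored by every
kept model, the probabilities are concatenated in reference column
order, standardized with the *reference* statistics (the only defensible
frozen-model behaviour), and projected with the reference loadings.
Labels transfer by majority vote among the `k_nn = 10` nearest reference
cells; vote ties break by smaller mean neighbour distance, then
lexicographically, so transfer is deterministic.  The confidence score
is the winning fraction of neighbours, hence in $\{1/k_{nn},\dots,1\}$.
Model features missing from a query are zero-filled (zero is the neutral
value for L1 models fitted on log-normalized data, where absence means
no expression); an overlap below 50% of model features is an error.
There is no rejection class: a query cell whose type is absent from the
reference still receives a label, but with visibly depressed confidence.

**Cell states.**  A cell's state score is the mean over kept runs of its
maximum (assigned-cluster) probability.  Transcriptionally distinct,
stable populations score high; transient or boundary states score low.
Per cell type, cells are sorted by score and cut into `n_bins = 20`
equal-count bins ("evenly sized" is read as equal cell counts —
quantile bins are robust to skewed score distributions; the remainder is
spread over the lowest bins and probability ties break by cell id).
Per-gene Pearson correlation between bin-mean score and bin-mean
expression ranks genes along the inferred state axis; zero-variance
genes and labels with fewer than three bins report `NA`.

# The synthetic-data generator

All tests run on data from `simulate_cells()`, never on downloads.  The
generator draws per-gene baseline log-means once, adds `de_lfc` on each
type's planted DE gene set (a *similar pair* shares a stated fraction of
one member's DE genes), adds signed batch shifts on a random gene subset
per batch, and samples negative-binomial counts with gene-wise
dispersion (uniform 0.1–0.4) under log-normally varying library sizes.
Named scenarios freeze the study designs: `balanced`, `imbalanced` (one
type at 5% in one batch), `ablated` (one type absent from one batch),
`similar_pairs` (a pair sharing 80% of DE genes, each member present in
only one batch), and `trajectory`.

The trajectory mode emulates a branching differentiation: progenitor
cells sit at pseudotime $u \in [0, 0.5]$ with a random branch, committed
cells at $u \in (0.5, 1]$ on their branch, and gene means interpolate
between the progenitor and branch-terminal profiles.  Two deliberate
realism choices, without which a simulated continuum is uniformly easy
to cluster and contains no transient-vs-stable contrast at all: per-cell
transcriptional noise decays with pseudotime (uncommitted progenitors
are noisier, as observed in real differentiation), and committed cells
accumulate near their terminal state (attractor density).  A
single-terminal (non-branching) trajectory remains supported, but note
that on a linear continuum both endpoints are distinct, so confidence
does not increase monotonely along it.

What the generator does *not* emulate: doublets, ambient RNA, nested
sub-batch structure, zero-inflation beyond NB sampling, or realistic
gene–gene correlation.  Passing tests therefore demonstrate the
algorithmic contracts and qualitative behaviours, not performance claims
on real tissue atlases.

# Numerical and design choices

* **Probability normalization.**  One-vs-rest sigmoid scores are divided
  by their row sum.  For $k = 2$ mirror-symmetric models this reduces to
  a single sigmoid of the decision value.
* **Ties.**  Argmax ties go to the lowest cluster index; probability
  ties in splitting send the member to the low child; binning ties break
  by cell id; kNN vote ties by mean distance then label order.  Every
  code path is deterministic under a fixed seed.
* **PCA.**  Base SVD with zero-variance features dropped from
  standardization and the positive-largest-loading sign convention; no
  randomized solver, so results are bit-reproducible.
* **k-means++.**  Seeded squared-distance sampling followed by Lloyd
  iterations; empty clusters are re-seeded once from the farthest
  points, then dropped.  `k` clips to the number of cells in the batch.
* **Degenerate inputs.**  Cells with zero total counts are rejected by
  normalization; all-zero features are dropped; a training-label
  collapse (a cluster vanishing from the subset) is surfaced to the loop
  and treated as a failed reiteration; a cluster collapse to $k = 1$
  ends the run's rounds.
* **Solver tolerances.**  Fits use a short warm-start lambda path down
  to the target penalty with the solver's default convergence threshold;
  a truncated path (non-convergence at the smallest lambda) falls back
  to the nearest converged solution, deterministically.

# Problem sizes used by the tests

The test-suite and acceptance experiments run at desk scale, chosen as
the package's own study conditions: integration recovery uses two
batches, five types, ~3000 cells, 600 genes, `K = 8`, `L = 8` over eight
seeds; label-transfer symmetry uses 4 types, 600 cells per batch,
`K = 8`, `L = 16` over five seeds; the trajectory analysis uses 1200
cells, 400 genes, `L = 8` and `K = 2` — with two terminal fates the
ensemble is run to two clusters, so assignment confidence measures
branch commitment; larger `K` tiles the dense terminal attractors and
places arbitrary boundaries through committed cells.

# Known limitations

* The engine models the HVG space only; features outside it never
  influence clustering, mapping, or coefficients.
* No rejection option in label transfer (by design, documented above).
* `L = 50` (the method's natural ensemble size) is scaled down in tests;
  very small `L` increases run-to-run variance of the embedding.
* The cost default (0.3) is a documented choice, not a printed value
  from an upstream source; calibrations of `K` to the data's granularity
  are the user's responsibility.
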