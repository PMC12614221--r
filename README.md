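# divicp

Multi-level integration of multi-batch single-cell expression data by
**divisive iterative clustering projection** (ICP), with
reference-based label transfer and probability-based cell-state
inference.

## Who this is for

Analysts integrating single-cell RNA-seq (or other single-cell
feature-count) datasets collected in batches — different donors,
platforms or runs — who need batch effects removed without flattening
subtle biology: imbalanced cell types, types absent from some batches,
or transcriptionally similar type pairs. The same fitted models support
automatic annotation of new datasets against an annotated reference and
scoring of within-type cell states (transient vs stable).

## The method

The core is a self-supervised clustering loop. For a working partition
$\pi_k = \{C_1,\dots,C_k\}$ of items $x_i \in \mathbb{R}^m$, each epoch
fits one L1-regularized logistic regression per cluster (one-vs-rest),

$$\min_w \; \sum_i \log\!\left(1 + e^{-y_i w^\top x_i}\right) + \tfrac{1}{C}\,\lVert w \rVert_1,$$

re-labels every item by its highest predicted probability (the
projection $\tilde\pi_k$), and accepts the epoch iff
$\mathrm{ARI}(\pi_k,\tilde\pi_k)$ strictly improves. A divisive outer
loop doubles the cluster count each round, $k = 2^q$ up to a target $K$,
by splitting every cluster at the batch-wise median of its members'
maximum assignment probability $p^{\max}_i$. Batch balance enters three
ways: the loop clusters batch-wise k-means++ *averaged profiles* rather
than raw cells; round 1 starts from batch-wise median splits along PC1;
and later epochs train on each (cluster, batch)'s most confident member
plus its $\lfloor 0.3\,|C_j|/B \rfloor$ nearest cross-batch neighbours.

The ensemble of $L$ independent runs yields per-cell cluster probability
matrices which are concatenated, z-scored and decomposed by PCA into an
integrated embedding. Label transfer projects a query's probability
vectors into an annotated reference's PCA space and votes among the
`k_nn = 10` nearest reference cells (the winning fraction is a
confidence score). A cell's state score is its mean assigned-cluster
probability across runs — high for distinct stable populations, low for
transient ones.

See `vignettes/divicp-methods.Rmd` for the full account, including
every default and tie-break.

## Worked example

Simulate two batches of three cell types (one type absent from nowhere,
batch shifts on 20% of genes), integrate, and check the result against
the known ground truth:

```r
library(divicp)

design <- sim_design(3, matrix(60L, 3, 2), 300, de_frac = 0.15,
                     de_lfc = 2, batch_lfc = 0.5, batch_gene_frac = 0.2,
                     seed = 7)
sim  <- simulate_cells(design)
x    <- filter_unexpressed(log_normalize(sim$counts))
meta <- align_metadata(x, sim$meta)

params <- divisive_params(K = 4, L = 4, icp = icp_params(seed = 7),
                          n_hvgs = 200, n_groups = 60, n_pcs = 10)
res <- run_divisive_icp(x, meta, params)
emb <- embed_probabilities(concatenate_probabilities(res), d = 10)

set.seed(7)
km <- kmeans(emb$scores, centers = 3, nstart = 10)
adjusted_rand_index(km$cluster, meta$label)
knn_batch_mixing(emb$scores, meta$batch, k = 15)
```

Output from this exact run:

```
kept runs: 4 of 4
terminal ARI per run: 0.792 0.81 0.812 0.933
clustering ARI vs true types: 1
batch mixing (integrated): 0.848
batch mixing (unintegrated PCA): 0.345
```

Reading the numbers: every run's final self-agreement (terminal ARI)
cleared the `ari_cutoff`, so all four probability tables feed the
embedding; k-means on the embedding recovers the three simulated types
perfectly (ARI 1 against truth); and neighbourhoods in the embedding are
far better batch-mixed (0.85, where 1 means own-batch neighbours at
chance level) than in the unintegrated HVG PCA (0.35).

## Command line

The installed package ships `exec/divicp` with four subcommands:

```sh
divicp simulate  --scenario similar_pairs --scale small --seed 1 --out sim/
divicp integrate --expr sim/matrix.mtx --meta sim/metadata.tsv \
                 --normalize true --K 8 --L 8 --seed 1 --out run/
divicp map       --reference run/model.archive --expr query.mtx --out mapped/
divicp states    --model run/model.archive --expr sim/matrix.mtx \
                 --meta sim/metadata.tsv --out states/
```

Options can also come from an INI-like `key=value` file via `--config`
(flags win). Each run writes its resolved configuration, seeds and input
checksums next to its outputs.

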