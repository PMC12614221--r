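# Shared fixture builders; everything is generated in code, seeded per call.

# Two well-separated Gaussian blobs in `d` dimensions.
make_blobs <- function(n_per = 20, d = 5, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n_per * d), n_per, d),
    matrix(stats::rnorm(n_per * d, mean = sep), n_per, d))
  rownames(x) <- paste0("item", seq_len(nrow(x)))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, labels = rep(1:2, each = n_per))
}

# Small log-normalized expression fixture from the simulator.
make_tiny_expression <- function(scenario = "balanced", seed = 1) {
  sim <- simulate_cells(make_scenario(scenario, "tiny", seed = seed))
  x <- filter_unexpressed(log_normalize(sim$counts))
  list(x = x, meta = align_metadata(x, sim$meta), truth = sim$truth)
}

# Independent contingency-table ARI used as a brute-force oracle.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  nij <- comb2(as.numeric(tab))
  ai <- comb2(as.numeric(rowSums(tab)))
  bj <- comb2(as.numeric(colSums(tab)))
  nn <- length(a) * (length(a) - 1) / 2
  exp_idx <- ai * bj / nn
  max_idx <- (ai + bj) / 2
  if (max_idx == exp_idx) return(1)
  (nij - exp_idx) / (max_idx - exp_idx)
}
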