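# Independent oracles, kept deliberately naive.

# Running-sum enrichment score by explicit iteration over every position.
oracle_es <- function(scores, inset, weight = 1) {
  N <- length(scores)
  w <- abs(scores)^weight
  wh_total <- sum(w[inset])
  if (wh_total == 0) { w[] <- 1; wh_total <- sum(inset) }
  n_miss <- N - sum(inset)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (inset[i]) w[i] / wh_total else -1 / n_miss
    running[i] <- acc
  }
  hi <- max(running); lo <- min(running)
  if (hi > -lo) hi else lo  # exact ties resolve to the negative extreme
}

# Hypergeometric upper tail P(X >= k) by summing exact binomial terms.
oracle_hyper_sum <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Hypergeometric upper tail by literal enumeration of all C(N, n) draws.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "set"
  mean(hits >= k)
}

# BH step-up computed from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(adj, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# small, fast simulation scenario used across module tests
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 400, n_gene_sets = 12, n_shifted_sets = 2,
               set_size_range = c(10L, 20L), n_tfs = 15,
               targets_per_tf_range = c(8L, 15L),
               library_size_range = c(2e5, 3e5), seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# one cell type's samples and counts from a bundle
subset_cell_type <- function(bundle, ct) {
  sub <- bundle$samples[bundle$samples$cell_type == ct, ]
  list(samples = sub, counts = bundle$counts[, sub$sample_id])
}
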