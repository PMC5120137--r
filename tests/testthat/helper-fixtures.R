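# small shared fixtures, built in code

tiny_genome <- function(n = 50, seed = 42) {
  make_genome(n_genes = n, mean_length = 600, seed = seed)
}

# wrap a per-cell abundance matrix into a cell_abundance_table
# (cells_collected = 1 makes copies == per-cell abundances)
wrap_table <- function(ab, regimes, n_rep = 3) {
  meta <- sample_meta(colnames(ab), rep(regimes, each = n_rep), "t2",
                      rep(seq_len(n_rep), times = length(regimes)),
                      cells_collected = 1)
  per_cell(ab, meta)
}

# abundance table from regime mean profiles + multiplicative lognormal
# replicate noise (no sequencing step) -- for stats/clustering tests
regime_table <- function(means, cv = 0.10, seed = 1) {
  regimes <- names(means)
  n_rep <- 3
  sdlog <- sqrt(log(1 + cv^2))
  ab <- withr::with_seed(seed, {
    cols <- lapply(regimes, function(r) {
      vapply(seq_len(n_rep), function(i)
        means[[r]] * rlnorm(length(means[[r]]), -sdlog^2 / 2, sdlog),
        numeric(length(means[[r]])))
    })
    do.call(cbind, cols)
  })
  colnames(ab) <- as.vector(vapply(regimes, function(r)
    sprintf("%s_rep%d", r, seq_len(n_rep)), character(n_rep)))
  rownames(ab) <- names(means[[1]])
  wrap_table(ab, regimes, n_rep)
}

# brute-force BH step-up straight from the definition (independent oracle)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
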