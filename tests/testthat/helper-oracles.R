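# Independent oracles used across the suite.

# Brute-force Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided rank-sum p by full enumeration of all C(N, m) subsets:
# P(|W - E W| >= |w_obs - E W|) for the observed set's rank-sum w_obs.
wilcox_enum_oracle <- function(statistics, in_set) {
  N <- length(statistics)
  m <- sum(in_set)
  r <- rank(statistics)
  w_obs <- sum(r[in_set])
  ws <- colSums(matrix(r[utils::combn(N, m)], nrow = m))
  ew <- mean(ws)
  mean(abs(ws - ew) >= abs(w_obs - ew))
}

# small noiseless screen configs used by several tests
noiseless_cfg <- function(..., seed) {
  screen_sim_config(..., noise_sd = 0, plate_effect_sd = 0,
                    gene_effect_sd = 0, seed = seed)
}
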