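# Shared fixtures, built in code at test time.

# small labeled partition: first `sizes[k]` nodes in network k
toy_partition <- function(sizes, labels = LETTERS[seq_along(sizes)]) {
  network_partition(default_node_ids(sum(sizes)),
                    rep(labels, times = sizes))
}

# random symmetric zero-diagonal matrix
random_symmetric <- function(n, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n, 0, sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# small cohort with D1DR attached
toy_cohort <- function(n_per_decade = 10, seed = 1) {
  coh <- simulate_cohort(n_per_decade, seed = seed)
  coh$d1dr_bpnd <- simulate_d1dr(coh$age, seed = seed + 1)
  coh
}

edge_within_mask_test <- function(partition) {
  ei <- edge_index(length(partition$node_ids))
  partition$network[ei$i] == partition$network[ei$j]
}

# hand Pearson correlation (loop oracle, no stats::cor)
pearson_loop <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
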