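# Shared fixtures and independent oracles.

# Random two-condition count matrix with lengths; guarantees at least one
# nonzero count per condition.
random_count_matrix <- function(n = 20, lambda = 8,
                                conditions = c("normal", "stz")) {
  acc <- sprintf("P%03d", seq_len(n))
  counts <- matrix(rpois(2L * n, lambda), ncol = 2L,
                   dimnames = list(acc, conditions))
  counts[1L, ] <- pmax(counts[1L, ], 1L)
  lens <- setNames(sample(50:500, n, replace = TRUE), acc)
  count_matrix(counts, conditions, lengths = lens)
}

# Rsc computed the textbook way (two explicit log2 calls), independent of
# the package's natural-log implementation.
rsc_oracle <- function(n_s, n_n, t_s, t_n, f = 1.25) {
  log2((n_s + f) / (n_n + f)) + log2((t_n - n_n + f) / (t_s - n_s + f))
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# size-n draws from N items of which the first K are in the category.
hyper_tail_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  in_cat <- colSums(draws <= K)
  mean(in_cat >= k)
}

write_temp_tsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
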