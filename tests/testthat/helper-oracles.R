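# Independent brute-force oracles used across the suite. These stay
# deliberately naive (string loops, explicit combinatorics) so they share
# no code path with the implementation they check.

# Per-window rescan: count exact ACGT-only windows equal to `oct`.
oracle_count_occurrences <- function(seqs, oct) {
  total <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < nchar(oct)) next
    for (i in seq_len(L - nchar(oct) + 1L)) {
      w <- substr(s, i, i + nchar(oct) - 1L)
      if (w == oct) total <- total + 1L
    }
  }
  total
}

# Valid (ACGT-only) octamer windows in a set of sequences.
oracle_valid_windows <- function(seqs, k = 8L) {
  total <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1L))
      if (grepl("^[ACGT]+$", substr(s, i, i + k - 1L)))
        total <- total + 1L
  }
  total
}

# One-sided Fisher enrichment P by explicit hypergeometric tail summation
# (log-binomial arithmetic; independent of stats::phyper / fisher.test).
oracle_fisher_p <- function(count_set, windows_set, count_rest,
                            windows_rest) {
  m <- count_set + count_rest            # successes in the urn
  total <- windows_set + windows_rest
  jmax <- min(windows_set, m)
  j <- count_set:jmax
  if (length(j) == 0L) return(1)
  terms <- lchoose(m, j) + lchoose(total - m, windows_set - j) -
    lchoose(total, windows_set)
  sum(exp(terms))
}

# Random promoter-like sequence (plain R, independent of the generator).
oracle_random_seq <- function(L, letters = c("A", "C", "G", "T"),
                              prob = NULL) {
  paste(sample(letters, L, replace = TRUE, prob = prob), collapse = "")
}
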