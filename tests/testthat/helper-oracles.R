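# Independent oracles used across the test files.

# Naive full-matrix affine-gap Smith-Waterman, O(mn) with explicit state
# matrices; deliberately independent of the package's kernel.
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  if (m == 0 || n == 0) return(0)
  S <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(0, m + 1, n + 1)
  Fm <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(0, E[i - 1, j] - ge, H[i - 1, j] - go - ge)
      Fm[i, j] <- max(0, Fm[i, j - 1] - ge, H[i, j - 1] - go - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], Fm[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Two-sided Fisher exact p by direct hypergeometric enumeration with
# explicit log-binomial arithmetic (probability-ordering definition, with
# the customary relative guard for floating-point ties).
fisher_oracle <- function(ht, nt, hb, nb) {
  k <- ht + hb
  x <- max(0, k - nb):min(k, nt)
  logp <- lchoose(nt, x) + lchoose(nb, k - x) - lchoose(nt + nb, k)
  p <- exp(logp)
  pobs <- p[x == ht]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

random_peptides <- function(n, max_len = 30, min_len = 1) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  lens <- min_len:max_len
  vapply(seq_len(n), function(i)
    paste(sample(aa, lens[sample.int(length(lens), 1)], replace = TRUE),
          collapse = ""), character(1))
}

# Single-isoform proteome from a named sequence vector.
toy_proteome <- function(species_id, reg_class, seqs) {
  proteome(species_id, reg_class,
           lapply(seqs, function(s) setNames(s, "t1")))
}
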