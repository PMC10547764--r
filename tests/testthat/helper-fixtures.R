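# shared fixtures: a small n=4 construct and independent oracles

toy_design <- function(n = 4) {
  suppressWarnings(library_design("TTGGA", "CCAAT", n))
}

# brute-force relative binding energy, written against the defining formula
# with explicit loops; independent of the vectorized implementation
oracle_ddg <- function(input_counts, bound_counts, pseudocount = 0) {
  pi <- (input_counts + pseudocount) / sum(input_counts + pseudocount)
  pb <- (bound_counts + pseudocount) / sum(bound_counts + pseudocount)
  out <- rep(NA_real_, length(pi))
  for (i in seq_along(pi)) {
    if (pi[i] > 0 && pb[i] > 0) out[i] <- -log2(pb[i] / pi[i])
  }
  names(out) <- names(input_counts)
  out
}

# naive substring scan, the oracle for core_mask
oracle_mask <- function(seqs, core) {
  hit <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    w <- nchar(core)
    for (s in seq_len(n - w + 1L)) {
      if (substr(seqs[i], s, s + w - 1L) == core) { hit[i] <- TRUE; break }
    }
  }
  seqs[hit]
}

random_count_table <- function(design, pool = "input", max_count = 50) {
  sp <- enumerate_space(design$n)
  counts <- stats::setNames(sample.int(max_count + 1L, length(sp$sequences),
                                       replace = TRUE) - 1L,
                            sp$sequences)
  count_table_from_counts(counts, design, pool)
}

# well-formed read pairs carrying the given cores
make_pairs <- function(cores, design) {
  r1 <- paste0(design$left_flank, cores, design$right_flank)
  list(read1 = r1, read2 = reverse_complement(r1))
}
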