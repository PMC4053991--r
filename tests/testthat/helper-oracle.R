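# Exhaustive-DP reference implementations used as oracles in the tests.
# Deliberately simple and independent of the package's C++ kernel.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# full affine-gap Smith-Waterman score (gap of length L costs open + L * ext)
oracle_sw_score <- function(q, s, score_fun, gap_open, gap_ext) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  gi <- gap_open + gap_ext
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - gi, E[i - 1, j] - gap_ext)
      F[i, j] <- max(H[i, j - 1] - gi, F[i, j - 1] - gap_ext)
      d <- H[i - 1, j - 1] + score_fun(qc[i - 1], sc[j - 1])
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

oracle_blosum62 <- local({
  # independent reference matrix, not the package's own table
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  M <- e$BLOSUM62
  function(a, b) M[a, b]
})

oracle_nt_score <- function(a, b) if (a == b && a != "N") 1L else -2L

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# naive entropy for cross-checks
oracle_entropy <- function(x) {
  p <- x / sum(x); p <- p[p > 0]
  -sum(p * log2(p))
}

# tiny deterministic two-exon transcript on a synthetic chromosome
make_toy_tx <- function(id = "tx1", gene = "g1", chrom = "chrZ",
                        starts = c(100L, 300L), ends = c(200L, 380L),
                        strand = "+", sequence = NULL) {
  ex <- genomic_intervals(chrom, starts, ends, strand)
  if (is.null(sequence))
    sequence <- paste(rep("A", sum(ends - starts)), collapse = "")
  transcript_model(id, gene, ex, strand = strand, sequence = sequence)
}
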