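#' Local sequence alignment and similarity searches
#'
#' The package carries its own seed-and-extend local aligner: exact k-mer
#' seeds (k = 4 for peptides, k = 11 for nucleotides) grouped by diagonal,
#' with clusters of two or more nearby-diagonal seeds extended by exact
#' affine-gap Smith-Waterman on a subject window around the cluster.
#' Expectation values follow Karlin-Altschul statistics,
#' E = K * m * n * exp(-lambda * S), with constants from standard published
#' tables for the scoring schemes in use (BLOSUM62 with gap open 11 /
#' extend 1: lambda = 0.267, K = 0.041; nucleotide match +1 / mismatch -2:
#' lambda = 1.28, K = 0.46).
#'
#' @name alignment
NULL

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")
NT_LETTERS <- c("A", "C", "G", "T", "N")

# BLOSUM62 over the 20 canonical residues; X scores -1 against everything.
blosum62_matrix <- function() {
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m <- matrix(v, 20, 20, byrow = TRUE)
  m <- rbind(cbind(m, -1L), -1L)
  dimnames(m) <- list(AA_LETTERS, AA_LETTERS)
  storage.mode(m) <- "integer"
  m
}

nt_matrix <- function(match = 1L, mismatch = -2L) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(NT_LETTERS, NT_LETTERS))
  diag(m)[1:4] <- match
  m[5L, 5L] <- mismatch
  storage.mode(m) <- "integer"
  m
}

encode_seq <- function(x, letters) {
  # byte-level lookup table; unknown letters -> last code
  tab <- rep.int(length(letters), 256L)
  tab[utf8ToInt(paste(letters, collapse = ""))] <- seq_along(letters)
  tab[utf8ToInt(tolower(paste(letters, collapse = "")))] <- seq_along(letters)
  ints <- utf8ToInt(x)
  ints[ints > 256L] <- 256L   # any non-ASCII character -> unknown
  as.integer(tab[ints] - 1L)
}

#' Exact local alignment score and ranges
#'
#' Full affine-gap Smith-Waterman between two sequences; a gap of length L
#' costs `gap_open + L * gap_ext`.
#'
#' @param query,subject character sequences.
#' @param type `"protein"` (BLOSUM62, 11/1) or `"nucleotide"` (+1/-2, 5/2).
#' @return list with `score` and 0-based half-open `q_start`, `q_end`,
#'   `s_start`, `s_end` of the optimal local alignment.
#' @export
local_align <- function(query, subject, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (type == "protein")
    sw_align_cpp(encode_seq(query, AA_LETTERS), encode_seq(subject, AA_LETTERS),
                 blosum62_matrix(), 11L, 1L)
  else
    sw_align_cpp(encode_seq(query, NT_LETTERS), encode_seq(subject, NT_LETTERS),
                 nt_matrix(), 5L, 2L)
}

karlin_altschul_evalue <- function(score, m, n, lambda, K) {
  K * m * n * exp(-lambda * score)
}

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

# translate the 3 forward frames of a nucleotide string to peptides
translate_frames <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  gc_tab <- codon_table()
  vapply(0:2, function(f) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) return("")
    at <- f + 3L * (seq_len(ncod) - 1L) + 1L
    aa <- gc_tab[substring(s, at, at + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "")
}

# six-frame translation: 3 forward + 3 of the reverse complement
six_frame_translations <- function(seq) {
  c(translate_frames(seq), translate_frames(revcomp(seq)))
}

# shared engine: encoded queries against encoded subjects, scores -> E-values
run_seeded_search <- function(queries, subjects, type, min_seeds = NULL,
                              diag_band = 10L, window_margin = 25L,
                              search_space = NULL) {
  if (type == "protein") {
    letters <- AA_LETTERS; sub <- blosum62_matrix()
    k <- 4L; go <- 11L; ge <- 1L; lambda <- 0.267; K <- 0.041
    alpha <- 20L
    if (is.null(min_seeds)) min_seeds <- 3L
  } else {
    letters <- NT_LETTERS; sub <- nt_matrix()
    k <- 11L; go <- 5L; ge <- 2L; lambda <- 1.28; K <- 0.46
    alpha <- 4L
    if (is.null(min_seeds)) min_seeds <- 2L
  }
  enc_q <- lapply(queries, encode_seq, letters = letters)
  enc_s <- lapply(subjects, encode_seq, letters = letters)
  hits <- seeded_search_cpp(enc_q, enc_s, k, alpha, sub, go, ge,
                            as.integer(min_seeds), as.integer(diag_band),
                            as.integer(window_margin))
  if (is.null(search_space)) {
    m <- sum(nchar(queries)); n <- sum(nchar(subjects))
    search_space <- as.numeric(m) * as.numeric(n)
  }
  hits$evalue <- karlin_altschul_evalue(hits$score, 1, search_space, lambda, K)
  hits$bit_score <- (lambda * hits$score - log(K)) / log(2)
  hits[order(hits$evalue), , drop = FALSE]
}

#' Search six-frame translations of a transcript against a protein set
#'
#' Peptide seed-and-extend search (k = 4 exact seeds, BLOSUM62, affine gaps
#' open 11 / extend 1) of all six translation frames against every subject.
#' E-values use a search space of (summed frame lengths) x (summed subject
#' lengths).
#'
#' @param query a [transcript_model()] or a nucleotide string.
#' @param proteins named character vector of peptide sequences.
#' @return data.frame of hits: `query_id`, `subject_id`, `frame` (1-6),
#'   `score`, `bit_score`, `evalue`, aligned ranges (`q_start`, `q_end` in
#'   frame peptide coordinates, `s_start`, `s_end`), sorted by `evalue`.
#' @export
protein_similarity_search <- function(query, proteins) {
  if (length(proteins) == 0L) stop("protein set must be non-empty")
  seq <- if (inherits(query, "transcript_model")) query$sequence else query
  id <- if (inherits(query, "transcript_model")) query$transcript_id else "query"
  if (is.na(seq) || nchar(seq) < 3L)
    stop("query shorter than one codon; apply the size filter first")
  frames <- six_frame_translations(seq)
  m <- sum(nchar(frames)); n <- sum(nchar(proteins))
  hits <- run_seeded_search(frames, unname(proteins), "protein",
                            search_space = as.numeric(m) * as.numeric(n))
  data.frame(query_id = rep(id, nrow(hits)),
             subject_id = names(proteins)[hits$subject],
             frame = hits$query, score = hits$score,
             bit_score = hits$bit_score, evalue = hits$evalue,
             q_start = hits$q_start, q_end = hits$q_end,
             s_start = hits$s_start, s_end = hits$s_end,
             stringsAsFactors = FALSE)
}

#' Nucleotide similarity search
#'
#' Seed-and-extend nucleotide search (k = 11 exact seeds, match +1 /
#' mismatch -2, affine gaps open 5 / extend 2) of each query and its reverse
#' complement against the subject set.
#'
#' @param queries named character vector of nucleotide sequences.
#' @param subjects named character vector of nucleotide sequences.
#' @return data.frame of best hits per query/subject/orientation:
#'   `query_id`, `subject_id`, `strand`, `score`, `bit_score`, `evalue`,
#'   aligned ranges; sorted by `evalue`.
#' @export
nucleotide_similarity_search <- function(queries, subjects) {
  if (length(subjects) == 0L) stop("subject set must be non-empty")
  if (length(queries) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      strand = character(), score = integer(),
                      bit_score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  both <- c(queries, revcomp(queries))
  strands <- rep(c("+", "-"), each = length(queries))
  qids <- rep(names(queries), 2L)
  space <- as.numeric(sum(nchar(queries))) * as.numeric(sum(nchar(subjects)))
  hits <- run_seeded_search(unname(both), unname(subjects), "nucleotide",
                            search_space = space)
  data.frame(query_id = qids[hits$query],
             subject_id = names(subjects)[hits$subject],
             strand = strands[hits$query], score = hits$score,
             bit_score = hits$bit_score, evalue = hits$evalue,
             q_start = hits$q_start, q_end = hits$q_end,
             s_start = hits$s_start, s_end = hits$s_end,
             stringsAsFactors = FALSE)
}
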