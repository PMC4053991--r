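#' Coding-potential scoring
#'
#' A trainable protein-coding-score test in the spirit of ORF-feature
#' classifiers: a logistic model on (i) log longest-ORF length in amino
#' acids, (ii) ORF coverage (ORF nt / transcript nt), (iii) a completeness
#' flag for the longest ORF, and (iv) the mean hexamer log-odds of the
#' transcript under coding vs noncoding 6-mer tables estimated from labeled
#' training sequences. A transcript is called coding iff its score (the
#' model's linear predictor) exceeds 0.
#'
#' @name coding_potential
NULL

count_hexamers <- function(seqs, pseudocount = 1) {
  kmers <- unlist(lapply(toupper(seqs), function(s) {
    if (nchar(s) < 6L) return(character())
    substring(s, 1:(nchar(s) - 5L), 6:nchar(s))
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  tab <- table(factor(kmers, levels = all_hexamers()))
  as.numeric(tab) + pseudocount
}

all_hexamers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T")
      cache <<- do.call(paste0, expand.grid(b, b, b, b, b, b,
                                            stringsAsFactors = FALSE)[, 6:1])
    }
    cache
  }
})

hexamer_logodds <- function(seq, logodds_table) {
  s <- toupper(seq)
  if (nchar(s) < 6L) return(0)
  kmers <- substring(s, 1:(nchar(s) - 5L), 6:nchar(s))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(0)
  mean(logodds_table[kmers])
}

orf_features <- function(seq) {
  orfs <- find_orfs(seq, strand = ".")
  if (nrow(orfs) == 0L)
    return(c(log_orf_aa = 0, orf_coverage = 0, orf_complete = 0))
  # features describe the putative CDS: the longest complete ORF when one
  # exists; a long open frame without start and stop is weaker evidence
  top <- if (any(orfs$complete)) orfs[orfs$complete, ][1L, ] else orfs[1L, ]
  c(log_orf_aa = log(top$aa_length + 1),
    orf_coverage = (top$end - top$start) / nchar(seq),
    orf_complete = as.numeric(top$complete))
}

#' Train the coding-potential model
#'
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences, each of length at least 50.
#' @return an object of class `coding_model`.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs) {
  if (length(coding_seqs) < 50L || length(noncoding_seqs) < 50L)
    stop("each training set needs at least 50 sequences")
  lo <- stats::setNames(
    log(count_hexamers(coding_seqs) / sum(count_hexamers(coding_seqs))) -
      log(count_hexamers(noncoding_seqs) / sum(count_hexamers(noncoding_seqs))),
    all_hexamers())
  feats <- function(seqs) t(vapply(seqs, function(s)
    c(orf_features(s), hexamer = hexamer_logodds(s, lo)),
    numeric(4)))
  x <- rbind(feats(coding_seqs), feats(noncoding_seqs))
  y <- c(rep(1L, length(coding_seqs)), rep(0L, length(noncoding_seqs)))
  df <- data.frame(x, y = y)
  fit <- suppressWarnings(
    stats::glm(y ~ log_orf_aa + orf_coverage + orf_complete + hexamer,
               data = df, family = stats::binomial()))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(coefficients = cf, logodds = lo),
            class = "coding_model")
}

#' Score coding potential of transcripts
#'
#' @param transcripts an [annotation_set()], a list of transcript models, or
#'   a character vector of sequences.
#' @param model a trained [train_coding_model()] object.
#' @return data.frame with `transcript_id`, `score` (logistic linear
#'   predictor) and `verdict` (`"coding"` iff score > 0, else
#'   `"noncoding"`).
#' @export
coding_potential_score <- function(transcripts, model) {
  if (!inherits(model, "coding_model"))
    stop("coding-potential model has not been trained")
  if (inherits(transcripts, "annotation_set"))
    transcripts <- transcripts$transcripts
  if (is.character(transcripts)) {
    ids <- if (is.null(names(transcripts)))
      paste0("seq", seq_along(transcripts)) else names(transcripts)
    seqs <- unname(transcripts)
  } else {
    ids <- vapply(transcripts, `[[`, "", "transcript_id")
    seqs <- vapply(transcripts, `[[`, "", "sequence")
  }
  b <- model$coefficients
  score <- vapply(seqs, function(s) {
    f <- c(1, orf_features(s), hexamer_logodds(s, model$logodds))
    sum(b * f)
  }, 0, USE.NAMES = FALSE)
  data.frame(transcript_id = ids, score = score,
             verdict = ifelse(score > 0, "coding", "noncoding"),
             stringsAsFactors = FALSE)
}
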