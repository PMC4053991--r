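#' Find open reading frames in a transcript
#'
#' Scans the three forward frames of the transcript sequence and, when the
#' transcript strand is unknown, also the three frames of the reverse
#' complement. An ORF is ATG..stop (complete, the stop codon included in its
#' span), ATG-to-sequence-end (incomplete, no downstream in-frame stop), or
#' frame-start-to-first-stop when no ATG precedes that stop (incomplete,
#' start codon presumed upstream of the transcript). A frame with neither
#' ATG nor stop yields one incomplete ORF covering the whole frame.
#'
#' @param transcript a [transcript_model()] or a nucleotide string
#'   (alphabet ACGTN; anything else is an error).
#' @param strand override the transcript's strand (`"+"`, `"-"`, `"."`).
#' @return data.frame of ORF calls sorted by `aa_length` descending:
#'   `start`, `end` (0-based half-open coordinates in the scanned sequence),
#'   `strand_of_scan` (`"sense"`/`"antisense"`), `frame` (0-2), `aa_length`,
#'   `complete`. Complete ORFs span start codon through stop codon;
#'   `aa_length` excludes the stop.
#' @export
find_orfs <- function(transcript, strand = NULL) {
  seq <- if (inherits(transcript, "transcript_model")) transcript$sequence
         else transcript
  if (is.null(strand))
    strand <- if (inherits(transcript, "transcript_model")) transcript$strand
              else "."
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains non-nucleotide characters beyond N")
  scans <- list(sense = seq)
  if (strand == ".") scans$antisense <- revcomp(seq)
  out <- do.call(rbind, lapply(names(scans), function(sc) {
    do.call(rbind, lapply(0:2, function(f)
      scan_frame_orfs(scans[[sc]], f, sc)))
  }))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand_of_scan = character(), frame = integer(),
                      aa_length = integer(), complete = logical()))
  out <- out[order(-out$aa_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_frame_orfs <- function(seq, frame, scan_label) {
  n <- nchar(seq)
  ncod <- (n - frame) %/% 3L
  if (ncod < 1L) return(NULL)
  starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L   # 1-based codon starts
  codons <- substring(seq, starts, starts + 2L)
  is_atg <- codons == "ATG"
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  orf <- list()
  add <- function(c0, c1, complete) {
    # codon indices [c0, c1] inclusive, 1-based into `codons`
    s <- frame + 3L * (c0 - 1L)
    e <- frame + 3L * c1
    aa <- (e - s) %/% 3L - if (complete) 1L else 0L
    if (aa > 0L)
      orf[[length(orf) + 1L]] <<- data.frame(
        start = s, end = e, strand_of_scan = scan_label, frame = frame,
        aa_length = aa, complete = complete, stringsAsFactors = FALSE)
  }
  stop_idx <- which(is_stop)
  prev_stop <- 0L
  for (st in stop_idx) {
    atg <- which(is_atg[seq_len(st - 1L)] &
                 seq_len(st - 1L) > prev_stop)
    if (length(atg)) add(atg[1L], st, complete = TRUE)
    else if (st > prev_stop + 0L && prev_stop == 0L)
      add(1L, st, complete = FALSE)   # leading frame-start-to-stop
    prev_stop <- st
  }
  # trailing region after the last stop (or whole frame if no stop)
  tail_atg <- which(is_atg & seq_along(is_atg) > prev_stop)
  if (length(tail_atg)) add(tail_atg[1L], ncod, complete = FALSE)
  else if (prev_stop == 0L) add(1L, ncod, complete = FALSE)
  if (length(orf)) do.call(rbind, orf) else NULL
}

#' Longest complete ORF length of a transcript, in amino acids
#'
#' @param transcript as in [find_orfs()].
#' @param strand as in [find_orfs()].
#' @return integer amino-acid length (0 if no complete ORF).
#' @export
longest_complete_orf <- function(transcript, strand = NULL) {
  orfs <- find_orfs(transcript, strand)
  cmpl <- orfs[orfs$complete, , drop = FALSE]
  if (nrow(cmpl) == 0L) 0L else max(cmpl$aa_length)
}

#' Size and ORF filter
#'
#' A transcript survives iff it is at least `min_len` nt long and its
#' longest complete ORF is at most `max_orf_aa` amino acids; incomplete
#' ORFs never disqualify.
#'
#' @param annotation an [annotation_set()].
#' @param min_len minimum transcript length in nt (default 200).
#' @param max_orf_aa maximum complete-ORF length in amino acids (default 100).
#' @return list with `candidates` (an [annotation_set()]) and `excluded`
#'   (data.frame: `transcript_id`, `label` in `too_short`/`long_orf`,
#'   `evidence` — the length or offending ORF aa length).
#' @export
filter_size_and_orf <- function(annotation, min_len = 200L, max_orf_aa = 100L) {
  txs <- annotation$transcripts
  records <- lapply(txs, function(tx) {
    len <- length(tx)
    if (len < min_len)
      return(data.frame(transcript_id = tx$transcript_id, label = "too_short",
                        evidence = len, stringsAsFactors = FALSE))
    orf <- longest_complete_orf(tx)
    if (orf > max_orf_aa)
      return(data.frame(transcript_id = tx$transcript_id, label = "long_orf",
                        evidence = orf, stringsAsFactors = FALSE))
    NULL
  })
  excluded <- do.call(rbind, records[!vapply(records, is.null, TRUE)])
  if (is.null(excluded))
    excluded <- data.frame(transcript_id = character(), label = character(),
                           evidence = numeric(), stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  keep <- setdiff(names(txs), excluded$transcript_id)
  list(candidates = annotation_set(unname(txs[keep])), excluded = excluded)
}
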