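#' Genomic intervals and transcript models
#'
#' All coordinates inside the package are 0-based half-open; conversion
#' to/from the 1-based inclusive GTF convention happens exactly once, at the
#' I/O boundary ([read_gtf()] / [write_gtf()]).
#'
#' @name coordinates
NULL

#' Create a set of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive.
#' @param strand one of `"+"`, `"-"`, `"."` (unknown), recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Construct a transcript model
#'
#' A transcript is an ordered chain of exons on one chromosome plus its
#' spliced sequence in transcript orientation (5'->3' when the strand is
#' known, reference orientation when unknown).
#'
#' @param transcript_id,gene_id identifiers.
#' @param exons a `data.frame` from [genomic_intervals()]; all exons must lie
#'   on one chromosome and must not overlap. Sorted by start internally.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param sequence spliced nucleotide sequence; length must equal the summed
#'   exon lengths (may be `NA` when no genome is at hand).
#' @param source `"annotation"` or `"assembly"`.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, exons, strand = ".",
                             sequence = NA_character_,
                             source = c("annotation", "assembly")) {
  source <- match.arg(source)
  stopifnot(nrow(exons) >= 1L)
  if (length(unique(exons$chrom)) != 1L)
    stop("exons of one transcript must share a chromosome")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons must not overlap")
  len <- sum(exons$end - exons$start)
  if (!is.na(sequence) && nchar(sequence) != len)
    stop(sprintf("sequence length %d != summed exon length %d for %s",
                 nchar(sequence), len, transcript_id))
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 exons = exons, strand = strand, sequence = sequence,
                 source = source),
            class = "transcript_model")
}

#' @export
length.transcript_model <- function(x) sum(x$exons$end - x$exons$start)

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d(%s) %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$exons$chrom[1L],
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), length(x)))
  invisible(x)
}

#' Bundle transcripts into an annotation set
#'
#' @param transcripts a list of [transcript_model()] objects with unique ids.
#' @return an object of class `annotation_set` with elements `transcripts`
#'   (named list) and `loci` (list of transcript ids per gene_id).
#' @export
annotation_set <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ", ids[duplicated(ids)][1L])
  names(transcripts) <- ids
  genes <- vapply(transcripts, `[[`, "", "gene_id")
  structure(list(transcripts = transcripts,
                 loci = split(unname(ids), genes)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts in %d loci\n",
              length(x$transcripts), length(x$loci)))
  invisible(x)
}

#' Introns of a transcript
#'
#' @param tx a `transcript_model`.
#' @return 0-based half-open intron intervals (0-row data.frame if single-exon).
#' @export
transcript_introns <- function(tx) {
  e <- tx$exons
  if (nrow(e) < 2L)
    return(genomic_intervals(character(), integer(), integer())[0, ])
  data.frame(chrom = e$chrom[-nrow(e)], start = e$end[-nrow(e)],
             end = e$start[-1L], strand = tx$strand,
             stringsAsFactors = FALSE)
}

#' Genomic span of a transcript
#' @param tx a `transcript_model`.
#' @return list with `chrom`, `start`, `end` of the full locus span.
#' @export
transcript_span <- function(tx) {
  list(chrom = tx$exons$chrom[1L], start = min(tx$exons$start),
       end = max(tx$exons$end))
}

# reverse complement of a plain character sequence (ACGTN alphabet)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# extract spliced transcript sequence from a genome (named list of strings)
spliced_sequence <- function(exons, strand, genome) {
  chrom <- exons$chrom[1L]
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  gl <- nchar(genome[[chrom]])
  if (any(exons$end > gl)) stop("exon coordinates exceed genome bounds on ", chrom)
  seq <- paste(substring(genome[[chrom]], exons$start + 1L, exons$end),
               collapse = "")
  if (identical(strand, "-")) revcomp(seq) else seq
}
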