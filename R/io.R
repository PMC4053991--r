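#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' wrapped sequence lines are concatenated and whitespace stripped.
#'
#' @param path file path.
#' @return named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0L) return(stats::setNames(character(), character()))
  hdr <- grepl("^>", lines)
  if (!hdr[keep[1L]])
    stop(sprintf("FASTA format error at line %d: sequence before first header",
                 keep[1L]))
  bad <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad))
    stop(sprintf("FASTA format error at line %d: malformed header", bad[1L]))
  rec <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- vapply(split(lines[!hdr & !grepl("^\\s*$", lines)],
                       factor(rec[!hdr & !grepl("^\\s*$", lines)],
                              levels = seq_along(ids))),
                 function(x) gsub("\\s+", "", paste(x, collapse = "")),
                 "", USE.NAMES = FALSE)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    at <- which(hdr)[empty[1L]]
    stop(sprintf("FASTA format error at line %d: empty sequence for '%s'",
                 at, ids[empty[1L]]))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; each must carry `gene_id` and
#' `transcript_id` attributes. GTF 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention; strand `"."`
#' becomes unknown. When a genome is supplied, spliced sequences are
#' extracted (reverse-complemented for minus-strand transcripts).
#'
#' @param path GTF file path.
#' @param genome optional named list/vector of chromosome sequences.
#' @param source transcript origin recorded on each model
#'   (`"annotation"` or `"assembly"`).
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path, genome = NULL,
                     source = c("annotation", "assembly")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(annotation_set(list()))
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "exon")
  if (length(gr) == 0L) return(annotation_set(list()))
  m <- S4Vectors::mcols(gr)
  if (is.null(m$transcript_id) || anyNA(m$transcript_id))
    stop("GTF format error: exon feature without transcript_id attribute")
  if (is.null(m$gene_id) || anyNA(m$gene_id))
    stop("GTF format error: exon feature without gene_id attribute")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = m$gene_id, transcript_id = m$transcript_id,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  txs <- lapply(split(df, df$transcript_id), function(d) {
    strand <- d$strand[1L]
    ex <- genomic_intervals(d$chrom, d$start, d$end, strand)
    seq <- NA_character_
    if (!is.null(genome))
      seq <- spliced_sequence(ex[order(ex$start), , drop = FALSE], strand,
                              genome)
    transcript_model(d$transcript_id[1L], d$gene_id[1L], ex, strand,
                     sequence = seq, source = source)
  })
  annotation_set(unname(txs))
}

#' Write an annotation set to GTF
#'
#' Emits one `exon` line per exon with 1-based inclusive coordinates;
#' unknown strand is written `"."`. [read_gtf()] of the output reproduces
#' the input exon structures exactly.
#'
#' @param annotation an [annotation_set()].
#' @param path output path.
#' @param feature_source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, feature_source = "lncherit") {
  lines <- unlist(lapply(annotation$transcripts, function(tx) {
    e <- tx$exons
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            e$chrom, feature_source, e$start + 1L, e$end, tx$strand,
            tx$gene_id, tx$transcript_id)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited table against a column schema
#'
#' @param path TSV path with a header row.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`). `"NA"` cells in
#'   numeric columns become missing values.
#' @param allow_extra keep columns not named in the schema.
#' @return a `data.frame` with the schema's columns coerced to type.
#' @export
read_table_schema <- function(path, schema, allow_extra = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop("schema error: missing required column '", missing_cols[1L], "'")
  for (col in names(schema)) {
    x <- df[[col]]
    x[x == "NA"] <- NA
    if (schema[[col]] %in% c("numeric", "integer")) {
      y <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(y) & !is.na(x))
      if (length(bad))
        stop(sprintf("parse error in column '%s', row %d: '%s' is not numeric",
                     col, bad[1L], x[bad[1L]]))
      df[[col]] <- if (schema[[col]] == "integer") as.integer(y) else y
    } else df[[col]] <- x
  }
  if (!allow_extra) df <- df[, names(schema), drop = FALSE]
  df
}
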