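#' Expression quantification and tissue-specificity
#'
#' @name expression_profiles
NULL

#' Build an expression matrix container
#'
#' @param counts integer matrix, transcripts x samples.
#' @param transcript_lengths named vector of transcript lengths (nt).
#' @param library_sizes named vector of mapped reads per sample.
#' @param sample_tissue named character vector mapping sample -> tissue
#'   (defaults to one tissue per sample).
#' @return object of class `expression_matrix` with `counts`, `lengths`,
#'   `library_sizes`, `rpkm`, `sample_tissue`.
#' @export
expression_matrix <- function(counts, transcript_lengths, library_sizes,
                              sample_tissue = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lens <- transcript_lengths[rownames(counts)]
  libs <- library_sizes[colnames(counts)]
  if (anyNA(lens)) stop("missing transcript length")
  if (anyNA(libs)) stop("missing library size")
  if (is.null(sample_tissue))
    sample_tissue <- stats::setNames(colnames(counts), colnames(counts))
  structure(list(counts = counts, lengths = lens, library_sizes = libs,
                 rpkm = compute_rpkm(counts, lens, libs),
                 sample_tissue = sample_tissue[colnames(counts)]),
            class = "expression_matrix")
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm[i, j] = counts[i, j] / (length_kb[i] * library_size_millions[j])`.
#'
#' @param counts transcripts x samples matrix.
#' @param lengths transcript lengths in nt (> 0).
#' @param library_sizes mapped reads per sample (> 0).
#' @return RPKM matrix of the same shape.
#' @export
compute_rpkm <- function(counts, lengths, library_sizes) {
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  counts <- as.matrix(counts)
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, library_sizes / 1e6, "/")
}

#' Detection calls and per-transcript tissue counts
#'
#' A transcript is detected in a sample iff its count is at least
#' `min_reads`; samples collapse to tissues by "any sample detected"
#' (i.e. the per-tissue maximum count is thresholded).
#'
#' @param counts transcripts x samples matrix.
#' @param sample_tissue named character vector mapping samples to tissues
#'   (default: each sample its own tissue).
#' @param min_reads detection threshold (default 4).
#' @return list: `detected_sample` (logical matrix per sample),
#'   `detected_tissue` (logical matrix per tissue), `tissues_detected`
#'   (integer per transcript).
#' @export
detect_expressed <- function(counts, sample_tissue = NULL, min_reads = 4L) {
  counts <- as.matrix(counts)
  if (is.null(sample_tissue))
    sample_tissue <- stats::setNames(colnames(counts), colnames(counts))
  det <- counts >= min_reads
  tissues <- unique(unname(sample_tissue[colnames(counts)]))
  det_t <- vapply(tissues, function(tt) {
    cols <- which(sample_tissue[colnames(counts)] == tt)
    if (length(cols) == 1L) det[, cols] else apply(det[, cols, drop = FALSE],
                                                   1, any)
  }, logical(nrow(counts)))
  if (is.null(dim(det_t))) det_t <- matrix(det_t, nrow = nrow(counts),
                                           dimnames = list(rownames(counts),
                                                           tissues))
  list(detected_sample = det, detected_tissue = det_t,
       tissues_detected = rowSums(det_t))
}

#' Shannon entropy of a tissue expression profile, in bits
#'
#' With proportions p_t = x_t / sum(x), H = -sum over expressed tissues of
#' p_t log2 p_t: 0 bits for single-tissue expression, log2(T) for uniform
#' expression over T tissues.
#'
#' @param x non-negative expression vector over tissues, not all zero.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(x) {
  if (length(x) < 1L || any(x < 0)) stop("need non-negative values")
  s <- sum(x)
  if (s == 0) stop("entropy undefined for an all-zero profile")
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p)) + 0   # + 0 normalizes IEEE negative zero
}

#' Ward hierarchical clustering of expression profiles
#'
#' Optionally row z-scores the RPKM matrix (per-gene normalization), then
#' clusters rows by Ward linkage on Euclidean distances. Constant rows
#' cannot be z-scored and are dropped with a warning.
#'
#' @param rpkm transcripts x tissues matrix.
#' @param per_gene_normalize row z-score first (default TRUE).
#' @return list: `tree` (an `hclust`), `matrix` (rows in leaf order),
#'   `order` (row names in leaf order).
#' @export
cluster_expression <- function(rpkm, per_gene_normalize = TRUE) {
  m <- as.matrix(rpkm)
  if (nrow(m) < 2L) stop("need at least two transcripts to cluster")
  if (per_gene_normalize) {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant row(s) dropped before clustering")
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    m <- (m - rowMeans(m)) / sds
  }
  tree <- stats::hclust(stats::dist(m), method = "ward.D2")
  ord <- rownames(m)[tree$order]
  list(tree = tree, matrix = m[tree$order, , drop = FALSE], order = ord)
}

# per-chromosome prefix sums of a per-base track for O(1) range means
track_prefix <- function(track, genome_lengths) {
  lapply(stats::setNames(names(genome_lengths), names(genome_lengths)),
         function(ch) {
    n <- genome_lengths[[ch]]
    v <- numeric(n)
    d <- track[track$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    cumsum(v)
  })
}

range_mean <- function(prefix, start, end) {
  # 0-based half-open [start, end)
  (prefix[end] - if (start > 0L) prefix[start] else 0) / (end - start)
}

#' Metagene profile of an epigenetic track over a set of loci
#'
#' Each locus body is mapped onto `body_bins` bins by linear coordinate
#' scaling (bin value = mean of overlapped base values); the 1-kb flanks
#' are taken at native 1-bp resolution. Minus-strand loci are flipped so
#' that upstream is always 5'. Profiles are averaged over loci.
#'
#' @param loci an [annotation_set()] (locus span = transcript span).
#' @param track data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open intervals with constant value).
#' @param genome_lengths named vector of chromosome lengths; the track must
#'   cover each locus +/- `flank` bp.
#' @param context label recorded on the result (e.g. "CG", "H3K27me3").
#' @param body_bins number of body bins (default 1000).
#' @param flank flank width in bp (default 1000).
#' @return object of class `metagene_profile`: list with `upstream`,
#'   `body`, `downstream` numeric vectors and `context`, `n_loci`.
#' @export
metagene_profile <- function(loci, track, genome_lengths, context = "track",
                             body_bins = 1000L, flank = 1000L) {
  prefix <- track_prefix(track, genome_lengths)
  up <- matrix(0, length(loci$transcripts), flank)
  dn <- matrix(0, length(loci$transcripts), flank)
  body <- matrix(0, length(loci$transcripts), body_bins)
  for (i in seq_along(loci$transcripts)) {
    tx <- loci$transcripts[[i]]
    sp <- transcript_span(tx)
    pf <- prefix[[sp$chrom]]
    gl <- length(pf)
    if (sp$start - flank < 0L || sp$end + flank > gl)
      stop("track/genome does not cover locus +/- flank: ", tx$transcript_id)
    u <- vapply(seq_len(flank), function(j)
      range_mean(pf, sp$start - flank + j - 1L, sp$start - flank + j), 0)
    d <- vapply(seq_len(flank), function(j)
      range_mean(pf, sp$end + j - 1L, sp$end + j), 0)
    len <- sp$end - sp$start
    edges <- sp$start + round(seq(0, len, length.out = body_bins + 1L))
    b <- vapply(seq_len(body_bins), function(j) {
      s <- edges[j]; e <- max(edges[j + 1L], s + 1L)
      e <- min(e, sp$end); s <- min(s, e - 1L)
      range_mean(pf, s, e)
    }, 0)
    if (identical(tx$strand, "-")) {
      tmp <- rev(u); u <- rev(d); d <- tmp; b <- rev(b)
    }
    up[i, ] <- u; dn[i, ] <- d; body[i, ] <- b
  }
  structure(list(upstream = colMeans(up), body = colMeans(body),
                 downstream = colMeans(dn), context = context,
                 n_loci = length(loci$transcripts)),
            class = "metagene_profile")
}

#' Compare an epigenetic mark between silent and expressed loci
#'
#' Loci are split by RPKM in `tissue`: silent (RPKM = 0) vs expressed
#' (RPKM > `expressed_min`); loci in (0, `expressed_min`] are excluded.
#' The mean mark level over each locus body is compared between groups by a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param loci an [annotation_set()].
#' @param track,genome_lengths as in [metagene_profile()].
#' @param rpkm transcripts x tissues matrix (rownames = transcript ids).
#' @param tissue column of `rpkm` to use.
#' @param expressed_min expressed threshold (default 1).
#' @return list: `silent` / `expressed` (named vectors of mean body mark),
#'   `p_value` (NA with a warning when a group is empty), `statistic`.
#' @export
mark_by_expression_state <- function(loci, track, genome_lengths, rpkm,
                                     tissue, expressed_min = 1) {
  if (!tissue %in% colnames(rpkm)) stop("tissue not in rpkm: ", tissue)
  prefix <- track_prefix(track, genome_lengths)
  ids <- names(loci$transcripts)
  body_mean <- vapply(loci$transcripts, function(tx) {
    sp <- transcript_span(tx)
    range_mean(prefix[[sp$chrom]], sp$start, sp$end)
  }, 0)
  expr <- rpkm[ids, tissue]
  silent <- body_mean[expr == 0]
  expressed <- body_mean[expr > expressed_min]
  if (length(silent) == 0L || length(expressed) == 0L) {
    warning("a group is empty; rank-sum comparison skipped")
    return(list(silent = silent, expressed = expressed,
                p_value = NA_real_, statistic = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(silent, expressed,
                                            alternative = "two.sided"))
  list(silent = silent, expressed = expressed, p_value = wt$p.value,
       statistic = unname(wt$statistic))
}
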