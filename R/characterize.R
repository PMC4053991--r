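#' Genomic characterization of lncRNA loci
#'
#' Strand inference by the GT-AG splice rule, anatomy relative to the
#' nearest gene (5-kb proximity classes), chromosomal bin densities,
#' length/exon statistics, and a permutation test of cross-species sequence
#' conservation against length-matched intergenic or intronic background
#' draws.
#'
#' @name locus_characterization
NULL

#' Infer transcript orientation from GT-AG splice sites
#'
#' @param transcript a [transcript_model()] with at least one intron
#'   (single-exon transcripts return `"."` immediately).
#' @param genome named list/vector of chromosome sequences.
#' @return `"+"` iff every intron reads GT..AG on the forward genome strand,
#'   `"-"` iff every intron's reverse complement reads GT..AG, otherwise
#'   (neither, or both) `"."`.
#' @export
infer_orientation_gt_ag <- function(transcript, genome) {
  introns <- transcript_introns(transcript)
  if (nrow(introns) == 0L) return(".")
  chrom <- introns$chrom[1L]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  gl <- nchar(genome[[chrom]])
  if (any(introns$end > gl)) stop("intron beyond genome bounds on ", chrom)
  donor <- substring(genome[[chrom]], introns$start + 1L, introns$start + 2L)
  accep <- substring(genome[[chrom]], introns$end - 1L, introns$end)
  fwd <- all(donor == "GT" & accep == "AG")
  # reverse complement of the intron reads GT..AG  <=>  forward reads CT..AC
  rev <- all(donor == "CT" & accep == "AC")
  if (fwd && !rev) "+" else if (rev && !fwd) "-" else "."
}

#' Classify lncRNAs by position relative to the nearest gene
#'
#' A lncRNA whose span overlaps any gene span is `genic_overlap`; otherwise
#' the edge-to-edge distance to the nearest gene decides
#' `upstream_within_5kb` / `downstream_within_5kb` (<= `max_dist` bp) or
#' `distal_intergenic`. Upstream/downstream is relative to the nearest
#' gene's strand (unknown-strand genes treated as plus); nearest-gene ties
#' break toward the smaller `gene_id`.
#'
#' @param lncrnas,genes [annotation_set()]s on the same chromosome
#'   namespace.
#' @param max_dist proximity cutoff in bp (default 5000).
#' @return data.frame: `transcript_id`, `category`, `distance_bp`,
#'   `nearest_gene_id`.
#' @export
classify_anatomy <- function(lncrnas, genes, max_dist = 5000L) {
  if (length(genes$transcripts) == 0L)
    stop("gene set must be non-empty")
  gene_spans <- do.call(rbind, lapply(genes$transcripts, function(tx) {
    sp <- transcript_span(tx)
    data.frame(gene_id = tx$gene_id, chrom = sp$chrom, start = sp$start,
               end = sp$end, strand = tx$strand, stringsAsFactors = FALSE)
  }))
  # collapse to one span per gene_id
  gene_spans <- do.call(rbind, lapply(split(gene_spans, gene_spans$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
                           start = min(d$start), end = max(d$end),
                           strand = d$strand[1L], stringsAsFactors = FALSE)))
  gene_spans <- gene_spans[order(gene_spans$gene_id), , drop = FALSE]
  calls <- lapply(lncrnas$transcripts, function(tx) {
    sp <- transcript_span(tx)
    g <- gene_spans[gene_spans$chrom == sp$chrom, , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(transcript_id = tx$transcript_id,
                        category = "distal_intergenic",
                        distance_bp = NA_integer_,
                        nearest_gene_id = NA_character_,
                        stringsAsFactors = FALSE))
    ov <- g$start < sp$end & g$end > sp$start
    if (any(ov)) {
      nearest <- g$gene_id[ov][1L]   # g sorted by gene_id: tie -> smaller id
      return(data.frame(transcript_id = tx$transcript_id,
                        category = "genic_overlap", distance_bp = 0L,
                        nearest_gene_id = nearest, stringsAsFactors = FALSE))
    }
    dist <- ifelse(g$end <= sp$start, sp$start - g$end, g$start - sp$end)
    dmin <- min(dist)
    nearest <- g[dist == dmin, , drop = FALSE][1L, ]  # sorted: smaller id
    gene_strand <- if (nearest$strand == "-") "-" else "+"
    before_gene <- sp$end <= nearest$start   # lncRNA left of the gene
    side <- if ((before_gene && gene_strand == "+") ||
                (!before_gene && gene_strand == "-")) "upstream"
            else "downstream"
    category <- if (dmin > max_dist) "distal_intergenic"
                else paste0(side, "_within_5kb")
    data.frame(transcript_id = tx$transcript_id, category = category,
               distance_bp = as.integer(dmin),
               nearest_gene_id = nearest$gene_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Two-proportion z-test (pooled)
#'
#' @param count_a,total_a successes and trials in group A.
#' @param count_b,total_b successes and trials in group B.
#' @return list with `z` and two-sided `p_value`.
#' @export
proximity_proportion_test <- function(count_a, total_a, count_b, total_b) {
  if (total_a < 1L || total_b < 1L) stop("totals must be >= 1")
  p1 <- count_a / total_a; p2 <- count_b / total_b
  pp <- (count_a + count_b) / (total_a + total_b)
  se <- sqrt(pp * (1 - pp) * (1 / total_a + 1 / total_b))
  if (se == 0) return(list(z = 0, p_value = 1))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Transcript counts per fixed-size physical bin
#'
#' Each transcript is assigned to the half-open bin containing its span
#' start.
#'
#' @param annotation an [annotation_set()].
#' @param bin_size_bp bin width (default 10 Mb).
#' @param chrom_lengths optional named vector; when given, empty bins up to
#'   each chromosome's end are included.
#' @return data.frame: `chrom`, `bin` (0-based index), `start`, `count`.
#' @export
bin_density <- function(annotation, bin_size_bp = 1e7,
                        chrom_lengths = NULL) {
  stopifnot(bin_size_bp > 0)
  spans <- do.call(rbind, lapply(annotation$transcripts, function(tx) {
    sp <- transcript_span(tx)
    data.frame(chrom = sp$chrom, start = sp$start, stringsAsFactors = FALSE)
  }))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else unique(spans$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    s <- spans$start[spans$chrom == ch]
    maxbin <- if (!is.null(chrom_lengths))
      max(0L, as.integer(ceiling(chrom_lengths[[ch]] / bin_size_bp)) - 1L)
    else if (length(s)) as.integer(max(s) %/% bin_size_bp) else 0L
    bins <- 0:maxbin
    counts <- as.integer(table(factor(s %/% bin_size_bp, levels = bins)))
    data.frame(chrom = ch, bin = bins,
               start = as.numeric(bins) * bin_size_bp, count = counts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Length and exon-count statistics of a transcript set
#'
#' @param annotation an [annotation_set()].
#' @param length_breaks histogram bin edges for transcript length.
#' @return list: `lengths`, `exon_counts` (named vectors), `mean_length`,
#'   `median_length`, `length_hist` (counts per length bin),
#'   `exon_count_hist` (counts per exon number), `single_exon_fraction`.
#' @export
structure_stats <- function(annotation,
                            length_breaks = c(0, 200, 400, 600, 800, 1000,
                                              Inf)) {
  if (length(annotation$transcripts) == 0L) stop("empty transcript set")
  lens <- vapply(annotation$transcripts, length, 0L)
  nex <- vapply(annotation$transcripts, function(tx) nrow(tx$exons), 0L)
  list(lengths = lens, exon_counts = nex,
       mean_length = mean(lens), median_length = stats::median(lens),
       length_hist = table(cut(lens, length_breaks, right = TRUE)),
       exon_count_hist = table(nex),
       single_exon_fraction = mean(nex == 1L))
}

# sample one background region of a given length; intervals is a data.frame
# chrom,start,end. Weighted by the number of admissible starts.
sample_background_region <- function(len, intervals) {
  fits <- intervals[intervals$end - intervals$start >= len, , drop = FALSE]
  if (nrow(fits) == 0L) return(NULL)
  w <- fits$end - fits$start - len + 1L
  i <- sample.int(nrow(fits), 1L, prob = w)
  s <- fits$start[i] + sample.int(w[i], 1L) - 1L
  list(chrom = fits$chrom[i], start = s, end = s + len)
}

#' Permutation test of cross-species sequence conservation
#'
#' The observed statistic is the fraction of query sequences with a
#' nucleotide-search hit at E < `evalue_cutoff` against a target genome.
#' Each permutation draws `length(query)` background regions length-matched
#' to the query length distribution (a query length is sampled, then a
#' uniform start within a background interval that fits) from the
#' (repeat-masked) reference genome, and records the same fraction. The
#' two-sided empirical p doubles the smaller add-one tail probability;
#' one-sided tails are also returned.
#'
#' @param query named character vector of query sequences.
#' @param target_genomes named list; each element a named character vector
#'   of target chromosome sequences.
#' @param background data.frame of background intervals (`chrom`, `start`,
#'   `end`; 0-based half-open) on `genome`.
#' @param genome named list/vector of (repeat-masked) reference chromosome
#'   sequences.
#' @param n_perm number of permutations (default 1000).
#' @param evalue_cutoff significance cutoff (default 1e-10).
#' @return named list over targets; each element has `observed_proportion`,
#'   `null_proportions`, `empirical_p`, `p_upper`, `p_lower`.
#' @export
conservation_permutation_test <- function(query, target_genomes, background,
                                          genome, n_perm = 1000L,
                                          evalue_cutoff = 1e-10) {
  if (sum(background$end - background$start) < sum(nchar(query)))
    stop("background regions must cover at least the query total length")
  lens <- nchar(query)
  # draw all n_perm x |query| background regions at once; grouping by the
  # drawn length lets each group sample (interval, start) uniformly over
  # all admissible placements in one vectorized step
  widths <- background$end - background$start
  gvec <- unlist(genome)[as.character(unique(background$chrom))]
  n_draw <- n_perm * length(query)
  dl <- lens[sample.int(length(lens), n_draw, replace = TRUE)]
  unfit <- dl > max(widths)
  if (any(unfit)) {
    warning(sum(unfit), " sampled length(s) fit no background interval; ",
            "resampled from lengths that fit")
    fit_lens <- lens[lens <= max(widths)]
    if (length(fit_lens) == 0L) stop("no query length fits the background")
    dl[unfit] <- fit_lens[sample.int(length(fit_lens), sum(unfit),
                                     replace = TRUE)]
  }
  drawn <- character(n_draw)
  for (L in unique(dl)) {
    idx <- which(dl == L)
    w <- pmax(0L, widths - L + 1L)
    iv <- sample.int(length(w), length(idx), replace = TRUE, prob = w)
    st <- background$start[iv] +
      floor(stats::runif(length(idx)) * w[iv])
    drawn[idx] <- substring(gvec[as.character(background$chrom[iv])],
                            st + 1, st + L)
  }
  null_draws <- split(drawn, rep(seq_len(n_perm), each = length(query)))
  # one batched search per target: sequence set 0 is the observed query set,
  # sets 1..n_perm are the permutation draws; the subject index is built
  # once and E-values are scaled per set so each set sees the same search
  # space it would in a standalone search
  sets <- c(list(unname(query)), null_draws)
  all_seqs <- unlist(sets, use.names = FALSE)
  set_of <- rep(seq_along(sets) - 1L, lengths(sets))
  set_m <- vapply(sets, function(s) sum(nchar(s)), 0)
  both <- c(all_seqs, revcomp(all_seqs))
  out <- lapply(target_genomes, function(target) {
    raw <- run_seeded_search(both, unname(target), "nucleotide",
                             search_space = 1)
    qset <- set_of[(raw$query - 1L) %% length(all_seqs) + 1L]
    qidx <- (raw$query - 1L) %% length(all_seqs) + 1L
    n_tot <- as.numeric(sum(nchar(target)))
    ev <- raw$evalue * set_m[qset + 1L] * n_tot
    sig_frac <- function(s) {
      keep <- qset == s & ev < evalue_cutoff
      length(unique(qidx[keep])) / length(sets[[s + 1L]])
    }
    obs <- sig_frac(0L)
    nulls <- vapply(seq_len(n_perm), sig_frac, 0)
    p_up <- (1 + sum(nulls >= obs)) / (n_perm + 1)
    p_lo <- (1 + sum(nulls <= obs)) / (n_perm + 1)
    list(observed_proportion = obs, null_proportions = nulls,
         empirical_p = min(1, 2 * min(p_up, p_lo)),
         p_upper = p_up, p_lower = p_lo)
  })
  out
}
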