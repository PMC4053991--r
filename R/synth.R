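#' Seeded synthetic-data generators
#'
#' Generators for every input the pipeline consumes -- genome, transcript
#' catalog, reference sets, small-RNA reads, expression matrices, epigenetic
#' tracks and a biparental RIL panel -- with ground truth attached, so every
#' downstream stage can be tested without external data. All generation is
#' a pure function of the configuration (fixed seed, byte-identical
#' reruns).
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults mirror the emulated study design: 13 tissues, 105 recombinant
#' inbred lines, lncRNA mean length near 463 nt with 81% single-exon loci
#' and about 3% longer than 1 kb, 54% of lncRNAs expressed in a single
#' tissue, and an intermated-population map expansion of 3x.
#'
#' @param seed integer master seed.
#' @param ... overrides of any default field.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chromosomes = 5L, chromosome_length_bp = 600000L,
    n_repeat_families = 8L, repeat_len_range = c(150L, 400L),
    repeat_copies_per_family = 6L,
    # catalog
    n_coding = 500L, n_hc_lncrna = 200L, n_pre_lncrna = 200L,
    n_housekeeping = 50L, n_hk_families = 10L,
    coding_orf_aa_range = c(120L, 300L), coding_exon_range = c(2L, 6L),
    coding_utr_range = c(50L, 150L), intron_len_range = c(60L, 200L),
    lnc_len_shape = 1.6, lnc_len_scale = 164, lnc_min_len = 200L,
    lnc_single_exon_prob = 0.81, lnc_extra_exon_max = 2L,
    pre_repeat_fraction = 0.74, hk_mutation_rate = 0.01,
    # small RNAs
    smallrna_per_precursor_mean = 3, smallrna_len_range = c(21L, 24L),
    n_background_smallrna = 100L,
    # expression
    n_tissues = 13L, library_size = 1e6,
    lnc_tissue_count_probs = c(0.54, 0.20, 0.12, 0.08, 0.06),
    coding_mean_count = 60, lnc_mean_count = 12, nb_dispersion = 5,
    # epigenetic tracks
    k27_silent = 0.8, k27_expressed = 0.1, k27_background = 0.3,
    meth_gene_body = 0.7, meth_lnc_body = 0.1, meth_background = 0.4,
    meth_chh = 0.05, track_noise_sd = 0.05,
    # RIL panel
    n_rils = 105L, n_markers = 150L, genetic_length_cM = 100,
    map_expansion = 3, n_traits_cis = 15L, n_traits_trans = 15L,
    n_traits_opposing = 10L, n_traits_null = 10L,
    eqtl_effect = 1, trait_noise_sd = 1, trait_baseline = 20,
    parent_noise_sd = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1L])
  utils::modifyList(cfg, over)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic genome and repeat library
#'
#' Chromosomes of i.i.d. background sequence with inserted copies of the
#' repeat families; the library is returned separately.
#'
#' @param config a [generator_config()].
#' @return list: `genome` (named chromosome sequences), `repeat_library`
#'   (named repeat consensus sequences), `repeat_positions` (data.frame of
#'   inserted copies).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  genome <- stats::setNames(
    vapply(seq_len(config$n_chromosomes), function(i)
      random_dna(config$chromosome_length_bp), ""),
    paste0("chr", seq_len(config$n_chromosomes)))
  lib <- character(0)
  pos <- list()
  if (config$n_repeat_families > 0L) {
    lib <- stats::setNames(
      vapply(seq_len(config$n_repeat_families), function(i)
        random_dna(sample(config$repeat_len_range[1L]:
                          config$repeat_len_range[2L], 1L)), ""),
      paste0("repfam", seq_len(config$n_repeat_families)))
    for (fam in names(lib)) {
      for (cp in seq_len(config$repeat_copies_per_family)) {
        ch <- sample(names(genome), 1L)
        w <- nchar(lib[[fam]])
        s <- sample.int(nchar(genome[[ch]]) - w, 1L)
        substr(genome[[ch]], s, s + w - 1L) <- lib[[fam]]
        pos[[length(pos) + 1L]] <- data.frame(
          family = fam, chrom = ch, start = s - 1L, end = s - 1L + w,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(genome = genome, repeat_library = lib,
       repeat_positions = if (length(pos)) do.call(rbind, pos)
                          else data.frame())
}

# fixed non-uniform codon usage giving coding sequences a hexamer signal
biased_codon_table <- function() {
  codons <- as.vector(outer(as.vector(outer(c("G", "C", "A", "T"),
                                            c("G", "C", "A", "T"), paste0)),
                            c("G", "C", "A", "T"), paste0))
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA", "ATG")]
  w <- ifelse(substr(codons, 3L, 3L) %in% c("G", "C"), 3, 1)
  stats::setNames(w / sum(w), codons)
}

make_coding_cds <- function(n_aa, codon_tab) {
  body <- sample(names(codon_tab), n_aa - 1L, replace = TRUE,
                 prob = codon_tab)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

make_intron <- function(len) paste0("GT", random_dna(len - 4L), "AG")

# draw an hc/pre-lncRNA spliced length
draw_lnc_length <- function(config) {
  config$lnc_min_len +
    round(stats::rgamma(1L, shape = config$lnc_len_shape,
                        scale = config$lnc_len_scale))
}

# sequence with no complete ORF > max_aa on either strand
draw_lnc_sequence <- function(len, max_aa = 100L, embed = NULL,
                              max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (!is.null(embed) && nchar(embed) + 20L < len) {
      at <- sample.int(len - nchar(embed), 1L)
      substr(s, at, at + nchar(embed) - 1L) <- embed
    }
    orfs <- find_orfs(s, strand = ".")
    cmpl <- orfs[orfs$complete, , drop = FALSE]
    if (nrow(cmpl) == 0L || max(cmpl$aa_length) <= max_aa) return(s)
  }
  stop("could not draw an ORF-free sequence of length ", len)
}

#' Generate the transcript catalog with ground-truth labels
#'
#' Coding transcripts carry a complete, codon-usage-biased ORF longer than
#' 100 aa whose translation enters the protein set; high-confidence lncRNAs
#' are >= 200 nt with no complete ORF over 100 aa on either strand;
#' precursor lncRNAs additionally receive small-RNA source segments (and a
#' configurable fraction embed repeat-family sequence); housekeeping
#' transcripts are lightly mutated copies of the housekeeping reference
#' entries. All intron boundaries read GT..AG on the coding strand. Loci
#' are written into the genome so spliced sequences match the reference.
#'
#' @param config a [generator_config()].
#' @param gen the result of [generate_genome()].
#' @return list: `annotation` ([annotation_set()]), `truth` (list with
#'   `locus_labels`), `proteins`, `housekeeping_db` (named character
#'   vectors), and `genome` (updated chromosome sequences).
#' @export
generate_transcripts <- function(config, gen) {
  set.seed(config$seed + 1L)
  genome <- gen$genome
  codon_tab <- biased_codon_table()
  cursors <- stats::setNames(rep(1000L, length(genome)), names(genome))
  txs <- list()
  labels <- character(0)
  proteins <- character(0)

  place_locus <- function(pieces, strand_known) {
    # pieces: list(exon= / intron=) character segments in transcript order
    glen <- sum(nchar(unlist(pieces)))
    ord <- sample(names(genome))
    ch <- NULL
    for (cand in ord) {
      if (cursors[[cand]] + glen + 2000L < nchar(genome[[cand]])) {
        ch <- cand; break
      }
    }
    if (is.null(ch))
      stop("chromosome_length too small to host the requested loci")
    start <- cursors[[ch]] + sample(200:2000, 1L)
    strand <- if (strand_known) sample(c("+", "-"), 1L) else "."
    locus_seq <- paste(unlist(pieces), collapse = "")
    if (strand == "-") locus_seq <- revcomp(locus_seq)
    substr(genome[[ch]], start + 1L, start + glen) <<- locus_seq
    cursors[[ch]] <<- start + glen
    # exon coordinates along the placed (genomic) orientation
    seg_len <- nchar(unlist(pieces))
    is_exon <- names(unlist(pieces)) |> startsWith("exon")
    if (strand == "-") { seg_len <- rev(seg_len); is_exon <- rev(is_exon) }
    ends <- cumsum(seg_len)
    starts <- ends - seg_len
    ex <- data.frame(start = start + starts[is_exon],
                     end = start + ends[is_exon])
    list(chrom = ch, exons = ex, strand = strand)
  }

  split_exons <- function(seq, n_exons) {
    if (n_exons == 1L) return(list(exon1 = seq))
    cuts <- sort(sample(seq(50L, nchar(seq) - 50L), n_exons - 1L))
    bounds <- c(0L, cuts, nchar(seq))
    out <- list()
    for (i in seq_len(n_exons)) {
      out[[paste0("exon", i)]] <- substr(seq, bounds[i] + 1L, bounds[i + 1L])
      if (i < n_exons)
        out[[paste0("intron", i)]] <-
          make_intron(sample(config$intron_len_range[1L]:
                             config$intron_len_range[2L], 1L))
    }
    out
  }

  add_tx <- function(id, seq, n_exons, strand_known, label, source) {
    pieces <- split_exons(seq, n_exons)
    loc <- place_locus(pieces, strand_known)
    tx_seq <- if (loc$strand == "-") seq else if (loc$strand == "+") seq
              else seq   # unknown strand: placed forward, reference orient.
    txs[[length(txs) + 1L]] <<- transcript_model(
      id, paste0("g_", id),
      genomic_intervals(loc$chrom, loc$exons$start, loc$exons$end,
                        loc$strand),
      loc$strand, sequence = tx_seq, source = source)
    labels[id] <<- label
  }

  # coding genes
  for (i in seq_len(config$n_coding)) {
    id <- sprintf("cod%04d", i)
    n_aa <- sample(config$coding_orf_aa_range[1L]:
                   config$coding_orf_aa_range[2L], 1L)
    cds <- make_coding_cds(n_aa, codon_tab)
    utr5 <- random_dna(sample(config$coding_utr_range[1L]:
                              config$coding_utr_range[2L], 1L))
    utr3 <- random_dna(sample(config$coding_utr_range[1L]:
                              config$coding_utr_range[2L], 1L))
    seq <- paste0(utr5, cds, utr3)
    n_ex <- sample(config$coding_exon_range[1L]:config$coding_exon_range[2L],
                   1L)
    add_tx(id, seq, n_ex, strand_known = TRUE, label = "coding",
           source = "annotation")
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1L, nchar(cds) - 3L)),
      if.fuzzy.codon = "X"))
    proteins[paste0("prot_", id)] <- pep
  }

  # housekeeping reference families and transcript copies
  hk_db <- stats::setNames(
    vapply(seq_len(config$n_hk_families), function(i)
      random_dna(sample(250:450, 1L)), ""),
    paste0("hkfam", seq_len(config$n_hk_families)))
  for (i in seq_len(config$n_housekeeping)) {
    id <- sprintf("hk%04d", i)
    fam <- sample(names(hk_db), 1L)
    seq <- mutate_seq(hk_db[[fam]], config$hk_mutation_rate)
    add_tx(id, seq, 1L, strand_known = FALSE, label = "housekeeping",
           source = "annotation")
  }

  lnc_exon_count <- function() {
    if (stats::runif(1L) < config$lnc_single_exon_prob) 1L
    else 1L + sample.int(config$lnc_extra_exon_max, 1L)
  }

  # high-confidence lncRNAs
  for (i in seq_len(config$n_hc_lncrna)) {
    id <- sprintf("hc%04d", i)
    seq <- draw_lnc_sequence(draw_lnc_length(config))
    add_tx(id, seq, lnc_exon_count(), strand_known = FALSE,
           label = "hc_lncrna", source = "assembly")
  }

  # small-RNA precursor lncRNAs (a fraction embed repeat sequence)
  for (i in seq_len(config$n_pre_lncrna)) {
    id <- sprintf("pre%04d", i)
    embed <- NULL
    if (length(gen$repeat_library) &&
        stats::runif(1L) < config$pre_repeat_fraction) {
      fam <- gen$repeat_library[[sample.int(length(gen$repeat_library), 1L)]]
      w <- min(nchar(fam), 150L)
      embed <- substr(fam, 1L, w)
    }
    len <- max(draw_lnc_length(config), 250L)
    seq <- draw_lnc_sequence(len, embed = embed)
    add_tx(id, seq, lnc_exon_count(), strand_known = FALSE,
           label = "pre_lncrna", source = "assembly")
  }

  list(annotation = annotation_set(txs),
       truth = list(locus_labels = labels),
       proteins = proteins, housekeeping_db = hk_db, genome = genome)
}

#' Generate small-RNA reads from precursor loci
#'
#' Reads of 21-24 nt are exact substrings of the precursor (pre-lncRNA)
#' transcripts -- every precursor yields at least one read -- plus
#' background reads sampled from intergenic space.
#'
#' @param config a [generator_config()].
#' @param annotation the generated [annotation_set()].
#' @param truth generated truth (with `locus_labels`).
#' @param genome the (updated) genome, for background reads.
#' @return named character vector of reads; names encode the source
#'   (`<precursor_id>_r<i>` or `bg<i>`).
#' @export
generate_small_rnas <- function(config, annotation, truth, genome = NULL) {
  set.seed(config$seed + 2L)
  pre_ids <- names(truth$locus_labels)[truth$locus_labels == "pre_lncrna"]
  reads <- character(0)
  for (id in pre_ids) {
    seq <- annotation$transcripts[[id]]$sequence
    n_reads <- 1L + stats::rpois(1L, config$smallrna_per_precursor_mean - 1)
    for (j in seq_len(n_reads)) {
      w <- sample(config$smallrna_len_range[1L]:
                  config$smallrna_len_range[2L], 1L)
      s <- sample.int(nchar(seq) - w + 1L, 1L)
      reads[paste0(id, "_r", j)] <- substr(seq, s, s + w - 1L)
    }
  }
  if (!is.null(genome) && config$n_background_smallrna > 0L) {
    for (j in seq_len(config$n_background_smallrna)) {
      ch <- sample(names(genome), 1L)
      w <- sample(config$smallrna_len_range[1L]:
                  config$smallrna_len_range[2L], 1L)
      # sample from the tail of the chromosome, beyond placed loci
      lo <- nchar(genome[[ch]]) - 50000L
      s <- lo + sample.int(50000L - w, 1L)
      reads[paste0("bg", j)] <- substr(genome[[ch]], s, s + w - 1L)
    }
  }
  reads
}
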