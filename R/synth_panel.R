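#' Generate tissue expression counts and epigenetic tracks
#'
#' Counts are negative-binomial. Coding and housekeeping transcripts are
#' expressed broadly at a higher mean; lncRNAs are expressed in a small
#' number of tissues (1 tissue with probability 0.54 by default) at a low
#' mean. Per-tissue H3K27me3 tracks are high over silent loci and low over
#' expressed ones; CG/CHG methylation is elevated over coding gene bodies
#' but not lncRNA bodies; CHH is uniformly low.
#'
#' @param config a [generator_config()].
#' @param annotation the generated [annotation_set()].
#' @param truth generated truth (with `locus_labels`).
#' @param genome_lengths named vector of chromosome lengths (for track
#'   background intervals).
#' @return list: `expression` (an [expression_matrix()], samples = tissues),
#'   `tissue_profile` (list of expressed-tissue sets per transcript),
#'   `k27_tracks` (list per tissue of track data.frames), `meth_tracks`
#'   (list per context `CG`, `CHG`, `CHH`).
#' @export
generate_expression <- function(config, annotation, truth, genome_lengths) {
  set.seed(config$seed + 3L)
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  ids <- names(annotation$transcripts)
  labels <- truth$locus_labels[ids]
  k_probs <- config$lnc_tissue_count_probs
  profile <- lapply(stats::setNames(ids, ids), function(id) {
    if (labels[[id]] %in% c("coding", "housekeeping")) tissues
    else {
      k <- sample.int(length(k_probs), 1L, prob = k_probs)
      sample(tissues, k)
    }
  })
  counts <- matrix(0L, length(ids), length(tissues),
                   dimnames = list(ids, tissues))
  for (i in seq_along(ids)) {
    mu <- if (labels[[ids[i]]] %in% c("coding", "housekeeping"))
      config$coding_mean_count else config$lnc_mean_count
    on <- tissues %in% profile[[ids[i]]]
    counts[i, on] <- stats::rnbinom(sum(on), mu = mu,
                                    size = config$nb_dispersion)
  }
  lens <- stats::setNames(
    vapply(annotation$transcripts, length, 0L), ids)
  libs <- stats::setNames(rep(config$library_size, length(tissues)), tissues)
  em <- expression_matrix(counts, lens, libs)

  spans <- lapply(annotation$transcripts, transcript_span)
  noise <- function(n, level) pmin(1, pmax(0,
    stats::rnorm(n, level, config$track_noise_sd)))
  background_rows <- function(value) do.call(rbind, lapply(
    names(genome_lengths), function(ch)
      data.frame(chrom = ch, start = 0L, end = genome_lengths[[ch]],
                 context = NA_character_, value = value,
                 stringsAsFactors = FALSE)))
  k27 <- lapply(stats::setNames(tissues, tissues), function(tt) {
    locus_rows <- do.call(rbind, lapply(ids, function(id) {
      sp <- spans[[id]]
      expressed <- tt %in% profile[[id]]
      lvl <- if (expressed) config$k27_expressed else config$k27_silent
      data.frame(chrom = sp$chrom, start = sp$start, end = sp$end,
                 context = "H3K27me3", value = noise(1L, lvl),
                 stringsAsFactors = FALSE)
    }))
    bg <- background_rows(config$k27_background)
    bg$context <- "H3K27me3"
    rbind(bg, locus_rows)   # locus rows later: they override the background
  })
  meth <- lapply(stats::setNames(c("CG", "CHG", "CHH"),
                                 c("CG", "CHG", "CHH")), function(ctx) {
    if (ctx == "CHH") {
      bg <- background_rows(config$meth_chh); bg$context <- ctx
      return(bg)
    }
    locus_rows <- do.call(rbind, lapply(ids, function(id) {
      sp <- spans[[id]]
      lvl <- if (labels[[id]] == "coding") config$meth_gene_body
             else config$meth_lnc_body
      data.frame(chrom = sp$chrom, start = sp$start, end = sp$end,
                 context = ctx, value = noise(1L, lvl),
                 stringsAsFactors = FALSE)
    }))
    bg <- background_rows(config$meth_background)
    bg$context <- ctx
    rbind(bg, locus_rows)
  })
  list(expression = em, tissue_profile = profile, k27_tracks = k27,
       meth_tracks = meth)
}

#' Generate a biparental RIL panel with planted eQTL
#'
#' Markers are placed evenly along each chromosome with both cM and bp
#' coordinates (base genetic length times a map-expansion factor for
#' intermated lines). Genotypes follow a two-state Markov walk with
#' Haldane recombination fractions. Expression traits are sums of planted
#' cis/trans marker effects plus Gaussian noise; parental expression is the
#' genotype-appropriate effect sum without segregation. Traits with two
#' opposing trans effects produce transgressive segregation.
#'
#' @param config a [generator_config()].
#' @param annotation optional [annotation_set()]; when given, traits borrow
#'   the genomic midpoints of its high-confidence lncRNA loci so cis
#'   relationships are meaningful.
#' @param truth optional truth list (with `locus_labels`).
#' @return list: `panel` (a [ril_panel()]), `planted_eqtl` (data.frame
#'   `trait_id`, `chrom`, `position_cM`, `additive_effect`, `cis_flag`),
#'   `trait_positions` (data.frame `trait_id`, `chrom`, `midpoint_bp`),
#'   `trait_kind` (named vector: cis/trans/opposing/null).
#' @export
generate_ril_panel <- function(config, annotation = NULL, truth = NULL) {
  set.seed(config$seed + 4L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  per_chrom <- ceiling(config$n_markers / config$n_chromosomes)
  total_cM <- config$genetic_length_cM * config$map_expansion
  map <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    cm <- seq(0, total_cM, length.out = per_chrom)
    data.frame(marker_id = sprintf("m_%s_%03d", chroms[ci],
                                   seq_len(per_chrom)),
               chrom = chroms[ci], position_cM = cm,
               position_bp = round(cm / total_cM *
                                   (config$chromosome_length_bp - 1L)),
               stringsAsFactors = FALSE)
  }))
  map <- genetic_map(map$marker_id, map$chrom, map$position_cM,
                     map$position_bp)
  lines <- sprintf("RIL%03d", seq_len(config$n_rils))
  G <- matrix(NA_character_, config$n_rils, nrow(map),
              dimnames = list(lines, map$marker_id))
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    d <- diff(map$position_cM[idx])
    r <- haldane_r(d)
    for (li in seq_len(config$n_rils)) {
      g <- character(length(idx))
      g[1L] <- sample(c("A", "B"), 1L)
      for (j in seq_along(d))
        g[j + 1L] <- if (stats::runif(1L) < r[j])
          setdiff(c("A", "B"), g[j]) else g[j]
      G[li, idx] <- g
    }
  }

  n_traits <- config$n_traits_cis + config$n_traits_trans +
    config$n_traits_opposing + config$n_traits_null
  kinds <- rep(c("cis", "trans", "opposing", "null"),
               c(config$n_traits_cis, config$n_traits_trans,
                 config$n_traits_opposing, config$n_traits_null))
  trait_ids <- sprintf("trait%03d", seq_len(n_traits))
  # trait genomic positions: borrow hc-lncRNA midpoints when available
  hc_ids <- if (!is.null(truth))
    names(truth$locus_labels)[truth$locus_labels == "hc_lncrna"] else character()
  positions <- do.call(rbind, lapply(seq_len(n_traits), function(i) {
    if (length(hc_ids) >= i && !is.null(annotation)) {
      sp <- transcript_span(annotation$transcripts[[hc_ids[i]]])
      data.frame(trait_id = trait_ids[i], chrom = sp$chrom,
                 midpoint_bp = floor((sp$start + sp$end) / 2),
                 source_transcript = hc_ids[i], stringsAsFactors = FALSE)
    } else data.frame(trait_id = trait_ids[i],
                      chrom = sample(chroms, 1L),
                      midpoint_bp = sample.int(config$chromosome_length_bp,
                                               1L),
                      source_transcript = NA_character_,
                      stringsAsFactors = FALSE)
  }))

  Gnum <- matrix(ifelse(G == "B", 1, -1), nrow(G), ncol(G),
                 dimnames = dimnames(G))
  nearest_marker <- function(chrom, bp) {
    mk <- map[map$chrom == chrom, ]
    mk[which.min(abs(mk$position_bp - bp)), ]
  }
  planted <- list()
  expr <- matrix(NA_real_, n_traits, config$n_rils,
                 dimnames = list(trait_ids, lines))
  pA <- stats::setNames(numeric(n_traits), trait_ids)
  pB <- stats::setNames(numeric(n_traits), trait_ids)
  for (i in seq_len(n_traits)) {
    eff <- list()
    a <- config$eqtl_effect
    if (kinds[i] == "cis") {
      mk <- nearest_marker(positions$chrom[i], positions$midpoint_bp[i])
      eff[[1L]] <- list(mk = mk, a = a, cis = TRUE)
    } else if (kinds[i] == "trans") {
      mk <- map[sample(which(map$chrom != positions$chrom[i]), 1L), ]
      eff[[1L]] <- list(mk = mk, a = a, cis = FALSE)
    } else if (kinds[i] == "opposing") {
      other <- which(map$chrom != positions$chrom[i])
      pick <- sample(other, 2L)
      eff[[1L]] <- list(mk = map[pick[1L], ], a = a, cis = FALSE)
      eff[[2L]] <- list(mk = map[pick[2L], ], a = -a, cis = FALSE)
    }
    y <- rep(config$trait_baseline, config$n_rils)
    a_sum_A <- 0; a_sum_B <- 0
    for (e in eff) {
      y <- y + e$a * Gnum[, e$mk$marker_id]
      a_sum_A <- a_sum_A - e$a
      a_sum_B <- a_sum_B + e$a
      planted[[length(planted) + 1L]] <- data.frame(
        trait_id = trait_ids[i], chrom = e$mk$chrom,
        position_cM = e$mk$position_cM, additive_effect = e$a,
        cis_flag = e$cis, stringsAsFactors = FALSE)
    }
    expr[i, ] <- y + stats::rnorm(config$n_rils, 0, config$trait_noise_sd)
    pA[i] <- config$trait_baseline + a_sum_A +
      stats::rnorm(1L, 0, config$parent_noise_sd)
    pB[i] <- config$trait_baseline + a_sum_B +
      stats::rnorm(1L, 0, config$parent_noise_sd)
  }
  counts <- round(pmax(expr, 0))
  panel <- ril_panel(map, G, expr, pA, pB, counts = counts)
  list(panel = panel,
       planted_eqtl = if (length(planted)) do.call(rbind, planted)
                      else data.frame(),
       trait_positions = positions,
       trait_kind = stats::setNames(kinds, trait_ids))
}

#' Run every generator and optionally write the pipeline's input files
#'
#' @param config a [generator_config()].
#' @param outdir optional directory; when given, writes genome and
#'   reference FASTAs, the catalog GTF, small-RNA FASTA, expression and
#'   track TSVs, and map/genotype/expression/parent TSVs for the RIL panel.
#' @return list with all generator outputs (`genome`, `repeat_library`,
#'   `annotation`, `truth`, `proteins`, `housekeeping_db`, `small_rnas`,
#'   `expression`, `ril`).
#' @export
generate_all <- function(config = generator_config(), outdir = NULL) {
  gen <- generate_genome(config)
  tx <- generate_transcripts(config, gen)
  small <- generate_small_rnas(config, tx$annotation, tx$truth, tx$genome)
  glens <- stats::setNames(nchar(tx$genome), names(tx$genome))
  ex <- generate_expression(config, tx$annotation, tx$truth, glens)
  ril <- generate_ril_panel(config, tx$annotation, tx$truth)
  out <- list(genome = tx$genome, repeat_library = gen$repeat_library,
              annotation = tx$annotation,
              truth = c(tx$truth, list(tissue_profile = ex$tissue_profile,
                                       planted_eqtl = ril$planted_eqtl)),
              proteins = tx$proteins, housekeeping_db = tx$housekeeping_db,
              small_rnas = small, expression = ex, ril = ril)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(outdir, "genome.fa"))
    write_fasta(out$repeat_library, file.path(outdir, "repeats.fa"))
    write_fasta(out$proteins, file.path(outdir, "proteins.fa"))
    write_fasta(out$housekeeping_db, file.path(outdir, "housekeeping.fa"))
    write_fasta(out$small_rnas, file.path(outdir, "small_rnas.fa"))
    write_gtf(out$annotation, file.path(outdir, "catalog.gtf"))
    utils::write.table(
      data.frame(transcript_id = rownames(ex$expression$counts),
                 ex$expression$counts, check.names = FALSE),
      file.path(outdir, "counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(ril$panel$map, file.path(outdir, "map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(line = rownames(ril$panel$genotypes), ril$panel$genotypes,
                 check.names = FALSE),
      file.path(outdir, "genotypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(trait_id = rownames(ril$panel$expression),
                 ril$panel$expression, check.names = FALSE),
      file.path(outdir, "ril_expression.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  out
}
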