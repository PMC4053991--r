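small_cfg <- function(seed = 11, ...) {
  generator_config(seed = seed, n_chromosomes = 2L,
                   chromosome_length_bp = 200000L,
                   n_coding = 15L, n_hc_lncrna = 10L, n_pre_lncrna = 10L,
                   n_housekeeping = 5L, n_repeat_families = 3L,
                   n_markers = 20L, n_background_smallrna = 10L, ...)
}

test_that("generator defaults encode the emulated study design", {
  cfg <- generator_config()
  expect_equal(cfg$n_tissues, 13L)
  expect_equal(cfg$n_rils, 105L)
  expect_equal(cfg$lnc_single_exon_prob, 0.81)
  expect_equal(cfg$map_expansion, 3)
  expect_equal(cfg$lnc_tissue_count_probs[1], 0.54)
  # gamma length model: min + shape*scale ~ 463 nt mean spliced length
  expect_equal(cfg$lnc_min_len + cfg$lnc_len_shape * cfg$lnc_len_scale,
               462.4, tolerance = 0.01)
  expect_equal(cfg$n_coding, 500L)
  expect_equal(cfg$n_hc_lncrna, 200L)
  expect_error(generator_config(no_such_field = 1), "unknown config field")
})

test_that("generation is a pure function of the configuration", {
  cfg <- small_cfg()
  a <- generate_all(cfg)
  b <- generate_all(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$locus_labels, b$truth$locus_labels)
  expect_identical(a$small_rnas, b$small_rnas)
  expect_identical(a$expression$expression$counts,
                   b$expression$expression$counts)
  expect_identical(a$ril$panel$genotypes, b$ril$panel$genotypes)
  expect_identical(a$ril$panel$expression, b$ril$panel$expression)
  # a different seed changes the genome
  c2 <- generate_all(small_cfg(seed = 12))
  expect_false(identical(a$genome, c2$genome))
})

test_that("genome carries the repeat library at the recorded positions", {
  gen <- generate_genome(small_cfg())
  expect_named(gen$genome, c("chr1", "chr2"))
  expect_equal(unname(nchar(gen$genome)), rep(200000L, 2))
  # a later insertion may overwrite an earlier copy; check intact copies
  rp <- gen$repeat_positions
  checked <- 0L
  for (i in seq_len(nrow(rp))) {
    p <- rp[i, ]
    later <- rp[-seq_len(i), , drop = FALSE]
    clobbered <- any(later$chrom == p$chrom &
                       later$start < p$end & later$end > p$start)
    if (clobbered) next
    expect_identical(
      substr(gen$genome[[p$chrom]], p$start + 1L, p$end),
      unname(gen$repeat_library[[p$family]]))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("truth labels match the generated sequence properties", {
  cfg <- small_cfg()
  gen <- generate_genome(cfg)
  tx <- generate_transcripts(cfg, gen)
  lab <- tx$truth$locus_labels
  expect_equal(sum(lab == "coding"), cfg$n_coding)
  expect_equal(sum(lab == "hc_lncrna"), cfg$n_hc_lncrna)
  expect_equal(sum(lab == "pre_lncrna"), cfg$n_pre_lncrna)
  expect_equal(sum(lab == "housekeeping"), cfg$n_housekeeping)
  for (id in names(lab)) {
    t1 <- tx$annotation$transcripts[[id]]
    lco <- longest_complete_orf(t1$sequence, strand = ".")
    if (lab[[id]] == "coding") {
      expect_gt(lco, 100L)
      expect_gte(nchar(t1$sequence), 200L)
    } else if (lab[[id]] %in% c("hc_lncrna", "pre_lncrna")) {
      expect_lte(lco, 100L)
      expect_gte(nchar(t1$sequence), 200L)
    }
  }
  # one protein per coding gene, translated from its ORF
  expect_length(tx$proteins, cfg$n_coding)
  expect_true(all(nchar(tx$proteins) >= cfg$coding_orf_aa_range[1] - 1))
})

test_that("placed loci reproduce their spliced sequence from the genome", {
  cfg <- small_cfg(seed = 13)
  tx <- generate_transcripts(cfg, generate_genome(cfg))
  ids <- names(tx$truth$locus_labels)
  for (id in sample(ids, 12)) {
    t1 <- tx$annotation$transcripts[[id]]
    got <- lncherit:::spliced_sequence(
      t1$exons[order(t1$exons$start), , drop = FALSE], t1$strand, tx$genome)
    expect_identical(got, t1$sequence)
  }
  # multi-exon loci have GT..AG introns on the coding strand
  multi <- Filter(function(t) nrow(t$exons) > 1L, tx$annotation$transcripts)
  expect_gt(length(multi), 0L)
  t2 <- multi[[1L]]
  intr <- transcript_introns(t2)
  iseq <- substr(tx$genome[[t2$exons$chrom[1]]],
                 intr$start[1] + 1L, intr$end[1])
  if (t2$strand == "-") iseq <- lncherit:::revcomp(iseq)
  if (t2$strand != ".") {
    expect_identical(substr(iseq, 1L, 2L), "GT")
    expect_identical(substr(iseq, nchar(iseq) - 1L, nchar(iseq)), "AG")
  } else {
    ok_fwd <- startsWith(iseq, "GT") && endsWith(iseq, "AG")
    rc <- lncherit:::revcomp(iseq)
    ok_rev <- startsWith(rc, "GT") && endsWith(rc, "AG")
    expect_true(ok_fwd || ok_rev)
  }
})

test_that("small-RNA reads are exact substrings of their precursor", {
  cfg <- small_cfg()
  gen <- generate_genome(cfg)
  tx <- generate_transcripts(cfg, gen)
  reads <- generate_small_rnas(cfg, tx$annotation, tx$truth, tx$genome)
  pre_ids <- names(tx$truth$locus_labels)[
    tx$truth$locus_labels == "pre_lncrna"]
  src <- sub("_r\\d+$", "", names(reads))
  # every precursor yields at least one read
  expect_true(all(pre_ids %in% src))
  for (nm in names(reads)[src %in% pre_ids]) {
    expect_true(grepl(reads[[nm]],
                      tx$annotation$transcripts[[sub("_r\\d+$", "", nm)]]$sequence,
                      fixed = TRUE))
    expect_true(nchar(reads[[nm]]) >= 21L && nchar(reads[[nm]]) <= 24L)
  }
  # background reads exist and are named bg<i>
  expect_equal(sum(grepl("^bg", names(reads))), cfg$n_background_smallrna)
})

test_that("expression respects the planted tissue profiles", {
  cfg <- small_cfg()
  gen <- generate_genome(cfg)
  tx <- generate_transcripts(cfg, gen)
  glens <- stats::setNames(nchar(tx$genome), names(tx$genome))
  ex <- generate_expression(cfg, tx$annotation, tx$truth, glens)
  cm <- ex$expression$counts
  expect_equal(ncol(cm), 13L)
  expect_setequal(rownames(cm), names(tx$truth$locus_labels))
  lab <- tx$truth$locus_labels
  # coding/housekeeping are "on" in every tissue
  for (id in names(lab)[lab %in% c("coding", "housekeeping")])
    expect_setequal(ex$tissue_profile[[id]], colnames(cm))
  # lncRNA counts vanish outside the planted profile
  lnc <- names(lab)[lab %in% c("hc_lncrna", "pre_lncrna")]
  for (id in lnc) {
    off <- setdiff(colnames(cm), ex$tissue_profile[[id]])
    expect_true(all(cm[id, off] == 0L))
  }
  # per-tissue K27 and three-context methylation tracks come along
  expect_length(ex$k27_tracks, 13L)
  expect_named(ex$meth_tracks, c("CG", "CHG", "CHH"))
})

test_that("RIL panel honors map expansion and plants coherent eQTL", {
  cfg <- small_cfg(n_rils = 40L,
                   n_traits_cis = 4L, n_traits_trans = 4L,
                   n_traits_opposing = 2L, n_traits_null = 2L)
  ril <- generate_ril_panel(cfg)
  expect_s3_class(ril$panel, "ril_panel")
  expect_equal(nrow(ril$panel$genotypes), 40L)
  expect_true(all(ril$panel$genotypes %in% c("A", "B")))
  expect_equal(max(ril$panel$map$position_cM),
               cfg$genetic_length_cM * cfg$map_expansion)
  # planted table: cis effects sit on the trait's own chromosome,
  # trans effects on another, null traits are absent
  pk <- merge(ril$planted_eqtl, ril$trait_positions, by = "trait_id")
  expect_true(all(pk$chrom.x[pk$cis_flag] == pk$chrom.y[pk$cis_flag]))
  expect_true(all(pk$chrom.x[!pk$cis_flag] != pk$chrom.y[!pk$cis_flag]))
  null_ids <- names(ril$trait_kind)[ril$trait_kind == "null"]
  expect_false(any(ril$planted_eqtl$trait_id %in% null_ids))
  # opposing traits carry two effects of opposite sign
  opp <- names(ril$trait_kind)[ril$trait_kind == "opposing"][1]
  eff <- ril$planted_eqtl$additive_effect[ril$planted_eqtl$trait_id == opp]
  expect_equal(sort(eff), c(-cfg$eqtl_effect, cfg$eqtl_effect))
  # parents sit at baseline +/- summed effect (no segregation, no noise)
  cis1 <- names(ril$trait_kind)[ril$trait_kind == "cis"][1]
  expect_equal(unname(ril$panel$parentB_expression[cis1]),
               cfg$trait_baseline + cfg$eqtl_effect)
  expect_equal(unname(ril$panel$parentA_expression[cis1]),
               cfg$trait_baseline - cfg$eqtl_effect)
})
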