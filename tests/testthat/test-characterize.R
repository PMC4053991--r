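test_that("GT-AG orientation inference recovers the coded strand", {
  set.seed(41)
  exon1 <- random_nt(80); exon2 <- random_nt(70)
  intron <- lncherit:::make_intron(60L)
  chrom <- paste0(random_nt(100), exon1, intron, exon2, random_nt(100))
  genome <- list(chrA = chrom)
  ex <- genomic_intervals("chrA", c(100L, 240L), c(180L, 310L))
  tx_plus <- transcript_model("t", "g", ex, strand = ".")
  expect_identical(infer_orientation_gt_ag(tx_plus, genome), "+")

  # the same structure on the reverse-complemented chromosome reads minus
  genome_rc <- list(chrA = lncherit:::revcomp(chrom))
  n <- nchar(chrom)
  ex_rc <- genomic_intervals("chrA", c(n - 310L, n - 180L),
                             c(n - 240L, n - 100L))
  tx_minus <- transcript_model("t", "g", ex_rc, strand = ".")
  expect_identical(infer_orientation_gt_ag(tx_minus, genome_rc), "-")

  # no GT..AG either way -> unknown
  genome_bad <- list(chrA = paste(rep("A", n), collapse = ""))
  expect_identical(infer_orientation_gt_ag(tx_plus, genome_bad), ".")
})

test_that("anatomy classification partitions by gene proximity", {
  genes <- annotation_set(list(
    make_toy_tx("gene1", "G1", starts = 10000L, ends = 15000L, strand = "+")))
  lnc <- annotation_set(list(
    make_toy_tx("inside", "L1", starts = 12000L, ends = 12400L),
    make_toy_tx("up", "L2", starts = 6000L, ends = 6400L),
    make_toy_tx("down", "L3", starts = 16000L, ends = 16400L),
    make_toy_tx("far", "L4", starts = 40000L, ends = 40400L)))
  res <- classify_anatomy(lnc, genes)
  cat_of <- setNames(res$category, res$transcript_id)
  expect_identical(unname(cat_of["inside"]), "genic_overlap")
  expect_identical(unname(cat_of["up"]), "upstream_within_5kb")
  expect_identical(unname(cat_of["down"]), "downstream_within_5kb")
  expect_identical(unname(cat_of["far"]), "distal_intergenic")
  # distances measured between closest span edges
  expect_equal(res$distance_bp[res$transcript_id == "up"], 10000 - 6400)
  # upstream/downstream flip with the gene strand
  genes_minus <- annotation_set(list(
    make_toy_tx("gene1", "G1", starts = 10000L, ends = 15000L,
                strand = "-")))
  res2 <- classify_anatomy(lnc, genes_minus)
  expect_identical(res2$category[res2$transcript_id == "up"], "downstream_within_5kb")
  expect_identical(res2$category[res2$transcript_id == "down"], "upstream_within_5kb")
  # every transcript gets exactly one category
  expect_setequal(res$transcript_id, names(lnc$transcripts))
})

test_that("two-proportion z-test matches prop.test without correction", {
  res <- proximity_proportion_test(30L, 100L, 50L, 120L)
  ref <- prop.test(c(30, 50), c(100, 120), correct = FALSE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$z^2, unname(ref$statistic))
})

test_that("bin densities count every transcript exactly once", {
  ann <- annotation_set(list(
    make_toy_tx("a", "g1", starts = 100L, ends = 500L),
    make_toy_tx("b", "g2", starts = 1500L, ends = 1900L),
    make_toy_tx("c", "g3", chrom = "chrY", starts = 100L, ends = 300L)))
  dens <- bin_density(ann, bin_size_bp = 1000)
  expect_equal(sum(dens$count), 3L)
  expect_equal(dens$count[dens$chrom == "chrZ" & dens$bin == 0L], 1L)
  expect_equal(dens$count[dens$chrom == "chrZ" & dens$bin == 1L], 1L)
  # empty bins materialize when chromosome lengths are known
  dens2 <- bin_density(ann, bin_size_bp = 1000,
                       chrom_lengths = c(chrZ = 4000, chrY = 1000))
  expect_equal(sum(dens2$chrom == "chrZ"), 4L)
  expect_equal(sum(dens2$count), 3L)
})

test_that("structure stats report the single-exon fraction", {
  ann <- annotation_set(list(
    make_toy_tx("a", "g1", starts = 100L, ends = 500L),
    make_toy_tx("b", "g2", starts = c(1000L, 1600L), ends = c(1400L, 1800L)),
    make_toy_tx("c", "g3", starts = 3000L, ends = 3500L)))
  st <- structure_stats(ann)
  expect_equal(st$single_exon_fraction, 2 / 3)
  expect_equal(unname(st$lengths[c("a", "b", "c")]), c(400L, 600L, 500L))
  expect_equal(st$mean_length, 500)
  expect_equal(st$median_length, 500)
  expect_equal(sum(st$exon_count_hist), 3L)
})

test_that("background sampling respects interval bounds and weights", {
  set.seed(43)
  iv <- data.frame(chrom = c("c1", "c2"), start = c(0L, 1000L),
                   end = c(100L, 1100L))
  for (i in 1:50) {
    reg <- lncherit:::sample_background_region(40L, iv)
    expect_true(reg$end - reg$start == 40L)
    row <- iv[iv$chrom == reg$chrom, ]
    expect_gte(reg$start, row$start)
    expect_lte(reg$end, row$end)
  }
  # a length that fits nowhere yields NULL
  expect_null(lncherit:::sample_background_region(500L, iv))
})

test_that("conservation test: self-alignment and extreme-p formulas", {
  set.seed(44)
  genome <- list(chr1 = random_nt(20000))
  bg <- data.frame(chrom = "chr1", start = 0L, end = 20000L)
  # queries copied verbatim from the target -> observed proportion 1,
  # nothing in the random background aligns -> p_upper = 1/(n_perm+1)
  target <- list(sp = c(t1 = random_nt(5000)))
  qs <- setNames(sapply(0:4, function(i)
    substr(target$sp[[1]], i * 900 + 1, i * 900 + 150)), paste0("q", 0:4))
  res <- conservation_permutation_test(qs, target, bg, genome, n_perm = 19)
  expect_equal(res$sp$observed_proportion, 1)
  expect_true(all(res$sp$null_proportions == 0))
  expect_equal(res$sp$p_upper, 1 / 20)
  expect_equal(res$sp$p_lower, 1)
  expect_equal(res$sp$empirical_p, 2 / 20)
  expect_length(res$sp$null_proportions, 19L)
})

test_that("conservation test requires adequate background coverage", {
  genome <- list(chr1 = "ACGTACGTAC")
  bg <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  qs <- c(q1 = "ACGTACGTACGTACGTACGT")
  expect_error(conservation_permutation_test(qs, list(sp = c(t = "ACGT")),
                                             bg, genome, n_perm = 19),
               "background")
})
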