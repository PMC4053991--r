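# small catalog with one transcript of each truth class, shared across tests
make_small_catalog <- function(seed = 31) {
  cfg <- generator_config(seed = seed, n_coding = 12, n_hc_lncrna = 8,
                          n_pre_lncrna = 8, n_housekeeping = 5,
                          n_chromosomes = 2L)
  generate_all(cfg)
}

catalog_env <- new.env()
small_catalog <- function() {
  if (is.null(catalog_env$dat)) catalog_env$dat <- make_small_catalog()
  catalog_env$dat
}

train_small_model <- function() {
  if (is.null(catalog_env$model)) {
    sets <- local({
      set.seed(321)
      tab <- lncherit:::biased_codon_table()
      coding <- replicate(60, paste0(
        random_nt(40), lncherit:::make_coding_cds(sample(110:200, 1), tab),
        random_nt(40)))
      noncoding <- replicate(60,
        lncherit:::draw_lnc_sequence(sample(250:600, 1)))
      list(coding = coding, noncoding = noncoding)
    })
    catalog_env$model <- train_coding_model(sets$coding, sets$noncoding)
  }
  catalog_env$model
}

test_that("catalog merging keeps structures seen in >= 2 experiments", {
  ref <- annotation_set(list(
    make_toy_tx("ann1", "g1", starts = c(100L, 300L), ends = c(200L, 380L))))
  novel2 <- function(id) make_toy_tx(id, paste0("g_", id),
                                     starts = c(1000L, 1300L),
                                     ends = c(1150L, 1400L))
  once <- make_toy_tx("once", "g_once", starts = 2000L, ends = 2400L)
  exp1 <- annotation_set(list(novel2("a1"), once))
  exp2 <- annotation_set(list(novel2("a2")))
  merged <- merge_transcript_catalogs(list(exp1, exp2), ref)
  ids <- names(merged$transcripts)
  expect_true("ann1" %in% ids)
  # the reproducible structure is retained exactly once, the singleton not
  novel <- setdiff(ids, "ann1")
  expect_length(novel, 1L)
  expect_equal(merged$transcripts[[novel]]$exons$start, c(1000L, 1300L))
})

test_that("single-exon merging uses reciprocal overlap", {
  ref <- annotation_set(list(make_toy_tx("ann1", "g1", starts = 100L,
                                         ends = 500L)))
  # 95% reciprocal overlap with the annotation: matches, not novel
  close1 <- make_toy_tx("c1", "gc1", starts = 110L, ends = 510L)
  close2 <- make_toy_tx("c2", "gc2", starts = 112L, ends = 512L)
  merged <- merge_transcript_catalogs(
    list(annotation_set(list(close1)), annotation_set(list(close2))), ref)
  expect_identical(names(merged$transcripts), "ann1")
})

test_that("catalog merging rejects foreign chromosome namespaces", {
  ref <- annotation_set(list(make_toy_tx("ann1", "g1")))
  alien <- annotation_set(list(make_toy_tx("a", "ga", chrom = "scaffold_9")))
  expect_error(merge_transcript_catalogs(list(alien, alien), ref),
               "chromosome")
})

test_that("housekeeping filter excludes near-identical copies only", {
  set.seed(33)
  db <- c(rRNA_1 = random_nt(600))
  hk_copy <- lncherit:::mutate_seq(db[[1]], 0.02)
  unrelated <- lncherit:::draw_lnc_sequence(400)
  cand <- annotation_set(list(
    make_toy_tx("hk", "g1", starts = 0L, ends = nchar(hk_copy), strand = ".",
                sequence = hk_copy),
    make_toy_tx("lnc", "g2", starts = 1000L, ends = 1400L, strand = ".",
                sequence = unrelated)))
  res <- housekeeping_filter(cand, db)
  expect_identical(names(res$kept$transcripts), "lnc")
  expect_identical(res$excluded$transcript_id, "hk")
})

test_that("small-RNA split requires an exact full-length read match", {
  set.seed(34)
  precursor <- lncherit:::draw_lnc_sequence(300)
  other <- lncherit:::draw_lnc_sequence(300)
  read <- substr(precursor, 100, 121)          # exact 22-mer
  cand <- annotation_set(list(
    make_toy_tx("pre", "g1", starts = 0L, ends = 300L, strand = ".",
                sequence = precursor),
    make_toy_tx("hc", "g2", starts = 1000L, ends = 1300L, strand = ".",
                sequence = other)))
  res <- split_by_small_rna(cand, c(r1 = read))
  expect_identical(names(res$pre_lncrna$transcripts), "pre")
  expect_identical(names(res$hc_lncrna$transcripts), "hc")
  # a read matching on the opposite strand also counts
  res_rc <- split_by_small_rna(cand, c(r1 = lncherit:::revcomp(read)))
  expect_identical(names(res_rc$pre_lncrna$transcripts), "pre")
  # reads outside 18-30 nt are skipped with a warning
  expect_warning(split_by_small_rna(cand, c(bad = substr(precursor, 1, 10))),
                 "18")
})

test_that("repeat annotation flags transcripts above coverage threshold", {
  set.seed(35)
  rep_seq <- random_nt(200)
  carrier <- paste0(rep_seq, random_nt(100))          # 2/3 repeat
  clean <- lncherit:::draw_lnc_sequence(300)
  res <- annotate_repeats(c(carrier = carrier, clean = clean),
                          repeat_library = rep_seq)
  expect_true(res$repeat_associated[res$transcript_id == "carrier"])
  expect_false(res$repeat_associated[res$transcript_id == "clean"])
  expect_gte(res$repeat_fraction[res$transcript_id == "carrier"], 0.5)
})

test_that("classifier output is a partition with stage-ordered labels", {
  dat <- small_catalog()
  res <- classify_pipeline(
    dat$annotation,
    list(proteins = dat$proteins, housekeeping = dat$housekeeping_db,
         repeats = dat$repeat_library, coding_model = train_small_model()),
    dat$small_rnas)
  recs <- res$records
  # exactly one record per input transcript, in input order
  expect_identical(recs$transcript_id, names(dat$annotation$transcripts))
  labels <- c("too_short", "long_orf", "protein_similar", "coding_potential",
              "housekeeping", "pre_lncrna", "hc_lncrna")
  expect_true(all(recs$label %in% labels))
  # summary counts the partition
  expect_equal(sum(res$summary$count), nrow(recs))
  expect_equal(unname(res$summary$count[res$summary$label == "hc_lncrna"]),
               sum(recs$label == "hc_lncrna"))
  # hc/pre annotation sets agree with the records
  expect_setequal(names(res$hc_lncrna$transcripts),
                  recs$transcript_id[recs$label == "hc_lncrna"])
  expect_setequal(names(res$pre_lncrna$transcripts),
                  recs$transcript_id[recs$label == "pre_lncrna"])
})

test_that("classifier recovers generator truth on a small catalog", {
  dat <- small_catalog()
  res <- classify_pipeline(
    dat$annotation,
    list(proteins = dat$proteins, housekeeping = dat$housekeeping_db,
         repeats = dat$repeat_library, coding_model = train_small_model()),
    dat$small_rnas)
  lab <- dat$truth$locus_labels
  pred <- setNames(res$records$label, res$records$transcript_id)[names(lab)]
  codingish <- c("long_orf", "protein_similar", "coding_potential")
  ok <- ifelse(lab == "coding", pred %in% codingish, pred == lab)
  expect_gte(mean(ok), 0.85)
})

test_that("classifier writes its output files when asked", {
  dat <- small_catalog()
  out <- withr::local_tempdir()
  classify_pipeline(
    dat$annotation,
    list(proteins = dat$proteins, housekeeping = dat$housekeeping_db,
         repeats = dat$repeat_library, coding_model = train_small_model()),
    dat$small_rnas, out_dir = out)
  expect_true(file.exists(file.path(out, "records.tsv")))
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "hc_lncrna.gtf")))
  back <- read_table_schema(file.path(out, "records.tsv"),
                            c(transcript_id = "character",
                              label = "character"))
  expect_equal(nrow(back), length(dat$annotation$transcripts))
})
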