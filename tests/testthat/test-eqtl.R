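# deterministic toy panel: 1 chromosome, evenly spaced markers, one planted
# additive QTL
make_toy_panel <- function(n_lines = 80, n_markers = 11, qtl_marker = 6,
                           effect = 1.5, noise_sd = 1, seed = 61) {
  set.seed(seed)
  map <- genetic_map(paste0("m", seq_len(n_markers)), "chr1",
                     seq(0, 100, length.out = n_markers),
                     seq(0, 2e6, length.out = n_markers))
  geno <- matrix("A", n_lines, n_markers,
                 dimnames = list(paste0("L", seq_len(n_lines)),
                                 map$marker_id))
  for (i in seq_len(n_lines)) {
    g <- sample(c("A", "B"), 1)
    for (j in seq_len(n_markers)) {
      if (j > 1 && runif(1) < lncherit::haldane_r(10)) # 10 cM spacing
        g <- if (g == "A") "B" else "A"
      geno[i, j] <- g
    }
  }
  score <- ifelse(geno[, qtl_marker] == "B", 1, -1)
  expr <- matrix(20 + effect * score + rnorm(n_lines, 0, noise_sd), 1,
                 n_lines, dimnames = list("trait1", rownames(geno)))
  counts <- matrix(50L, 1, n_lines,
                   dimnames = list("trait1", rownames(geno)))
  ril_panel(map, geno, expr,
            parentA_expression = c(trait1 = 20 - effect),
            parentB_expression = c(trait1 = 20 + effect),
            counts = counts)
}

test_that("Haldane map function has the right limits and values", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(1e9), 0.5)
  expect_equal(haldane_r(50), (1 - exp(-1)) / 2)
  # monotone increasing
  d <- seq(0, 200, by = 5)
  expect_true(all(diff(haldane_r(d)) > 0))
})

test_that("LR/LOD conversion is exact and self-inverse", {
  expect_equal(lr_to_lod(19.23), 19.23 / (2 * log(10)))
  x <- c(0.5, 4.17, 20)
  expect_equal(lr_to_lod(lod_to_lr(x)), x)
})

test_that("genetic_map validates cM/bp consistency", {
  expect_error(genetic_map(c("a", "b"), "chr1", c(0, 10), c(100, 50)),
               "disagree")
  m <- genetic_map(c("b", "a"), "chr1", c(10, 0), c(100, 50))
  expect_equal(m$marker_id, c("a", "b"))   # sorted by position
})

test_that("genotype probabilities interpolate correctly", {
  panel <- make_toy_panel()
  # at a typed marker the probability is the genotype itself
  p6 <- genotype_probability(panel, "chr1", panel$map$position_cM[6])
  expect_equal(unname(p6), as.numeric(panel$genotypes[, 6] == "B"))
  # between two identical flanks the probability stays near that genotype
  p_mid <- genotype_probability(panel, "chr1", 55)
  same_bb <- panel$genotypes[, 6] == "B" & panel$genotypes[, 7] == "B"
  same_aa <- panel$genotypes[, 6] == "A" & panel$genotypes[, 7] == "A"
  expect_true(all(p_mid[same_bb] > 0.9))
  expect_true(all(p_mid[same_aa] < 0.1))
  # between opposite flanks it is strictly intermediate
  flip <- panel$genotypes[, 6] == "A" & panel$genotypes[, 7] == "B"
  if (any(flip)) expect_true(all(p_mid[flip] > 0.1 & p_mid[flip] < 0.9))
  expect_true(all(p_mid >= 0 & p_mid <= 1))
})

test_that("interval mapping finds the planted QTL with the right effect", {
  panel <- make_toy_panel()
  sc <- interval_mapping_scan(panel, "trait1")
  expect_s3_class(sc, "lod_curve")
  peak <- sc[which.max(sc$lod), ]
  expect_lt(abs(peak$pos_cM - panel$map$position_cM[6]), 10)
  expect_gt(peak$lod, 5)
  expect_gt(peak$effect, 0)          # B allele raises expression
  expect_gt(peak$var_explained, 0.2)
  # LOD relates to the nested-model RSS ratio: recompute at the peak of a
  # cofactor-free scan with a simple regression
  sc0 <- interval_mapping_scan(panel, "trait1", cofactors = 0L)
  peak0 <- sc0[which.max(sc0$lod), ]
  y <- as.numeric(panel$expression["trait1", rownames(panel$genotypes)])
  x <- 2 * genotype_probability(panel, "chr1", peak0$pos_cM) - 1
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ x))^2)
  expect_equal(peak0$lod, (length(y) / 2) * log10(rss0 / rss1),
               tolerance = 1e-6)
})

test_that("permutation thresholds are quantiles of null maxima", {
  panel <- make_toy_panel()
  set.seed(62)
  th <- permutation_threshold(panel, "trait1", n_perm = 50)
  expect_length(th$max_lods, 50L)
  expect_equal(th$lod_threshold,
               unname(quantile(th$max_lods, 0.95, type = 7)))
  expect_equal(th$lr_threshold, lod_to_lr(th$lod_threshold))
  expect_error(permutation_threshold(panel, "trait1", n_perm = 5), "20")
  # the fast no-cofactor path agrees with explicit permuted scans
  set.seed(63)
  g <- lncherit:::scan_grid(panel, 1)
  y <- as.numeric(panel$expression["trait1", rownames(panel$genotypes)])
  yp <- sample(y)
  Xc <- sweep(g$X, 2, colMeans(g$X))
  yc <- yp - mean(yp)
  lod_cf <- (length(y) / 2) * log10(
    sum(yc^2) / pmax(sum(yc^2) -
      as.numeric(crossprod(Xc, yc))^2 / colSums(Xc^2),
      .Machine$double.eps))
  shuf <- panel
  expr2 <- panel$expression
  expr2["trait1", ] <- yp
  shuf$expression <- expr2
  sc <- interval_mapping_scan(shuf, "trait1", cofactors = 0L, grid = g)
  expect_equal(max(sc$lod, na.rm = TRUE), max(lod_cf), tolerance = 1e-10)
})

test_that("support intervals drop 1 LOD with interpolation", {
  curve <- structure(
    data.frame(chrom = "chr1", pos_cM = seq(0, 40, by = 10),
               lod = c(1, 3, 5, 2, 1),
               effect = 1, var_explained = 0.1),
    class = c("lod_curve", "data.frame"))
  si <- support_interval(curve, 3L)
  # target 4: crossing between 10 (lod 3) and 20 (lod 5) -> 15;
  # right: between 20 (5) and 30 (2) -> 20 + 10/3
  expect_equal(unname(si["left"]), 15)
  expect_equal(unname(si["right"]), 20 + 10 / 3)
  # interval is clamped at chromosome ends
  si2 <- support_interval(curve, 3L, drop = 10)
  expect_equal(unname(si2), c(0, 40))
  # a peak at the first or last grid position must not crash
  edge <- structure(
    data.frame(chrom = "chr1", pos_cM = c(0, 10, 20),
               lod = c(5, 3, 1), effect = 1, var_explained = 0.1),
    class = c("lod_curve", "data.frame"))
  si3 <- support_interval(edge, 1L)
  expect_equal(unname(si3), c(0, 5))
  edge2 <- structure(
    data.frame(chrom = "chr1", pos_cM = c(0, 10, 20),
               lod = c(1, 3, 5), effect = 1, var_explained = 0.1),
    class = c("lod_curve", "data.frame"))
  si4 <- support_interval(edge2, 3L)
  expect_equal(unname(si4), c(15, 20))
})

test_that("nearby peaks merge transitively, keeping the strongest", {
  peaks <- data.frame(
    trait_id = "t", chrom = "chr1",
    peak_cM = c(10, 18, 25, 60),
    lod = c(4, 6, 5, 7),
    left_cM = c(8, 15, 23, 55), right_cM = c(12, 20, 27, 65),
    effect = 1, var_explained = 0.1, stringsAsFactors = FALSE)
  merged <- merge_peaks(peaks)
  # 10-18-25 chain merges (gaps < 10), 60 stays
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$peak_cM, c(18, 60))
  expect_equal(merged$left_cM[1], 8)
  expect_equal(merged$right_cM[1], 27)
})

test_that("cis/trans classification uses the support interval", {
  map <- genetic_map(c("m1", "m2"), "chr1", c(0, 100), c(0, 1e6))
  peak <- data.frame(chrom = "chr1", left_cM = 40, right_cM = 60)
  # trait at bp 500000 -> 50 cM: inside
  expect_identical(classify_cis_trans(peak, "chr1", 5e5, map), "cis")
  expect_identical(classify_cis_trans(peak, "chr1", 1e5, map), "trans")
  peak2 <- data.frame(chrom = "chr2", left_cM = 40, right_cM = 60)
  expect_identical(classify_cis_trans(peak2, "chr1", 5e5, map), "trans")
  expect_warning(
    out <- classify_cis_trans(peak, "chrX", 5e5, map), "unmapped")
  expect_identical(out, "unknown")
})

test_that("dominant regulation picks the larger variance share, tie to cis", {
  pk <- data.frame(relation = c("cis", "trans"),
                   var_explained = c(0.3, 0.2))
  expect_identical(dominant_regulation_class(pk), "cis_dominant")
  pk$var_explained <- c(0.2, 0.3)
  expect_identical(dominant_regulation_class(pk), "trans_dominant")
  pk$var_explained <- c(0.25, 0.25)
  expect_identical(dominant_regulation_class(pk), "cis_dominant")
})

test_that("map_eqtl maps the planted QTL end to end", {
  panel <- make_toy_panel()
  set.seed(64)
  th <- permutation_threshold(panel, "trait1", n_perm = 100)
  res <- map_eqtl(panel, "trait1", th$lod_threshold,
                  trait_chrom = "chr1", trait_bp = 1e6)
  expect_equal(nrow(res), 1L)
  expect_identical(res$relation, "cis")
  true_cM <- panel$map$position_cM[6]
  expect_gte(true_cM, res$left_cM)
  expect_lte(true_cM, res$right_cM)
  expect_gt(res$effect, 0)
})

test_that("parent deviation is zero for parents at the progeny mean", {
  panel <- make_toy_panel()
  y <- panel$expression["trait1", ]
  panel$parentA_expression["trait1"] <- mean(y)
  panel$parentB_expression["trait1"] <- mean(y)
  d <- parent_deviation(panel, "trait1")
  expect_equal(d$dev_parentA, 0)
  expect_equal(d$magnitude, 0)
  # affine invariance: shifting and scaling expression leaves it unchanged
  panel2 <- make_toy_panel()
  d1 <- parent_deviation(panel2, "trait1")
  panel3 <- panel2
  panel3$expression <- 3 * panel2$expression + 7
  panel3$parentA_expression <- 3 * panel2$parentA_expression + 7
  panel3$parentB_expression <- 3 * panel2$parentB_expression + 7
  d3 <- parent_deviation(panel3, "trait1")
  expect_equal(d3$dev_parentA, d1$dev_parentA)
  expect_equal(d3$magnitude, d1$magnitude)
})

test_that("parent deviation restricts to detected lines", {
  panel <- make_toy_panel()
  # silence half the lines: their expression must not influence mu/sigma
  silent <- seq(1, 40)
  panel$counts["trait1", silent] <- 0L
  y_kept <- panel$expression["trait1", -silent]
  d <- parent_deviation(panel, "trait1")
  expect_equal(d$dev_parentA,
               (panel$parentA_expression[["trait1"]] - mean(y_kept)) /
                 sd(y_kept))
  expect_error(parent_deviation(make_toy_panel(noise_sd = 0, effect = 0),
                                "trait1"), "degenerate")
})

test_that("detection classes cut at 80% and 40%", {
  panel <- make_toy_panel()
  counts <- rbind(panel$counts,
                  matrix(c(rep(50L, 48), rep(0L, 32)), 1, 80,
                         dimnames = list("trait2", colnames(panel$counts))),
                  matrix(0L, 1, 80,
                         dimnames = list("trait3", colnames(panel$counts))))
  panel$counts <- counts
  cls <- expression_detection_classes(panel)
  expect_equal(cls$class[cls$trait_id == "trait1"], 1L)
  expect_equal(cls$class[cls$trait_id == "trait2"], 2L)
  expect_equal(cls$class[cls$trait_id == "trait3"], 3L)
})

test_that("deviation comparison matches wilcox.test", {
  set.seed(65)
  a <- abs(rnorm(20)); b <- abs(rnorm(20, 1))
  res <- deviation_comparison(a, b)
  expect_equal(res$p_value,
               suppressWarnings(wilcox.test(a, b)$p.value))
  expect_error(deviation_comparison(numeric(0), b), "non-empty")
})
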