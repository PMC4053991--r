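#' Expression inheritance and eQTL mapping in a RIL panel
#'
#' The scan is composite interval mapping realized as Haley-Knott
#' regression: expression is regressed on the expected genotype at each
#' grid position, with forward-selected marker cofactors excluded within a
#' window of the test position. LOD = (n/2) log10(RSS0/RSS1). Permutation
#' thresholds shuffle line labels; peaks get 1.0-LOD support intervals, are
#' merged when closer than 10 cM, and are labeled cis when the e-trait's
#' interpolated genetic position falls inside the support interval.
#'
#' @name inheritance_eqtl
NULL

#' Haldane map function
#'
#' @param d_cM genetic distance in centimorgans.
#' @return recombination fraction r = (1 - exp(-2 d / 100)) / 2.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Build a genetic map
#'
#' @param marker_id,chrom,position_cM,position_bp parallel vectors.
#' @return data.frame of class `genetic_map`, ordered by chrom then cM.
#' @export
genetic_map <- function(marker_id, chrom, position_cM, position_bp) {
  m <- data.frame(marker_id = as.character(marker_id),
                  chrom = as.character(chrom),
                  position_cM = as.numeric(position_cM),
                  position_bp = as.numeric(position_bp),
                  stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$position_cM), , drop = FALSE]
  for (ch in unique(m$chrom)) {
    d <- m[m$chrom == ch, ]
    if (is.unsorted(d$position_bp))
      stop("cM and bp orders disagree on chromosome ", ch)
  }
  rownames(m) <- NULL
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Assemble a RIL panel
#'
#' @param map a [genetic_map()].
#' @param genotypes lines x markers matrix coded `"A"` (parent A allele),
#'   `"B"` (parent B allele) or `NA`; column names are marker ids.
#' @param expression traits x lines numeric matrix (e.g. RPKM).
#' @param parentA_expression,parentB_expression named vectors over traits.
#' @param counts optional traits x lines integer counts (for detection).
#' @return object of class `ril_panel`.
#' @export
ril_panel <- function(map, genotypes, expression, parentA_expression,
                      parentB_expression, counts = NULL) {
  if (!all(colnames(genotypes) == map$marker_id))
    genotypes <- genotypes[, map$marker_id, drop = FALSE]
  stopifnot(ncol(genotypes) == nrow(map))
  if (!all(colnames(expression) == rownames(genotypes)))
    stopifnot(setequal(colnames(expression), rownames(genotypes)))
  structure(list(map = map, genotypes = genotypes, expression = expression,
                 parentA_expression = parentA_expression,
                 parentB_expression = parentB_expression, counts = counts,
                 line_count = nrow(genotypes)),
            class = "ril_panel")
}

#' @export
print.ril_panel <- function(x, ...) {
  cat(sprintf("<ril_panel> %d lines, %d markers on %d chromosome(s), %d traits\n",
              x$line_count, nrow(x$map), length(unique(x$map$chrom)),
              nrow(x$expression)))
  invisible(x)
}

#' Classify traits by the fraction of lines with detectable expression
#'
#' @param panel a [ril_panel()] with `counts`.
#' @param min_reads detection threshold per line (default 4).
#' @return data.frame: `trait_id`, `detected_fraction`, `class` (1 when
#'   >= 80% of lines, 2 when strictly between 40% and 80%, 3 otherwise).
#' @export
expression_detection_classes <- function(panel, min_reads = 4L) {
  if (is.null(panel$counts)) stop("panel has no counts")
  frac <- rowMeans(panel$counts >= min_reads)
  cls <- ifelse(frac >= 0.8, 1L, ifelse(frac > 0.4, 2L, 3L))
  data.frame(trait_id = rownames(panel$counts), detected_fraction = frac,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Parental deviation of a trait from the progeny distribution
#'
#' For each parent P, the statistic (Exp_P - mu_progeny) / sigma_progeny,
#' with the progeny mean and standard deviation taken over lines with
#' detectable expression (all non-missing lines when the panel has no
#' counts). The magnitude is the Euclidean norm of the two deviations.
#'
#' @param panel a [ril_panel()].
#' @param trait_id trait to evaluate.
#' @param min_reads detection threshold when counts are available.
#' @return list: `trait_id`, `dev_parentA`, `dev_parentB`, `magnitude`.
#' @export
parent_deviation <- function(panel, trait_id, min_reads = 4L) {
  y <- panel$expression[trait_id, ]
  keep <- !is.na(y)
  if (!is.null(panel$counts))
    keep <- keep & panel$counts[trait_id, ] >= min_reads
  y <- y[keep]
  if (length(y) < 2L) stop("too few detected lines for ", trait_id)
  mu <- mean(y); sigma <- stats::sd(y)
  if (sigma == 0) stop("degenerate trait (zero progeny variance): ", trait_id)
  da <- (panel$parentA_expression[[trait_id]] - mu) / sigma
  db <- (panel$parentB_expression[[trait_id]] - mu) / sigma
  list(trait_id = trait_id, dev_parentA = da, dev_parentB = db,
       magnitude = sqrt(da^2 + db^2))
}

#' Compare deviation magnitudes between two trait sets
#'
#' @param devs_a,devs_b numeric vectors of deviation magnitudes.
#' @return list with `p_value` (two-sided Wilcoxon rank-sum) and
#'   `statistic`.
#' @export
deviation_comparison <- function(devs_a, devs_b) {
  if (length(devs_a) == 0L || length(devs_b) == 0L)
    stop("both sets must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(devs_a, devs_b))
  list(p_value = wt$p.value, statistic = unname(wt$statistic))
}

# numeric genotype score in [-1, 1]: -1 = parent A, +1 = parent B
genotype_score <- function(g) ifelse(g == "B", 1, ifelse(g == "A", -1, NA))

# conditional probability of parent-B genotype at pos_cM for every line
genotype_prob_vector <- function(panel, chrom, pos_cM) {
  mk <- panel$map[panel$map$chrom == chrom, , drop = FALSE]
  if (nrow(mk) == 0L) stop("no markers on chromosome ", chrom)
  if (pos_cM < min(mk$position_cM) - 1e-9 ||
      pos_cM > max(mk$position_cM) + 1e-9)
    stop("position off the map span of chromosome ", chrom)
  G <- panel$genotypes[, mk$marker_id, drop = FALSE]
  n <- nrow(G)
  probs <- numeric(n)
  same <- function(d) 1 - haldane_r(d)   # P(no genotype switch)
  for (i in seq_len(n)) {
    g <- G[i, ]
    typed <- which(!is.na(g))
    if (length(typed) == 0L) { probs[i] <- 0.5; next }
    left <- typed[mk$position_cM[typed] <= pos_cM + 1e-9]
    right <- typed[mk$position_cM[typed] >= pos_cM - 1e-9]
    l <- if (length(left)) left[length(left)] else NA
    r <- if (length(right)) right[1L] else NA
    trans <- function(from_B, d) {
      s <- same(d)
      if (from_B) s else 1 - s
    }
    if (!is.na(l) && !is.na(r) && l == r) {
      probs[i] <- as.numeric(g[l] == "B")
    } else if (!is.na(l) && !is.na(r)) {
      dl <- pos_cM - mk$position_cM[l]; dr <- mk$position_cM[r] - pos_cM
      # P(B | gl, gr) = P(gl->B; dl) P(B->gr; dr) / P(gl->gr; dl+dr)
      num <- trans(g[l] == "B", dl) *
        (if (g[r] == "B") same(dr) else 1 - same(dr))
      den <- if (g[l] == g[r]) same(dl + dr) else 1 - same(dl + dr)
      probs[i] <- num / den
    } else if (!is.na(l)) {
      probs[i] <- trans(g[l] == "B", pos_cM - mk$position_cM[l])
    } else {
      probs[i] <- trans(g[r] == "B", mk$position_cM[r] - pos_cM)
    }
  }
  probs
}

#' Probability of the parent-B genotype at an arbitrary map position
#'
#' At a typed marker the probability is the observed genotype (0/1);
#' between markers it is the conditional probability given the flanking
#' genotypes under a two-state Markov chain with Haldane recombination
#' fractions; missing genotypes fall back to the nearest typed flank(s).
#'
#' @param panel a [ril_panel()].
#' @param chrom chromosome.
#' @param position_cM genetic position (must lie on the chromosome's span).
#' @param line line name or index (omit for all lines).
#' @return probability (or vector over lines) of the parent-B genotype.
#' @export
genotype_probability <- function(panel, chrom, position_cM, line = NULL) {
  p <- genotype_prob_vector(panel, chrom, position_cM)
  names(p) <- rownames(panel$genotypes)
  if (is.null(line)) p else unname(p[line])
}

# grid of test positions and their expected genotype scores (lines x pos)
scan_grid <- function(panel, step_cM) {
  grids <- lapply(unique(panel$map$chrom), function(ch) {
    mk <- panel$map[panel$map$chrom == ch, ]
    pos <- seq(min(mk$position_cM), max(mk$position_cM), by = step_cM)
    if (pos[length(pos)] < max(mk$position_cM))
      pos <- c(pos, max(mk$position_cM))
    data.frame(chrom = ch, pos_cM = pos, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  X <- vapply(seq_len(nrow(grid)), function(i)
    2 * genotype_prob_vector(panel, grid$chrom[i], grid$pos_cM[i]) - 1,
    numeric(nrow(panel$genotypes)))
  list(grid = grid, X = X)
}

# imputed numeric marker matrix (lines x markers) for cofactor selection
marker_scores <- function(panel) {
  X <- vapply(seq_len(nrow(panel$map)), function(i)
    2 * genotype_prob_vector(panel, panel$map$chrom[i],
                             panel$map$position_cM[i]) - 1,
    numeric(nrow(panel$genotypes)))
  colnames(X) <- panel$map$marker_id
  X
}

forward_select_cofactors <- function(y, M, n_cofactors) {
  chosen <- integer()
  res <- y - mean(y)
  for (k in seq_len(n_cofactors)) {
    r2 <- suppressWarnings(as.vector(stats::cor(res, M)))^2
    r2[is.na(r2)] <- 0
    r2[chosen] <- 0
    best <- which.max(r2)
    if (r2[best] < 1e-6) break
    chosen <- c(chosen, best)
    fit <- stats::lm.fit(cbind(1, M[, chosen, drop = FALSE]), y)
    res <- fit$residuals
  }
  chosen
}

#' Genome scan for a single expression trait
#'
#' Haley-Knott regression of expression on the expected genotype at each
#' grid position, with up to `cofactors` forward-selected marker
#' covariates; cofactors within `window_cM` of the test position (same
#' chromosome) are excluded from that position's model.
#'
#' @param panel a [ril_panel()].
#' @param trait_id trait to scan.
#' @param step_cM grid step (default 1).
#' @param cofactors number of marker cofactors (default 3; 0 gives simple
#'   interval mapping).
#' @param window_cM cofactor exclusion window (default 10).
#' @param grid optional precomputed [scan positions] from an earlier scan of
#'   the same panel (internal reuse).
#' @return data.frame of class `lod_curve`: `chrom`, `pos_cM`, `lod`,
#'   `effect` (additive, positive = parent-B allele increases the trait),
#'   `var_explained`.
#' @export
interval_mapping_scan <- function(panel, trait_id, step_cM = 1,
                                  cofactors = 3L, window_cM = 10,
                                  grid = NULL) {
  y <- panel$expression[trait_id, rownames(panel$genotypes)]
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  n <- length(y)
  if (n < 10L) stop("too few lines with expression for ", trait_id)
  if (is.null(grid)) grid <- scan_grid(panel, step_cM)
  X <- grid$X[keep, , drop = FALSE]
  gpos <- grid$grid
  tss <- sum((y - mean(y))^2)

  cof_idx <- integer()
  M <- NULL
  if (cofactors > 0L) {
    M <- marker_scores(panel)[keep, , drop = FALSE]
    cof_idx <- forward_select_cofactors(y, M, cofactors)
  }
  cof_pos <- if (length(cof_idx))
    panel$map[cof_idx, c("chrom", "position_cM")] else NULL

  out <- data.frame(gpos, lod = NA_real_, effect = NA_real_,
                    var_explained = NA_real_)
  skipped <- 0L
  for (i in seq_len(nrow(gpos))) {
    x <- X[, i]
    use_cof <- cof_idx
    if (length(cof_idx)) {
      far <- !(cof_pos$chrom == gpos$chrom[i] &
               abs(cof_pos$position_cM - gpos$pos_cM[i]) < window_cM)
      use_cof <- cof_idx[far]
    }
    base <- if (length(use_cof)) cbind(1, M[, use_cof, drop = FALSE])
            else matrix(1, n, 1L)
    if (stats::var(x) < 1e-12) { skipped <- skipped + 1L; next }
    f0 <- stats::lm.fit(base, y)
    f1 <- stats::lm.fit(cbind(base, x), y)
    rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
    if (rss1 <= 0) rss1 <- .Machine$double.eps
    out$lod[i] <- (n / 2) * log10(rss0 / rss1)
    out$effect[i] <- unname(f1$coefficients[length(f1$coefficients)])
    out$var_explained[i] <- max(0, (rss0 - rss1) / tss)
  }
  if (skipped > 0L)
    warning(skipped, " monomorphic position(s) skipped")
  class(out) <- c("lod_curve", "data.frame")
  attr(out, "trait_id") <- trait_id
  attr(out, "n") <- n
  out
}

#' Convert a likelihood-ratio statistic to a LOD score
#'
#' LOD = LR / (2 ln 10).
#'
#' @param lr non-negative likelihood-ratio test statistic.
#' @return LOD score.
#' @export
lr_to_lod <- function(lr) {
  if (any(lr < 0)) stop("likelihood ratio must be non-negative")
  lr / (2 * log(10))
}

#' @rdname lr_to_lod
#' @param lod LOD score.
#' @export
lod_to_lr <- function(lod) {
  if (any(lod < 0)) stop("LOD must be non-negative")
  lod * 2 * log(10)
}

#' Genome-wide permutation significance threshold
#'
#' For each sampled trait and each replicate, line labels of the expression
#' vector are permuted against the genotypes and the genome-wide maximum
#' LOD recorded; the threshold is the (1 - alpha) quantile of all
#' trait-by-replicate maxima.
#'
#' @param panel a [ril_panel()].
#' @param traits trait ids to permute (default: all).
#' @param n_perm replicates per trait (>= 20).
#' @param alpha genome-wide significance level (default 0.05).
#' @param step_cM,cofactors,window_cM scan settings (cofactors default 0:
#'   the null scan needs no background control and is much faster).
#' @return list: `lod_threshold`, `lr_threshold`, `max_lods` (all maxima).
#' @export
permutation_threshold <- function(panel, traits = NULL, n_perm = 200L,
                                  alpha = 0.05, step_cM = 1, cofactors = 0L,
                                  window_cM = 10) {
  if (n_perm < 20L) stop("need at least 20 permutation replicates")
  if (is.null(traits)) traits <- rownames(panel$expression)
  grid <- scan_grid(panel, step_cM)
  maxima <- numeric(0)
  for (tr in traits) {
    y <- panel$expression[tr, rownames(panel$genotypes)]
    if (cofactors == 0L && !anyNA(y)) {
      # closed-form fast path: with no cofactors each position is a simple
      # regression, so all permutations reduce to one cross-product
      y <- as.numeric(y); n <- length(y)
      Y <- vapply(seq_len(n_perm), function(p) y[sample.int(n)], numeric(n))
      Yc <- sweep(Y, 2L, colMeans(Y))
      ssy <- colSums(Yc^2)
      Xc <- sweep(grid$X, 2L, colMeans(grid$X))
      sxx <- colSums(Xc^2)
      poly <- sxx >= 1e-12
      sxy <- crossprod(Xc[, poly, drop = FALSE], Yc)   # positions x perms
      lod <- (n / 2) * log10(sweep(sxy^2 / sxx[poly], 2L, ssy, function(a, b)
        b / pmax(b - a, .Machine$double.eps)))
      maxima <- c(maxima, apply(lod, 2L, max))
      next
    }
    for (p in seq_len(n_perm)) {
      shuf <- panel
      shuf$expression <- panel$expression[, sample(ncol(panel$expression)),
                                          drop = FALSE]
      colnames(shuf$expression) <- colnames(panel$expression)
      curve <- interval_mapping_scan(shuf, tr, step_cM, cofactors,
                                     window_cM, grid = grid)
      maxima <- c(maxima, max(curve$lod, na.rm = TRUE))
    }
  }
  lod_thr <- unname(stats::quantile(maxima, 1 - alpha, type = 7))
  list(lod_threshold = lod_thr, lr_threshold = lod_to_lr(lod_thr),
       max_lods = maxima)
}

#' 1.0-LOD support interval around a peak
#'
#' Left/right bounds are where the LOD curve first drops below
#' `peak - drop` moving away from the peak, linearly interpolated between
#' grid points and clamped to the chromosome ends.
#'
#' @param lod_curve a single-chromosome `lod_curve` (or subset thereof).
#' @param peak_index row index of the peak in `lod_curve`.
#' @param drop LOD drop defining the interval (default 1.0).
#' @return numeric `c(left_cM, right_cM)`.
#' @export
support_interval <- function(lod_curve, peak_index, drop = 1.0) {
  pos <- lod_curve$pos_cM; lod <- lod_curve$lod
  target <- lod[peak_index] - drop
  cross <- function(i0, i1) {
    # interpolate where lod crosses target between grid points i0 (above)
    # and i1 (below)
    if (is.na(lod[i1])) return(pos[i1])
    pos[i0] + (pos[i1] - pos[i0]) * (lod[i0] - target) / (lod[i0] - lod[i1])
  }
  left <- pos[1L]
  if (peak_index > 1L) {
    for (i in seq(peak_index, 2L)) {
      if (!is.na(lod[i - 1L]) && lod[i - 1L] < target) {
        left <- cross(i, i - 1L); break
      }
    }
  }
  right <- pos[length(pos)]
  if (peak_index < length(pos)) {
    for (i in seq(peak_index, length(pos) - 1L)) {
      if (!is.na(lod[i + 1L]) && lod[i + 1L] < target) {
        right <- cross(i, i + 1L); break
      }
    }
  }
  c(left = left, right = right)
}

# local maxima of a LOD curve above a threshold, one chromosome
chrom_peaks <- function(curve, threshold) {
  lod <- curve$lod
  n <- length(lod)
  idx <- which(!is.na(lod) & lod >= threshold)
  peaks <- idx[vapply(idx, function(i) {
    lf <- if (i > 1L) lod[i - 1L] else -Inf
    rt <- if (i < n) lod[i + 1L] else -Inf
    lf <- ifelse(is.na(lf), -Inf, lf); rt <- ifelse(is.na(rt), -Inf, rt)
    lod[i] >= lf && lod[i] > rt || (lod[i] >= lf && i == n)
  }, TRUE)]
  peaks
}

#' Merge adjacent eQTL peaks
#'
#' Adjacent peaks whose support intervals overlap, or whose positions are
#' closer than `min_sep_cM`, are merged transitively into one peak keeping
#' the higher-LOD peak's position, LOD, effect and variance explained, with
#' the union support interval.
#'
#' @param peaks data.frame of peaks on one chromosome for one trait
#'   (columns `peak_cM`, `lod`, `left_cM`, `right_cM`, `effect`,
#'   `var_explained`), sorted by position.
#' @param min_sep_cM merge distance (default 10).
#' @param overlap_rule `"either"` merges on interval overlap OR peak
#'   distance < `min_sep_cM`; `"distance"` uses peak distance only.
#' @return merged data.frame of the same shape.
#' @export
merge_peaks <- function(peaks, min_sep_cM = 10,
                        overlap_rule = c("either", "distance")) {
  overlap_rule <- match.arg(overlap_rule)
  if (nrow(peaks) <= 1L) return(peaks)
  peaks <- peaks[order(peaks$peak_cM), , drop = FALSE]
  merged <- list(peaks[1L, , drop = FALSE])
  for (i in 2:nrow(peaks)) {
    cur <- merged[[length(merged)]]
    nxt <- peaks[i, , drop = FALSE]
    near <- (nxt$peak_cM - cur$peak_cM) < min_sep_cM
    overl <- nxt$left_cM <= cur$right_cM
    if (near || (overlap_rule == "either" && overl)) {
      keep <- if (nxt$lod > cur$lod) nxt else cur
      keep$left_cM <- min(cur$left_cM, nxt$left_cM)
      keep$right_cM <- max(cur$right_cM, nxt$right_cM)
      merged[[length(merged)]] <- keep
    } else merged[[length(merged) + 1L]] <- nxt
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

# interpolate a bp position to cM via flanking mapped markers
bp_to_cM <- function(map, chrom, bp) {
  mk <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(mk) == 0L) return(NA_real_)
  if (bp <= mk$position_bp[1L]) return(mk$position_cM[1L])
  n <- nrow(mk)
  if (bp >= mk$position_bp[n]) return(mk$position_cM[n])
  i <- findInterval(bp, mk$position_bp)
  b0 <- mk$position_bp[i]; b1 <- mk$position_bp[i + 1L]
  c0 <- mk$position_cM[i]; c1 <- mk$position_cM[i + 1L]
  if (b1 == b0) return(c0)
  c0 + (c1 - c0) * (bp - b0) / (b1 - b0)
}

#' Label an eQTL peak cis or trans
#'
#' The trait's genomic position (its transcript midpoint) is interpolated
#' to cM via flanking mapped markers; the peak is cis iff that position
#' lies inside the peak's support interval on the same chromosome.
#'
#' @param peak one-row data.frame with `chrom`, `left_cM`, `right_cM`.
#' @param trait_chrom,trait_bp genomic location of the e-trait (midpoint).
#' @param map a [genetic_map()].
#' @return `"cis"`, `"trans"`, or `"unknown"` (trait on an unmapped
#'   chromosome, with a warning).
#' @export
classify_cis_trans <- function(peak, trait_chrom, trait_bp, map) {
  if (!trait_chrom %in% map$chrom) {
    warning("trait on unmapped chromosome ", trait_chrom)
    return("unknown")
  }
  if (peak$chrom != trait_chrom) return("trans")
  cm <- bp_to_cM(map, trait_chrom, trait_bp)
  if (cm >= peak$left_cM && cm <= peak$right_cM) "cis" else "trans"
}

#' Predominant regulation class of a trait
#'
#' Compares the maximum variance explained among the trait's cis peaks with
#' that among its trans peaks; an absent side counts as 0 and ties go to
#' cis.
#'
#' @param peaks data.frame with columns `relation` and `var_explained`.
#' @return `"cis_dominant"` or `"trans_dominant"`.
#' @export
dominant_regulation_class <- function(peaks) {
  if (nrow(peaks) == 0L) stop("trait has no peaks")
  cis <- max(c(0, peaks$var_explained[peaks$relation == "cis"]))
  trans <- max(c(0, peaks$var_explained[peaks$relation == "trans"]))
  if (trans > cis) "trans_dominant" else "cis_dominant"
}

#' Scan a trait and report merged, classified eQTL peaks
#'
#' @param panel a [ril_panel()].
#' @param trait_id trait to map.
#' @param lod_threshold significance threshold (e.g. from
#'   [permutation_threshold()]).
#' @param trait_chrom,trait_bp e-trait genomic location (midpoint) for
#'   cis/trans labels; omit to skip labeling.
#' @param ... passed to [interval_mapping_scan()].
#' @return data.frame of eQTL peaks: `trait_id`, `chrom`, `peak_cM`,
#'   `lod`, `left_cM`, `right_cM`, `effect`, `var_explained`, `relation`.
#' @export
map_eqtl <- function(panel, trait_id, lod_threshold, trait_chrom = NULL,
                     trait_bp = NULL, ...) {
  curve <- interval_mapping_scan(panel, trait_id, ...)
  res <- list()
  for (ch in unique(curve$chrom)) {
    cc <- curve[curve$chrom == ch, , drop = FALSE]
    rownames(cc) <- NULL
    pk <- chrom_peaks(cc, lod_threshold)
    if (length(pk) == 0L) next
    peaks <- do.call(rbind, lapply(pk, function(i) {
      si <- support_interval(cc, i)
      data.frame(trait_id = trait_id, chrom = ch, peak_cM = cc$pos_cM[i],
                 lod = cc$lod[i], left_cM = si[["left"]],
                 right_cM = si[["right"]], effect = cc$effect[i],
                 var_explained = cc$var_explained[i],
                 stringsAsFactors = FALSE)
    }))
    res[[ch]] <- merge_peaks(peaks)
  }
  if (length(res) == 0L)
    return(data.frame(trait_id = character(), chrom = character(),
                      peak_cM = numeric(), lod = numeric(),
                      left_cM = numeric(), right_cM = numeric(),
                      effect = numeric(), var_explained = numeric(),
                      relation = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$relation <- NA_character_
  if (!is.null(trait_chrom))
    out$relation <- vapply(seq_len(nrow(out)), function(i)
      classify_cis_trans(out[i, ], trait_chrom, trait_bp, panel$map), "")
  out
}
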