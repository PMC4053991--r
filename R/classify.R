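#' Transcript-catalog merging and the lncRNA classification cascade
#'
#' The classifier applies, in order: size filter (>= 200 nt), complete-ORF
#' filter (<= 100 aa), protein-similarity filter (E <= 0.001 against a
#' protein set), coding-potential score, housekeeping-RNA elimination
#' (E < 1e-10 against tRNA/rRNA/snRNA/snoRNA/SRP sequences), and finally the
#' small-RNA split: candidates containing small-RNA reads verbatim (either
#' strand) are precursors (pre-lncRNA), the rest are high-confidence
#' lncRNAs.
#'
#' @name lncrna_classifier
NULL

structure_key <- function(tx) {
  e <- tx$exons
  if (nrow(e) == 1L) return(NA_character_)
  introns <- transcript_introns(tx)
  paste0(e$chrom[1L], ":", paste(introns$start, introns$end, sep = "-",
                                 collapse = ","))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Merge per-experiment assemblies with a reference annotation
#'
#' An assembled isoform is retained iff an identical structure appears in at
#' least `min_experiments` experiments: multi-exon isoforms match on an
#' identical intron chain (same chromosome); single-exon isoforms match at
#' reciprocal overlap >= `min_overlap`. Retained isoforms that match no
#' annotation isoform are added as novel; the result is the non-redundant
#' union keyed by structure.
#'
#' @param assembly_sets list of [annotation_set()]s, one per experiment.
#' @param annotation the reference [annotation_set()].
#' @param min_experiments detection threshold (default 2).
#' @param min_overlap single-exon reciprocal-overlap threshold (default 0.9).
#' @return an [annotation_set()]: all annotation isoforms plus retained
#'   novel assembly isoforms.
#' @export
merge_transcript_catalogs <- function(assembly_sets, annotation,
                                      min_experiments = 2L,
                                      min_overlap = 0.9) {
  if (length(assembly_sets) < 1L) stop("need at least one assembly set")
  ann_chroms <- unique(unlist(lapply(annotation$transcripts,
                                     function(tx) tx$exons$chrom)))
  asm <- list()
  for (i in seq_along(assembly_sets)) {
    for (tx in assembly_sets[[i]]$transcripts) {
      if (length(ann_chroms) && !tx$exons$chrom[1L] %in% ann_chroms)
        stop("assembly set ", i, " uses chromosome '", tx$exons$chrom[1L],
             "' absent from the annotation namespace")
      asm[[length(asm) + 1L]] <- list(tx = tx, experiment = i,
                                      key = structure_key(tx))
    }
  }
  multi <- asm[!vapply(asm, function(a) is.na(a$key), TRUE)]
  single <- asm[vapply(asm, function(a) is.na(a$key), TRUE)]

  retained <- list()
  # multi-exon: group by intron chain, count distinct experiments
  if (length(multi)) {
    keys <- vapply(multi, `[[`, "", "key")
    for (k in unique(keys)) {
      grp <- multi[keys == k]
      if (length(unique(vapply(grp, `[[`, 0L, "experiment"))) >=
          min_experiments)
        retained[[length(retained) + 1L]] <- grp[[1L]]$tx
    }
  }
  # single-exon: greedy clustering by reciprocal overlap
  if (length(single)) {
    spans <- do.call(rbind, lapply(single, function(a) {
      sp <- transcript_span(a$tx)
      data.frame(chrom = sp$chrom, start = sp$start, end = sp$end,
                 experiment = a$experiment, stringsAsFactors = FALSE)
    }))
    ord <- order(spans$chrom, spans$start, spans$end)
    cluster_of <- integer(nrow(spans))
    reps <- list()   # cluster representatives (row indices)
    for (i in ord) {
      assigned <- FALSE
      for (ci in seq_along(reps)) {
        r <- reps[[ci]]
        if (spans$chrom[r] == spans$chrom[i] &&
            reciprocal_overlap(spans$start[r], spans$end[r],
                               spans$start[i], spans$end[i]) >= min_overlap) {
          cluster_of[i] <- ci; assigned <- TRUE; break
        }
      }
      if (!assigned) { reps[[length(reps) + 1L]] <- i
                       cluster_of[i] <- length(reps) }
    }
    for (ci in seq_along(reps)) {
      members <- which(cluster_of == ci)
      if (length(unique(spans$experiment[members])) >= min_experiments)
        retained[[length(retained) + 1L]] <- single[[members[1L]]]$tx
    }
  }

  # drop retained isoforms already present in the annotation
  ann_keys <- vapply(annotation$transcripts, structure_key, "")
  ann_single <- annotation$transcripts[is.na(ann_keys)]
  ann_spans <- lapply(ann_single, transcript_span)
  is_known <- function(tx) {
    k <- structure_key(tx)
    if (!is.na(k)) return(k %in% ann_keys)
    sp <- transcript_span(tx)
    any(vapply(ann_spans, function(a)
      a$chrom == sp$chrom &&
        reciprocal_overlap(a$start, a$end, sp$start, sp$end) >= min_overlap,
      TRUE))
  }
  novel <- retained[!vapply(retained, is_known, TRUE)]
  annotation_set(c(unname(annotation$transcripts), novel))
}

#' Eliminate housekeeping RNAs
#'
#' Candidates with a nucleotide-alignment expectation value below
#' `evalue_cutoff` against the housekeeping set (tRNA/rRNA/snRNA/snoRNA/SRP)
#' are excluded.
#'
#' @param candidates an [annotation_set()].
#' @param housekeeping_db named character vector of housekeeping RNA
#'   sequences.
#' @param evalue_cutoff exclusion threshold (default 1e-10).
#' @return list with `kept` ([annotation_set()]) and `excluded` (data.frame
#'   `transcript_id`, `label` = "housekeeping", `evidence` = best E-value).
#' @export
housekeeping_filter <- function(candidates, housekeeping_db,
                                evalue_cutoff = 1e-10) {
  if (length(housekeeping_db) == 0L) stop("housekeeping set must be non-empty")
  txs <- candidates$transcripts
  if (length(txs) == 0L)
    return(list(kept = candidates,
                excluded = data.frame(transcript_id = character(),
                                      label = character(),
                                      evidence = numeric(),
                                      stringsAsFactors = FALSE)))
  seqs <- stats::setNames(vapply(txs, `[[`, "", "sequence"), names(txs))
  hits <- nucleotide_similarity_search(seqs, housekeeping_db)
  sig <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  best <- sig[!duplicated(sig$query_id), , drop = FALSE]
  excluded <- data.frame(transcript_id = best$query_id,
                         label = rep("housekeeping", nrow(best)),
                         evidence = best$evalue, stringsAsFactors = FALSE)
  keep <- setdiff(names(txs), excluded$transcript_id)
  list(kept = annotation_set(unname(txs[keep])), excluded = excluded)
}

#' Split candidates into small-RNA precursors and high-confidence lncRNAs
#'
#' A candidate is a precursor (pre-lncRNA) iff at least `min_matches`
#' distinct reads occur in it verbatim (full read length, zero mismatches,
#' either strand); otherwise it is a high-confidence lncRNA.
#'
#' @param candidates an [annotation_set()].
#' @param small_rnas character vector of small-RNA reads (18-30 nt; reads
#'   outside that range are skipped with a warning).
#' @param min_matches minimum distinct matching reads (default 1).
#' @return list with `hc_lncrna` and `pre_lncrna` ([annotation_set()]s) and
#'   `match_counts` (named integer vector of distinct-read matches).
#' @export
split_by_small_rna <- function(candidates, small_rnas, min_matches = 1L) {
  txs <- candidates$transcripts
  reads <- toupper(unique(small_rnas))
  bad <- nchar(reads) < 18L | nchar(reads) > 30L
  if (any(bad)) {
    warning(sum(bad), " read(s) outside 18-30 nt skipped")
    reads <- reads[!bad]
  }
  counts <- stats::setNames(integer(length(txs)), names(txs))
  if (length(reads) && length(txs)) {
    subj <- Biostrings::DNAStringSet(
      stats::setNames(vapply(txs, `[[`, "", "sequence"), names(txs)))
    hit_any <- matrix(FALSE, length(reads), length(txs))
    for (w in unique(nchar(reads))) {
      idx <- which(nchar(reads) == w)
      pd_f <- Biostrings::PDict(Biostrings::DNAStringSet(reads[idx]))
      pd_r <- Biostrings::PDict(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[idx])))
      cf <- Biostrings::vcountPDict(pd_f, subj)
      cr <- Biostrings::vcountPDict(pd_r, subj)
      hit_any[idx, ] <- (cf + cr) > 0L
    }
    counts[] <- colSums(hit_any)
  }
  pre_ids <- names(counts)[counts >= min_matches]
  hc_ids <- setdiff(names(txs), pre_ids)
  list(hc_lncrna = annotation_set(unname(txs[hc_ids])),
       pre_lncrna = annotation_set(unname(txs[pre_ids])),
       match_counts = counts)
}

#' Fraction of each transcript covered by repeat-library k-mers
#'
#' Positions covered by any exact `k`-mer shared with the repeat library
#' (either strand) are masked; the repeat fraction is masked length /
#' transcript length. A transcript is "repeat-associated" iff its fraction
#' is at least `threshold`.
#'
#' @param candidates an [annotation_set()] or named character vector.
#' @param repeat_library character vector of repeat consensus sequences.
#' @param k shared k-mer size (default 15).
#' @param threshold repeat-associated cutoff (default 0.5).
#' @return data.frame: `transcript_id`, `repeat_fraction`,
#'   `repeat_associated`.
#' @export
annotate_repeats <- function(candidates, repeat_library, k = 15L,
                             threshold = 0.5) {
  if (length(repeat_library) == 0L) stop("repeat library must be non-empty")
  if (inherits(candidates, "annotation_set"))
    seqs <- stats::setNames(
      vapply(candidates$transcripts, `[[`, "", "sequence"),
      names(candidates$transcripts))
  else seqs <- candidates
  lib <- toupper(c(repeat_library, revcomp(repeat_library)))
  lib_kmers <- unique(unlist(lapply(lib, function(s) {
    if (nchar(s) < k) return(character())
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  }), use.names = FALSE))
  frac <- vapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(0)
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    hit <- which(kmers %in% lib_kmers)
    if (length(hit) == 0L) return(0)
    covered <- logical(n)
    for (i in hit) covered[i:(i + k - 1L)] <- TRUE
    sum(covered) / n
  }, 0)
  data.frame(transcript_id = names(seqs), repeat_fraction = unname(frac),
             repeat_associated = unname(frac) >= threshold,
             stringsAsFactors = FALSE)
}

# batch protein-similarity filter: returns best E-value per transcript
protein_filter_batch <- function(txs, proteins) {
  frames <- lapply(txs, function(tx) six_frame_translations(tx$sequence))
  all_frames <- unlist(frames, use.names = FALSE)
  owner <- rep(seq_along(txs), each = 6L)
  n_total <- sum(nchar(proteins))
  hits <- run_seeded_search(all_frames, unname(proteins), "protein",
                            search_space = 1)
  m_per_tx <- vapply(frames, function(f) sum(nchar(f)), 0)
  best <- stats::setNames(rep(Inf, length(txs)), names(txs))
  if (nrow(hits)) {
    tx_of_hit <- owner[hits$query]
    ev <- hits$evalue * m_per_tx[tx_of_hit] * n_total
    for (i in seq_along(ev))
      best[tx_of_hit[i]] <- min(best[tx_of_hit[i]], ev[i])
  }
  best
}

#' Run the full lncRNA classification cascade
#'
#' @param annotation an [annotation_set()] with sequences attached.
#' @param references list with elements `proteins` (peptides),
#'   `housekeeping` (nucleotide), `repeats` (nucleotide), and the
#'   coding-potential training sets `coding_train` / `noncoding_train`
#'   (nucleotide) or a pre-trained `coding_model`.
#' @param small_rnas character vector of small-RNA reads.
#' @param config list of thresholds: `min_len` (200), `max_orf_aa` (100),
#'   `protein_evalue` (1e-3), `hk_evalue` (1e-10), `min_smallrna_matches`
#'   (1), `repeat_k` (15), `repeat_threshold` (0.5).
#' @param out_dir optional directory; when given, writes `records.tsv`,
#'   `summary.tsv`, `hc_lncrna.gtf`, `pre_lncrna.gtf`.
#' @return list with `records` (one row per input transcript:
#'   `transcript_id`, `label`, `evidence`, `repeat_fraction`), `summary`
#'   (counts per label), `hc_lncrna` and `pre_lncrna` annotation sets.
#' @export
classify_pipeline <- function(annotation, references, small_rnas,
                              config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(
    list(min_len = 200L, max_orf_aa = 100L, protein_evalue = 1e-3,
         hk_evalue = 1e-10, min_smallrna_matches = 1L, repeat_k = 15L,
         repeat_threshold = 0.5), config)
  recs <- list()
  push <- function(df) recs[[length(recs) + 1L]] <<- df

  # 1-2: size and ORF
  sz <- filter_size_and_orf(annotation, cfg$min_len, cfg$max_orf_aa)
  if (nrow(sz$excluded)) push(sz$excluded)
  cand <- sz$candidates

  # 3: protein similarity
  if (length(cand$transcripts)) {
    best_ev <- protein_filter_batch(cand$transcripts, references$proteins)
    hit <- names(best_ev)[best_ev <= cfg$protein_evalue]
    if (length(hit))
      push(data.frame(transcript_id = hit, label = "protein_similar",
                      evidence = unname(best_ev[hit]),
                      stringsAsFactors = FALSE))
    cand <- annotation_set(unname(
      cand$transcripts[setdiff(names(cand$transcripts), hit)]))
  }

  # 4: coding-potential score
  if (length(cand$transcripts)) {
    model <- if (inherits(references$coding_model, "coding_model"))
      references$coding_model
    else train_coding_model(references$coding_train, references$noncoding_train)
    cp <- coding_potential_score(cand, model)
    hit <- cp$transcript_id[cp$verdict == "coding"]
    if (length(hit))
      push(data.frame(transcript_id = hit, label = "coding_potential",
                      evidence = cp$score[cp$verdict == "coding"],
                      stringsAsFactors = FALSE))
    cand <- annotation_set(unname(
      cand$transcripts[setdiff(names(cand$transcripts), hit)]))
  }

  # 5: housekeeping elimination
  hk <- housekeeping_filter(cand, references$housekeeping, cfg$hk_evalue)
  if (nrow(hk$excluded)) push(hk$excluded)
  cand <- hk$kept

  # 6: small-RNA split
  sp <- split_by_small_rna(cand, small_rnas, cfg$min_smallrna_matches)
  if (length(sp$pre_lncrna$transcripts))
    push(data.frame(transcript_id = names(sp$pre_lncrna$transcripts),
                    label = "pre_lncrna",
                    evidence = unname(sp$match_counts[
                      names(sp$pre_lncrna$transcripts)]),
                    stringsAsFactors = FALSE))
  if (length(sp$hc_lncrna$transcripts))
    push(data.frame(transcript_id = names(sp$hc_lncrna$transcripts),
                    label = "hc_lncrna", evidence = 0,
                    stringsAsFactors = FALSE))

  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  # repeat annotation on all inputs
  rep_frac <- annotate_repeats(annotation, references$repeats,
                               cfg$repeat_k, cfg$repeat_threshold)
  records <- merge(records, rep_frac[, c("transcript_id", "repeat_fraction")],
                   by = "transcript_id", all.x = TRUE, sort = FALSE)
  records <- records[match(names(annotation$transcripts),
                           records$transcript_id), , drop = FALSE]
  rownames(records) <- NULL
  labels <- c("too_short", "long_orf", "protein_similar", "coding_potential",
              "housekeeping", "pre_lncrna", "hc_lncrna")
  summary <- data.frame(label = labels,
                        count = as.integer(table(factor(records$label,
                                                        levels = labels))),
                        stringsAsFactors = FALSE)
  out <- list(records = records, summary = summary,
              hc_lncrna = sp$hc_lncrna, pre_lncrna = sp$pre_lncrna)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(records, file.path(out_dir, "records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gtf(sp$hc_lncrna, file.path(out_dir, "hc_lncrna.gtf"))
    write_gtf(sp$pre_lncrna, file.path(out_dir, "pre_lncrna.gtf"))
  }
  out
}
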