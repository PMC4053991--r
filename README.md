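# lncherit

Identification, characterization and expression inheritance of long
non-coding RNAs (lncRNAs), as an end-to-end tested R package.

`lncherit` implements a desk-scale emulation of a transcriptome-wide
lncRNA study in a biparental plant population:

* **Classification cascade** — partition an assembled transcript catalog
  into high-confidence lncRNAs (`hc_lncrna`), likely small-RNA precursors
  (`pre_lncrna`), and excluded classes (`too_short`, `long_orf`,
  `protein_similar`, `coding_potential`, `housekeeping`). lncRNAs are
  ≥200 nt with no *complete* ORF over 100 amino acids, no protein
  similarity at E ≤ 10⁻³, a noncoding hexamer/ORF logistic score, no
  housekeeping-RNA similarity at E < 10⁻¹⁰, and (for `hc_lncrna`) no
  exact small-RNA read match.
* **Locus characterization** — strand inference from the GT–AG intron
  rule, gene-proximity anatomy (genic overlap / within 5 kb up- or
  downstream / distal intergenic), chromosomal bin densities, and a
  permutation test of sequence conservation against length-matched
  intergenic background draws.
* **Expression profiles** — RPKM, ≥4-read detection collapsed to
  tissues, Shannon-entropy tissue specificity (0 bits = single tissue,
  log2(T) = uniform across T tissues), Ward clustering, metagene
  profiles of epigenetic tracks (H3K27me3, CG/CHG/CHH methylation).
* **Inheritance mapping** — composite interval mapping (Haley–Knott
  regression with forward-selected cofactors) of expression traits in a
  recombinant-inbred-line (RIL) panel: permutation LOD thresholds, 1-LOD
  support intervals, peak merging, cis/trans classification by interval
  containment of the trait's interpolated genomic position, and
  parent-deviation statistics for transgressive segregation.
* **Synthetic data** — seeded generators for every input (genome with
  repeat families, transcript catalog, protein and housekeeping
  references, small-RNA reads, tissue expression, epigenetic tracks, a
  RIL panel with planted eQTL), with ground truth attached. Defaults
  encode the emulated study design: 13 tissues, 105 RILs, 81%
  single-exon lncRNAs with mean spliced length ≈ 463 nt, 54%
  single-tissue expression, 3× genetic-map expansion.

Alignment-heavy steps run on a C++ seeded Smith–Waterman engine whose
scores provably equal the exhaustive dynamic-programming optimum (an
acceptance test checks this against an R oracle).

See `vignettes/lncrna-inheritance-methods.Rmd` for the models and
parameter rationale.

## Worked example

```r
library(lncherit)

## 1. generate a small synthetic study with ground truth
cfg <- generator_config(seed = 11, n_chromosomes = 2L,
                        chromosome_length_bp = 200000L,
                        n_coding = 40L, n_hc_lncrna = 25L,
                        n_pre_lncrna = 25L, n_housekeeping = 10L,
                        n_markers = 100L)
dat <- generate_all(cfg)
dat$annotation
#> <annotation_set> 100 transcripts in 100 loci

## 2. classify the transcript catalog
set.seed(12)
tab <- lncherit:::biased_codon_table()
coding_train <- replicate(60, paste0(
  paste(sample(c("A","C","G","T"), 40, TRUE), collapse = ""),
  lncherit:::make_coding_cds(sample(110:250, 1), tab),
  paste(sample(c("A","C","G","T"), 40, TRUE), collapse = "")))
noncoding_train <- replicate(60, lncherit:::draw_lnc_sequence(sample(250:700, 1)))

res <- classify_pipeline(
  dat$annotation,
  list(proteins = dat$proteins, housekeeping = dat$housekeeping_db,
       repeats = dat$repeat_library,
       coding_train = coding_train, noncoding_train = noncoding_train),
  dat$small_rnas)
res$summary
#>              label count
#> 1        too_short     0
#> 2         long_orf    43
#> 3  protein_similar     0
#> 4 coding_potential     0
#> 5     housekeeping     7
#> 6       pre_lncrna    25
#> 7        hc_lncrna    25

## agreement with generator truth
lab <- dat$truth$locus_labels
pred <- setNames(res$records$label, res$records$transcript_id)[names(lab)]
codingish <- c("long_orf", "protein_similar", "coding_potential")
mean(ifelse(lab == "coding", pred %in% codingish, pred == lab))
#> [1] 0.97

## 3. tissue specificity of the recovered hc-lncRNAs
rpkm <- dat$expression$expression$rpkm
hc <- names(pred)[pred == "hc_lncrna"]
ent <- apply(rpkm[hc, , drop = FALSE] + 1e-9, 1, shannon_entropy)
summary(ent)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.0000  0.8454  0.6746  0.9911  2.1272

## 4. map the inheritance of one lncRNA expression trait
panel <- dat$ril$panel
pos1 <- dat$ril$trait_positions[1, ]
th <- permutation_threshold(panel, "trait001", n_perm = 200)
th$lod_threshold
#> [1] 2.670974
map_eqtl(panel, "trait001", th$lod_threshold,
         trait_chrom = pos1$chrom, trait_bp = pos1$midpoint_bp)
#>   trait_id chrom peak_cM      lod left_cM right_cM    effect var_explained
#> 1 trait001  chr2      80 14.31139 75.5638 89.07259 0.8433934     0.4393434
#>   relation
#> 1      cis
```

The generator planted a cis-eQTL of additive effect +1 for `trait001`;
the scan recovers a single cis peak with the right sign and about half
the trait variance explained, as designed (effect 1, noise SD 1).
Most hc-lncRNAs show low-entropy (tissue-specific) expression while
coding genes are broadly expressed — the contrast the entropy index
is built to measure.

## Tests and reproduction

The testthat suite contains unit and property tests for each module plus
`tests/testthat/test-acceptance.R`, one test per headline criterion
(analytic LR/LOD and entropy identities, parent-deviation nullity,
classifier truth recovery ≥95% at full catalog scale, eQTL null
calibration and planted-eQTL recovery, aligner oracle equivalence,
conservation p-value uniformity). Run it with:

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "lncherit",
                               load_package = "installed")'
```

`scripts/acceptance.R` recomputes the headline quantities against the
installed package and writes them as a flat JSON object:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
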