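---
title: "Fragmentomics-based detection of biliopancreatic cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentomics-based detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Plasma cell-free DNA (cfDNA) is mostly nucleosome-protected chromatin
shed by dying cells. Its *physical* properties — fragment length, the
nucleotide context of fragment ends, and where coverage dips around
transcription start sites (TSS) — differ between cancer patients and
healthy individuals because tumor-derived cfDNA carries the chromatin
signature of its tissue of origin. `fragstack` implements a complete
low-coverage-WGS detection pipeline over three such feature families and a
stacked classifier, plus a fusion model with the serum marker CA19-9:

1. **Read qualification.** From a coordinate-sorted paired-end BAM (or a
   plain fragment table) we keep one fragment per read pair, recomputing the
   insert from mate coordinates, and apply five rules in fixed order:
   autosomal alignment; mapping quality strictly greater than 20 for both
   mates; insert size within [150, 600] bp (inclusive); proper pairing; and
   a reference interval free of non-ACGT bases. Each rejected pair is
   tallied against the first rule it fails.
2. **Fragment-size profile.** Qualified fragments with length in
   [130, 237] bp are split into short ([130, 177)) and long ([177, 237])
   classes — the printed class bounds overlap at 177, which we resolve to a
   half-open short class so the classes partition — and assigned to one
   genomic bin by midpoint. Short and total (short+long) per-bin counts are
   z-scored *within the sample across bins* and concatenated: 1008 features
   on the shipped 504-bin 5-Mb scaffold. Per-sample standardization makes
   the feature depth-invariant and usable on a single sample at prediction
   time.
3. **Codon end motif.** At both 5' ends of each fragment we read three 3-bp
   reference motifs at offsets 1, 4 and 7 of the informative end window
   (after skipping `umi_offset` bases; 5 for the UMI chemistry the feature
   was designed around, 0 for UMI-free data). Each position's 64 motif
   counts are normalized to an independent simplex: 3 × 64 = 192 features.
   Motifs are read from the reference at the fragment coordinates, not the
   read bases, which removes sequencing-error noise; both ends contribute.
4. **Nucleosome footprint (NF).** Per gene, NF = mean whole-fragment
   coverage over the closed central window TSS ± 250 bp (501 positions)
   divided by mean coverage over the strand-aware flanking reference
   windows [−2000, −1000] and [1000, 2000]. Low NF marks nucleosome
   depletion, i.e. active transcription. Genes missing NF (zero reference
   coverage) in more than `1 - min_presence` of training samples are
   dropped; remaining gaps are mean-imputed, and validation cohorts are
   projected with training-fit gene lists and means only.
5. **Models.** Linear soft-margin SVMs (cost 1) for the fragment-size and
   NF blocks, a 500-tree random forest for the motif block; stratified
   ten-fold cross-validation with fold-internal standardization and
   fold-internal Platt-style margin calibration produces out-of-fold scores
   in [0, 1]; an unpenalized logistic meta-learner stacks the three
   out-of-fold score columns; the decision cutoff minimizes size-weighted
   Gini impurity over out-of-fold stacked scores with ties broken toward
   specificity. The CF fusion model is a linear SVM on the out-of-fold
   stacked score and log2(CA19-9 + 1). Subtype contrasts reuse the same
   machinery with group membership as the outcome.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally (BED/BAM
  native); 1-based annotation input is converted at the reader boundary.
  Chromosome-name dialects ("chr1" vs "1") are harmonized against the
  genome at every reader.
* **Insert-size boundaries** are inclusive; "greater than 20" mapping
  quality is strict (MAPQ 20 fails). The global [150, 600] floor conflicts
  with the 130-bp short-class bound, so the size featurizer applies its own
  [130, 237] window via `size_bounds()` and the diagnostic distribution uses
  [90, 600]; the strict default governs motif and NF features.
* **The 504-bin scaffold.** The published bin set descends from a filtered
  hg19 tiling whose exclusion mask is not public.
  `inst/extdata/hg19_5mb_bins_synthetic.bed` is a labelled synthetic
  reconstruction: naive 5-Mb tiling of the 22 autosomes (567 bins) minus
  the 63 bins nearest approximate centromere/telomere positions. Bin count
  and geometry are reproduced; the exact mask is not. Synthetic genomes use
  naive `tile_bins()` instead.
* **Margin calibration.** The linear SVM's decision values are mapped to
  [0, 1] by a logistic fit on smoothed (Platt) targets, fit per fold on the
  training portion only, so calibrated scores are commensurate with forest
  vote fractions and survive perfectly separated folds.
* **Stacked out-of-fold estimates.** The meta-learner is fit on the
  out-of-fold base scores, and a training sample's cross-validated stacked
  estimate is the meta-learner applied to its own out-of-fold base scores
  (the standard, non-nested construction); the CF model consumes these.
* **Cross-validated AUC intervals** are fold-wise percentile intervals
  (`fold_auc_summary()`), labelled as such.
* **Degenerate inputs.** Constant feature columns get scale 1 during
  standardization (and therefore zero mapped-back coefficients); a constant
  bin vector z-scores to all zeros; NF with zero reference coverage is
  missing rather than infinite; `stratified_folds()` shrinks k to the
  minority class size with a warning.
* **Validation scoring** uses the models refit on the full training cohort
  (not an ensemble of fold models).

## What the synthetic cohorts emulate

The study's clinical data is access-controlled, so the package ships a
seeded generator (`cohort_config()`, `simulate_study()`) whose defaults are
the package's standing study conditions:

* **Cohort shape**: 89 training samples (31 non-cancer, 16 CCA, 14 GBC,
  28 PAC) and 129 validation samples (40/39/16/34), the published design.
* **Depth**: 20,000 fragments per sample on a 1.2-Mb two-chromosome
  genome, i.e. ~2.8× coverage — the same per-position depth regime as the
  study's low-coverage WGS, so per-gene NF estimates carry realistic
  Poisson noise (~10 fragments per central window). Retaining 17% of
  fragments is the analogue of downsampling ~2.9× data to 0.5×.
* **Fragment lengths**: a mono-nucleosome Gaussian at 166 ± 9 bp, a
  sub-nucleosomal comb at 10-bp spacing below 160 bp, and a small
  di-nucleosome shoulder. Cancer classes get a global short-fraction boost
  (leftward shift) *and* a bin-structured short-fraction/density profile:
  within-sample z-scoring removes purely global shifts, so regional
  structure, as produced by real tumor copy-number and fragmentation
  variation, is what the DELFI-style feature can detect. The regional
  profile is shared across the three cancer classes; per-class profiles
  would make the size feature a subtype classifier, which contradicts the
  observed phenomenology (subtypes separate on NF, not size).
* **End motifs**: the genome is a first-order Markov chain (adjacent-base
  correlation, the motivation for splitting a 9-bp motif into three 3-bp
  blocks), and cancer fragments are accept-reject resampled toward sites
  whose reference 9-bp end context matches six signature motifs (1-AAG,
  4-ATG, 7-ACA up; 1-GTT, 1-GTC, 7-GTC down). Positions move; sequence is
  never rewritten, keeping reference-based extraction honest.
* **NF**: half the genes are expressed with uniform levels; fragments whose
  midpoint falls in an expressed gene's central window are rejection-thinned
  with probability `depletion_depth × expression`. A 10-gene pan-cancer
  program (silent in controls, expression `nf_effect = 0.75` in cancer,
  ~35-50% NF reduction) carries the detection signal; 8-gene per-subtype
  programs (`subtype_nf_effect = 0.45`) carry tissue-of-origin signal.
  Moderate per-gene effects are deliberate: they keep the NF family the
  most depth-sensitive one, as observed in real data, while remaining
  recoverable from the linear model's coefficients at study scale. An early
  draft with ~50% per-gene effects made NF *depth-robust*, which is
  unrealistic.
* **CA19-9**: per-class log-normals (controls around 8 U/mL with ~2% above
  the 39 U/mL clinical cutoff; cancer classes with medians 70-180 U/mL
  chosen to approximate the published per-subtype positivity rates), and an
  8% Lewis-antigen-negative cancer subset whose values are forced low
  regardless of class — the subpopulation in which CA19-9 fails and the
  fragmentomics score is complementary.

**What is not emulated** (and what passing tests therefore do not show
about real data): sequencing error and base qualities, GC amplification
bias, duplicate/UMI read structure, realistic gene-density and chromatin
heterogeneity, mappability artifacts, batch effects, and biological
covariance between the three feature families beyond their shared class
labels. AUC values near 1 on default synthetic cohorts reflect cleanly
planted effects, not expected clinical performance; the published real-data
AUCs are not reproducible from this package.

## Problem sizes

Tests and the acceptance script run the full pipeline at the published
cohort shape (89/129) with 20,000 fragments per sample on the 1.2-Mb
genome, a null cohort of 60 controls vs 60 cancers with every class effect
zeroed, and smaller cohorts for unit-level checks. These sizes were chosen
so the end-to-end suite exercises every stage at realistic per-position
depth while remaining quick on a single CPU.

## Known limitations

* `read_fragments()` loads and pairs all primary records in memory; it is
  sized for low-coverage data and synthetic fixtures, not deep WGS.
* No GC-content correction of the fragmentation profile is applied (an
  upstream variant of this feature family applies LOESS GC adjustment; the
  method implemented here does not), and no liftover between assemblies.
* The gene-selection rule behind the published 24,639-gene NF panel is not
  specified; the explicit `min_presence` filter stands in for it and the
  annotation is fully user-supplied.
* Mann-Whitney p-values switch from the exact to the tie-corrected normal
  form at combined n > 20 (`stats::wilcox.test` semantics); two-sided by
  default.
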