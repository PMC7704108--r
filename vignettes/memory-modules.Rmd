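---
title: "Methods: scoring DNA-methylation memory modules at NF-kB binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring DNA-methylation memory modules at NF-kB binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memoryscan)
library(dplyr)
```

## The biology being modelled

Cells that have experienced sustained TNF-alpha signalling can respond to a
later TNF-alpha exposure faster, more strongly and far more sensitively —
inflammatory transcriptional memory. The epigenetic substrate of this memory
is active DNA demethylation at p65 (RELA)-bound kappaB sites: during a long
first stimulation, p65 occupancy nucleates TET-dependent demethylation of
the CpGs flanking the motif; the demethylated module then favours p65
binding and stronger activation on re-exposure. memoryscan implements the
desk-scale quantitative machinery of that analysis:

1. **Bisulfite clone quantification** (`call_clone()`, `qc_filter()`,
   `locus_level()`, `plot_lollipop()`) — locus-specific methylation from
   Sanger clones of bisulfite PCR amplicons.
2. **Memory-gene classification** (`call_responsive()`, `call_memory()`) —
   the five-condition FPKM design: naive, first 12 h induction, sustained
   12-day treatment, 10-day recovery, second 12 h induction.
3. **Peak-module scoring** (`scan_kb_motif()`, `cpgs_in_flank()`,
   `peak_methylation()`, `score_peak_modules()`,
   `demethylation_grouping()`, `link_peaks_to_genes()`,
   `demethylation_profile()`, `normalize_signal()`) — motif-anchored CpG
   accounting, total methylation M, total demethylation delta-M, state
   classes, quantile groups, peak-to-gene linking and profiles.
4. **A synthetic-data generator** (`sim_config()`, `simulate_study()` and
   friends) that plants known truth with the statistical structure the
   analysis assumes, so every stage is exercisable and testable offline.

## Classifier definitions

A gene is **TNF-alpha-responsive** when its first-induction fold change
(mean FPKM at 12 h over naive, pseudocount 1 on both means) is strictly
greater than 2 with p < 0.01. It is a **memory gene** when it is
responsive, is expressed at least 1.3-fold higher (inclusive) in the second
induction than in the first, and has a mean second-induction FPKM strictly
above 5. The FPKM floor is applied to the second induction — the condition
in which memory is asserted; the alternative readings (first induction, or
both) are not distinguished by the criteria's wording, and our choice is the
conservative one for memory claims. The 1.3-fold criterion uses condition
means rather than per-replicate values. Recovery-baseline elevation
(recovery/naive ratio) is reported but never thresholded: an IL32-like gene
with an elevated baseline and no stronger second induction must be, and is,
rejected by the second-induction ratio criterion alone.

### Why the default significance engine is a moderated t

FPKM tables in this design carry two replicates per condition. A per-gene
Welch t with n = 2 per group has one to two degrees of freedom; even a
50-fold induction with tiny noise frequently fails p < 0.01, because the
per-gene variance estimate is itself almost unestimable. The standard
remedy is to share variance information across the transcriptome, so the
default test is limma's empirical-Bayes moderated t on log2(FPKM + 1)
(`test = "moderated"`). The unmoderated Welch t remains available
(`test = "welch"`), and `p_values =` injects p-values from any external
differential-expression engine, which is the intended slot for count-based
models. The fold-change gate, not the test, does most of the specificity
work: a non-induced gene cannot pass however small its p.

A pseudocount of 1 FPKM is used in every ratio and log transform, so
all-zero genes have well-defined (unit) folds. Thresholds are strict (`>`)
for the 2-fold and FPKM-5 criteria and inclusive (`>=`) for the 1.3-fold
criterion, matching their verbal definitions ("greater than", "at least").

## Peak-module scoring

All coordinates are 0-based half-open; Bismark coverage files (1-based) are
converted at the reader (`read_bismark_cov()`), so no module ever sees mixed
conventions. The kappaB motif is found by log-odds PWM scanning on both
strands (uniform background; ties broken by leftmost position, then the
plus strand); the default PWM is a near-consensus matrix for GGGACTTTCC and
any PWM can be supplied as a position-by-ACGT TSV (`read_pwm()`). The motif
center of an even-width motif is `start + width %/% 2`.

Per peak, the CpGs within ±250 bp of the motif center (boundary inclusive)
are collected; CpGs covered by fewer than 5 reads are excluded, not
imputed, and a peak with no usable CpG carries an explicit no-data sentinel
that propagates (it is dropped from methylation-stratified analyses rather
than silently scored 0). **Total methylation** M is the sum of per-CpG
levels over those flank CpGs ("methylated-CpG equivalents": it deliberately
conflates CpG density and methylation level, because both determine the
epigenetic barrier); **total demethylation** is delta-M = M(t0) − M(12 d),
so M(t0) − delta-M = M(12 d) holds identically. Initial states use the mean
flank level: methylated at >= 50% (inclusive), unmethylated below 20%,
intermediate between. Candidate memory modules are the initially methylated
peaks whose delta-M is strictly greater than the upper quartile (Q3,
type-7 quantile) of delta-M; `demethylation_grouping()` also provides
equal-count quantile bins for the quartile/quintile views.

Peaks are linked to the single nearest TSS by absolute motif-center
distance, capped at 100 kb (inclusive), with ties resolved to the smaller
gene id and a `within_10kb` flag for distance stratification. Both 100 kb
and stricter 50 kb caps are common in enhancer-gene assignment; 100 kb is
the default and `max_dist` exposes any other choice.

Demethylation profiles smooth per-CpG levels against signed, strand-
oriented distance to the motif center with `stats::lowess` (span 0.3 by
default). The difference curve is the lowess of per-CpG differences
(t0 − t12), not the difference of two lowess fits: pairing is defined at
CpGs, and smoothing after subtraction avoids any grid mismatch between
independently smoothed curves. Curves are tabulated on a fixed grid by
linear interpolation, holding boundary values beyond the outermost CpG.

ChIP-seq-style tracks are normalized in two steps: counts-per-million per
sample, then a scale factor equalizing each sample's mean signal at
initially unmethylated (< 20%) peaks — regions whose occupancy should not
change with demethylation and therefore anchor the scale. The operation is
a fixed point: renormalizing a normalized track returns it unchanged.
Occupancy change between inductions is classified at |log2 ratio| >=
log2(1.5), inclusive; the higher/lower split has no canonical numeric
definition, so 1.5-fold is our documented default and an argument.
Enhancer RNA is quantified as RPKM over peak regions
(count / (kb × millions of mapped reads)) and compared between inductions
with a paired two-tailed t-test on log2(RPKM + 1) per demethylation group.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions, not tuning knobs:

* **Bisulfite clones** — each clone is the top-strand bisulfite image of a
  reference: non-CpG cytosines convert C→T with probability 0.99, CpG
  cytosines are retained with their per-site methylation probability, and
  every base is substituted with probability 1e-3. A CMV-promoter-like
  amplicon has 17 CpGs and is read in sets of 200 clones. Reverse-strand
  chemistry and indels are out of scope; the clone caller is deliberately
  gapless (amplicons have fixed length; indel clones fail the length check)
  and QC defaults (conversion >= 0.95, mismatch <= 0.10) are conventional
  bisulfite clone QC.
* **Toy genome** — one megabase-scale chromosome, CpG-free backbone, with
  p65 peaks each embedding the kappaB consensus, planted CpG landscapes of
  alternating density (low 0–5 / high 10–25 CpGs per ±250 bp flank) and
  alternating initial methylation class (~0.02–0.10 vs ~0.70–0.95).
  Peaks occupy the first 60% of the chromosome and TSSs are planted so
  nearest-peak distances span the < 10 kb, 10–100 kb and > 100 kb strata.
* **Methylation dynamics** — t12 level = t0 − g·δ·exp(−d/λ) clipped to
  [0, 1], with δ = 0.6, λ = 300 bp, and genotype multipliers g: WT 1.0,
  TET2-KO 0.3, TET3-KO 0.7, TET1-KO 0.95, RELA-KO 0.05, TET-TKO 0.05.
  The multipliers reproduce the qualitative ordering (demethylation mainly
  TET2-dependent, some TET3, little TET1, p65-required); they are simulator
  knobs, not estimates, because no quantitative genotype effect sizes are
  available. Counts are binomial at 30× coverage per CpG.
* **Occupancy** — summit signal amplitude·exp(−β·M)·2^ε with β = ln 2 per
  methylated-CpG equivalent and ε Gaussian (sd 0.1) on the log2 scale. The
  noise is multiplicative rather than additive by design: occupancy spans
  orders of magnitude across the M range, and a lognormal error keeps the
  signal strictly positive and its relative error constant, so the
  occupancy–methylation ordering is a property of the model, not of where
  the absolute noise floor happens to sit.
* **Expression** — replicate FPKMs are lognormal (sd 0.1 log2 units,
  2 replicates) around planted condition means: six memory genes
  (CALCB/PTGES/EGFP/CCL2/TNF/LHX2-like, planted to satisfy all three
  criteria with margin, e.g. a CALCB-like 699-FPKM sustained mean),
  an IL32-like elevated-baseline non-memory control, two responsive-only
  controls, and ~500 background genes with condition-independent means
  spanning 0.5–200 FPKM.

Everything is seeded through `sim_config()`: one config, bit-identical
outputs, including the emitted FASTA/BED/TSV/bedGraph fixtures
(`write_simulation()`).

### What passing on synthetic data does and does not show

The generator reproduces the statistical *structure* the analysis assumes —
binomial clone and count sampling, exponential demethylation geometry,
log-scale expression noise, occupancy–methylation coupling — but not the
messiness of real data: no mapping artefacts, no copy-number or repeat
effects, no correlated replicates, no DSS-style smoothing of methylation,
and CpG landscapes far tidier than a real genome's. Green tests therefore
certify the correctness and calibration of the computations, not the
biological error rates one would see on sequencing data.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation) everywhere; the top-quartile
  rule is strict (> Q3). An all-tied delta-M set yields an empty top group
  with a warning rather than an arbitrary split.
* `classify_initial_state()` propagates NA (no usable CpGs) instead of
  inventing a state.
* Degenerate zero-variance t-tests return the limiting values (p = 1 for
  identical means, p = 0 otherwise) so zero-noise simulations remain
  classifiable.
* Readers reject malformed rows loudly with line numbers; the Bismark
  percentage column is advisory and recomputed from counts, warning at
  > 0.5 percentage-point disagreement.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: clone sets of 200 clones × 17 CpGs (25 seeded replicates for the
recovery checks), toy genomes of 1 Mb with 20 peaks and 30 genes,
expression tables of ~510 genes × 5 conditions × 2 replicates, and 100
randomized toy instances per brute-force oracle comparison. These sizes
give the estimators enough data to be sharply calibrated (the clone-level
standard error is ~0.5 percentage points) while keeping a full run in tens
of seconds.

## Known limitations

* Top-strand bisulfite chemistry only; no hemimethylation or 5hmC.
* The motif scan reports the single best hit per peak; multi-site peaks
  are summarized by their strongest kappaB site.
* Peak calling, read alignment, and smoothing-based differential
  methylation are out of scope; inputs enter at the peak/coverage-table
  level.
* Enhancer–gene assignment is nearest-TSS by linear distance; no
  chromatin-contact information.

## A worked end-to-end run

```{r pipeline}
cfg <- sim_config(seed = 11)
study <- simulate_study(cfg)

scores <- score_peak_modules(study$genome$sequence, study$genome$peaks,
                             kb_pwm(), study$meth$t0, study$meth$t12)
scores |>
  filter(initial_state == "methylated") |>
  demethylation_grouping("top_quartile") |>
  count(group)

calls <- call_memory(study$expression)
glance(calls)
filter(calls, memory)$gene
```
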