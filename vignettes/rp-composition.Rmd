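---
title: "Mapping ribosomal protein composition across tissues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ribosomal protein composition across tissues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocomp)
```

## The problem

The mammalian ribosome carries ~80 ribosomal proteins (RPs). When ribosomal
fractions are purified from different organs and quantified by label-free
MS, the relative stoichiometry of individual RPs is not constant: paralogs
(Rpl3l, Rpl10l, Rpl39l, ...) replace canonical RPs in specific tissues, and
several canonical RPs are reproducibly enriched or depleted. `ribocomp`
implements the quantitative chain that takes peptide- or protein-level
abundance tables to a *stable / variable / tissue-specific* classification
of RPs, with three independent corroborating routes: hierarchical
clustering of relative-abundance profiles, targeted (PRM) isotope-dilution
quantification, and comparison with organ-level transcript (RPKM)
profiles.

## The discovery model

### Quantification and filtering

Protein abundance is iBAQ: the summed intensity of a protein's *specific*
peptides divided by its count of theoretically observable tryptic peptides
(cleavage C-terminal to K/R with no proline exception, zero missed
cleavages, peptide length 7--30; the length window is the conventional
observability range and is configurable). The denominator is floored at 1
so iBAQ stays defined for short proteins.

Two reliability rules are applied before statistics: a protein must have
been observed in *all* replicates of at least one tissue, and any per-tissue
set of values with exactly one observed replicate is discarded. With
three replicates per tissue this means every retained (protein, tissue)
pair has 0, 2 or 3 observed replicates. Each sample is then normalized by
its total RP iBAQ, making samples comparable in ribosome input; within a
sample, RP values sum to 1 and between-protein ratios are untouched.

### Missing values: POV and MEC

After log2 transformation, missing cells fall in two regimes with distinct
mechanisms and distinct imputations:

* **POV** (partially observed value): the tissue retains observed
  replicates. The cell is reconstructed from the within-tissue structure by
  a two-way least-squares fit, value = protein effect + sample offset,
  where the sample offsets are estimated from proteins observed in all
  replicates of the tissue. This additive surrogate preserves what is known
  about the missing replicate (its sample's global shift and the protein's
  within-tissue level). If a tissue has no fully observed protein the fit
  degenerates to the within-tissue protein mean, with a warning.
* **MEC** (missing in the entire condition): the protein was below the
  detection limit in the whole tissue. The cell is floored to the minimum
  observed log2 value of its sample — an explicit left-censoring floor.

The imputation mask is carried through the pipeline: fold changes are
always computed *without* MEC cells (a fold change against a censoring
floor would be arbitrary), and a significant contrast whose fold change is
undefined for that reason is reported as a `not_detected` call rather than
an enrichment or depletion.

Whether MEC cells enter the ANOVA is exposed as `exclude_mec`
(default `FALSE`, i.e. testing follows imputation); excluding them changes
the test's sample sizes for tissue-restricted proteins, which are set
aside before testing anyway.

### The statistical layer

Per RP, a classical one-way fixed-effects ANOVA across tissues is computed
on the log2 imputed values and adjusted by the Benjamini--Hochberg step-up
(the "FDR below 1%" gate is implemented as BH q < 0.01). RPs detected in at
most two tissues are classified *tissue-specific* by detection and never
tested — their fold changes against a pooled "all others" group would be
dominated by censoring.

For ANOVA-positive RPs, each tissue is compared against the pooled samples
of all other tissues. The contrast is the difference of group means on the
log2 scale; its variance is the two-group pooled variance moderated toward
an empirical-Bayes prior: a scaled inverse-chi-square prior (d0, s0²) is
fitted across proteins by matching moments of log s² on the
digamma/trigamma scale, and the posterior variance
(d0·s0² + d·s²)/(d0 + d) is used with d + d0 degrees of freedom. At d0 = 0
this is exactly the ordinary pooled-variance two-sample t-test; at d0 = ∞
it is a z-statistic with variance s0² — both limits are asserted to 1e-10
in the test suite, and the fitted prior is cross-checked against an
independent implementation (limma's `squeezeVar`). The prior is fitted per
tissue contrast because the pooled two-group variance is contrast-specific;
a shared moderation can be supplied explicitly via the `moderation`
argument. BH adjustment is applied jointly across all (protein, tissue)
pairs, mirroring a merged multiple-testing family.

Classification thresholds are q < 0.01 and |log2FC| > 1 (both exposed):
*variable* requires the ANOVA gate plus at least one enriched or depleted
tissue call; everything else detected in more than two tissues is *stable*.

### Open choices made here

* Fold changes are differences of mean log2 values (consistent with
  testing on the log2 scale), not log2 ratios of mean raw values.
* "All others" pools all non-target samples rather than averaging per-tissue
  means — the standard one-vs-all contrast on per-sample observations.

## Clustering route

Sample-level profiles (each sample's normalized values over the RP's mean
across samples, log2) drive replicate correlation and sample dendrograms;
tissue-level profiles (replicate-averaged, renormalized per tissue,
relative to the RP's cross-tissue mean) are the heatmap values. Both use
Ward linkage (`ward.D2`) on Euclidean distances; the test suite checks the
linkage against an exhaustive greedy Ward agglomeration on small point
sets. Missing cells enter distance computations as 0 (= "at the RP's own
mean") and are never imputed for reporting.

How the heatmap's stable/variable groups are delineated is genuinely
under-specified by visual clustering; `clustering_variable_set()` is a
declared surrogate: cut the RP dendrogram into k groups (default 10 for a
~85-RP panel) and flag groups whose mean profile variance exceeds the grand
mean per-RP variance. The grand *mean* — not the median — is the default
threshold because per-RP variances are strongly right-skewed: the median
falls inside the tight stable block and would flag it wholesale. RPs
detected in at most two tissues are always included: their relative profile
is computed against their own detected-tissue mean, so it is numerically
flat (a one-tissue paralog has an identically zero profile) and invisible
to any variance ranking. Both k and the threshold are arguments.

## Targeted (PRM) route

Transition tables (five mono-charged y-ions per peptide and channel) are
filtered in two stages: peptides whose summed heavy-standard signal has a
coefficient of variation above 50% across all samples are discarded
entirely (the heavy standard is spiked at a constant amount, so its
instability invalidates the peptide's calibration; the CV is computed
globally because the spike is global), and, per tissue, transitions must
exceed signal-to-noise 10 in *all* replicates of that tissue (both bounds
are strict; an alternative global scope is selectable). Peptide-level
signal is the sum of surviving transition areas; endogenous amounts follow
the isotope-dilution ratio amount = (endo/heavy) × spiked, and all amounts
are normalized per sample to the reference peptide GTGIVSAPVPK from the
stably incorporated Rps2, which removes per-sample input variation (the
suite asserts invariance under arbitrary per-sample rescaling). The
statistical layer is the discovery layer applied at peptide granularity;
peptides detected in at most two tissues are flagged specific.

## Transcript comparison

Organ-level RPKM tables are renormalized per organ over the RP gene set,
value × n_RP / ΣRPKM, which has unit mean per organ and is invariant to any
per-organ rescaling. Protein and transcript sides are aligned on shared
organs through an explicit name mapping (cortex→brain, adrenal
gland→gland). Concordance is reported per RP as the Pearson r between log2
relative profiles across shared organs (≥3 complete pairs required),
with a thresholded flag (default r ≥ 0.5). The threshold is an artifact
convention — published comparisons of this kind argue from barplots, which
is not directly assertable — so the continuous r is always reported
alongside.

## The synthetic study conditions

`sim_config()` encodes the emulated experiment: 14 tissues × 3 replicates,
85 RPs (59 stable, 22 variable, 4 tissue-restricted paralogs whose
canonical partners are reduced 2--4-fold in the host tissues) plus 100
background proteins, 2--6 specific peptides per protein, lognormal
replicate noise of sd 0.3 on log2 (giving replicate Pearson r ≈ 0.95--0.99),
planted fold changes of ±1.5 and ±2 on one or two target tissues, logistic
MNAR missingness in log2 intensity plus 2% MCAR, and spiked-in PRM panels
with deliberately unstable heavy standards and sub-threshold
signal-to-noise transitions.

Two generator choices deserve explanation:

* **Organ modulation.** Every RP receives a small per-tissue modulation
  (sd 0.15 log2, row-centered) shared between the protein truth profile and
  the transcript generator. Without it, stable RPs have mathematically flat
  profiles and protein--transcript correlation is undefined or
  noise-driven, which would make concordance testing meaningless; with it,
  every RP has a reproducible organ profile whose magnitude (≪ 1 log2)
  cannot flip any classification call. Transcript base abundances are drawn
  in a narrow range (2^5--2^8 RPKM) because RP mRNAs are uniformly highly
  expressed; a wide range would let a few dominant genes leak their
  profiles into the per-organ renormalization.
* **Deterministic violations.** CV-violating PRM peptides alternate their
  heavy signal by ±80% (realized CV ≈ 0.75) instead of drawing
  high-variance noise, and planted low-S/N transitions are set explicitly
  below 10, so "the filters discard exactly the planted violations" is a
  well-posed property rather than a probabilistic one.

The truth object stores the *expected* normalized log2 tissue profiles and
one-vs-all fold changes, which include the shift introduced by RP-total
normalization (an enrichment of one RP slightly deflates all others in
that tissue); in the noiseless limit the pipeline reproduces these
expectations to 1e-9, which the suite asserts.

What the generator does **not** emulate: correlated peptide-level
interference, retention-time drift and cross-run alignment artifacts,
protein-inference ambiguity, batch structure, or heavy-standard digestion
variability beyond a global response factor. Passing the recovery suite
therefore demonstrates the correctness and calibration of the statistical
chain under clean MS-like noise, not robustness to every failure mode of
real acquisitions.

## Numerical choices and problem sizes

Step-up BH is computed exactly and verified against brute force; the
trigamma inversion in the moderation fit uses Newton iterations to
relative 1e-10; Ward heights are on the Euclidean (`ward.D2`) scale;
results tables are written with 10 significant digits, which bounds
read/write round-trip error at 1e-9 relative. Degenerate inputs are
handled explicitly: empty heavy signal (CV filter flags and discards),
constant profiles (correlation undefined and flagged), tissues without
fully observed proteins (imputation falls back with a warning), fewer than
three usable variances (no moderation, d0 = 0, with a warning).

The test suite and the acceptance script run the default conditions at
full size (85 RPs × 42 samples; 20 and 10 simulation replicates for the
recovery properties) — a few seconds per replicate — and smaller
parameterised fixtures elsewhere; sizes were chosen so the full suite
completes in well under a minute of compute per module.

## Known limitations

* The POV imputation is a documented additive surrogate for
  structured-least-squares imputation; exact per-cell agreement with other
  tools' implementations is not claimed (category-level results are robust
  to this, which is what the recovery suite measures).
* The clustering-derived variable set depends on k and the variance
  threshold; it is a surrogate for a visual heatmap delineation and should
  be read as corroboration of the statistical route, not an independent
  gold standard.
* Concordance with transcripts uses a fixed-threshold Pearson flag over at
  most seven organs; with so few points, r is a coarse statistic and the
  continuous value should be inspected.
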