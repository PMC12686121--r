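---
title: "Calling and modelling zygotic genome activation genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and modelling zygotic genome activation genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgakit)
```

## The problem

During the maternal-to-zygotic transition, a mammalian embryo switches from
maternally deposited transcripts to transcription from its own genome —
zygotic genome activation (ZGA). The timing of the major wave differs by
species: the 2-cell stage in mouse, the 4–8-cell stages in human and pig,
the 8–16-cell stages in bovine and goat. `zgakit` implements a complete desk
pipeline around this phenomenon:

1. call ZGA genes from staged expression tables with species-specific
   TPM-ratio rules, and non-ZGA genes as those near-silent throughout
   preimplantation development;
2. represent each gene by the k-mer spectrum of its TSS (−2, +1 kb) and TES
   (−1, +2 kb) flanks, or by binned histone-mark signal around the TSS;
3. train and tune classifiers that separate ZGA from non-ZGA genes;
4. interpret them with Shapley attributions (global importance, predictor
   direction, per-gene explanations, pairwise interactions);
5. link salient k-mers to transcription-factor motifs via PWM comparison;
6. screen genome-wide score tables with a high-confidence rule.

A coupled synthetic-data generator plants known structure (enriched k-mers,
class-specific chromatin bumps, rule-consistent expression) so that every
stage of the pipeline is testable end to end without external data.

## Calling ZGA and non-ZGA genes

A ruleset holds ratio conditions of the form *numerator stage / denominator
stage > threshold*. The mouse preset, for example, tests
early2C/1C > 2.5, late2C/1C > 3, early2C/MII > 3, late2C/MII > 3 and
late2C/early2C > 3; the human/pig and bovine/goat presets shift the same
five-condition pattern to their own activation stages. A gene is ZGA when
any condition fires.

```{r ruleset}
zga_ruleset("mouse")$conditions
```

The published criteria qualify the ratios with a maternal-TPM clause
("when the TPM values of MII or 1C < 0.5") that admits two readings, and the
caller implements both:

* **floor** (default): every ratio is computed as
  `numerator / max(denominator, 0.5)`. A gene silent in the oocyte and
  expressed at the 2-cell stage still yields a large, finite ratio; a gene
  already expressed maternally needs proportionally more zygotic signal.
* **gate**: ratios are computed plainly, but a condition only counts for
  genes whose maternal-stage TPM is below 0.5.

The floor reading is the default because it degrades gracefully (no division
blow-up at zero maternal TPM) and preserves the intent — rewarding de novo
transcription — without discarding genes whose maternal TPM sits just above
the cut. Both modes are exposed via `call_zga(..., mode =)`.

Non-ZGA genes are those with summed TPM below 2 across preimplantation
stages. The MII oocyte is excluded from the sum (it precedes preimplantation
development), and genes called ZGA by the ratio rules are excluded from the
non-ZGA set so the two sets are disjoint by construction.

```{r call}
rs <- zga_ruleset("mouse")
tab <- matrix(0.1, 3, length(rs$stages),
              dimnames = list(c("zga1", "silent", "maternal"), rs$stages))
tab["zga1", c("early2C", "late2C")] <- c(6, 30)
tab["maternal", ] <- 5
call_zga(tab, rs)
```

## Sequence features: the k-mer spectrum of TSS/TES flanks

For each gene, `featurize()` extracts the TSS (−2, +1 kb) and TES
(−1, +2 kb) windows in the direction of transcription (minus-strand genes
are reverse-complemented), counts all `4^k` words with a step-1 sliding
window, sums the two regions into one spectrum and divides by the number of
valid windows. Choices worth stating:

* **Summed, not concatenated, regions.** The model features are plain
  6-mers (`TATATA`, `CTGCAG`, ...) with no region suffix, so both flank
  regions contribute to a single spectrum per gene.
* **Reverse complements are kept distinct** — `ATATAT` and `TATATA` are
  separate features, which matters because attribution later reports them
  separately.
* **Windows containing N are skipped**, not imputed, so counts stay
  interpretable; frequencies are used rather than raw counts because clipped
  windows (genes near chromosome ends) change the denominator.
* Columns are in fixed lexicographic order, so any feature is addressable
  by name.

`k = 6` is the default (with `k` scanned over 4–8 in the published setting,
6 is the accuracy/cost compromise the models settled on).

## Chromatin features: 20 bins around the TSS

`assemble_epi_matrix()` converts per-mark bedGraph coverage into a gene ×
(mark × bin) matrix: 20 bins of 300 bp spanning TSS ± 3 kb, FPKM-normalised
(`bin_sum / ((bin_width/1000) · (library_size/10^6))`), columns named
`mark_i`. Bin 1 is always the most upstream bin *in the direction of
transcription* (minus-strand genes reverse their reference-order bins), so
bins 10/11 straddle the TSS on both strands and a near-TSS feature such as
`H3K27me3_10` means the same thing for every gene. Replicates are merged by
averaging per-replicate FPKM, the scale-equivalent of merging alignments.
Peak calling, input correction and spike-in normalisation are out of scope.

## Learning

`balance_and_split()` subsamples negatives to match the positive count and
makes a stratified 80/20 train/test split. Feature selection and
hyperparameter search run strictly inside the training split.

**MIC ranking.** Features are ranked by the maximal information coefficient
against the label. No MINE implementation ships with the installed R stack,
so the statistic is computed exactly by this package for the binary-target
case: with the label axis fixed at two rows, the MINE search over grids with
`nx · ny ≤ n^0.6` reduces to maximising mutual information over x-axis
partitions with at most `n^0.6 / 2` bins, solved by dynamic programming over
tie-respecting clumps (pre-merged to at most `5 ·` that many superclumps, as
in ApproxMaxMI). The suite checks it against exhaustive partition
enumeration on small inputs.

**Incremental feature selection** evaluates nested prefixes of the ranking
(sizes 1..20 by default) by 10-fold cross-validated accuracy and keeps the
best prefix, breaking ties toward fewer features. The cap of 20 reflects
the size of the published final models, where five shared features made up
roughly a quarter of the modelled features. On strongly planted synthetic
data the selection often stops after the planted k-mers themselves — the
accuracy plateau is reached immediately, and the tie-break keeps the model
minimal.

**Classifiers.** Four algorithms are supported behind one interface: RBF
SVM (`e1071`), random forest (`ranger`, probability trees), L2 logistic
regression (`glmnet`, ridge) and gradient boosting (`xgboost`).
`grid_search_train()` scores every grid row by mean 10-fold CV accuracy
(accuracy is the selection metric; AUC is reported alongside), refits the
best row on the full training split, and records everything needed to
reproduce the fit. The default grids are conventional and overridable:
RF trees {100, 300, 500} × depth {unlimited, 10, 20}; SVM C {0.1, 1, 10} ×
gamma {scale, 0.01}; LR C {0.01, 0.1, 1, 10}; GBM trees {100, 300} ×
learning rate {0.1, 0.05} × depth {3, 6}. The binned chromatin model is
trained on the full mark × bin matrix (no feature selection) so that
near-TSS bins of every mark remain inspectable by attribution — consistent
with how the published chromatin model reports a repressive near-TSS bin at
rank 20.

**Evaluation.** `evaluate()` thresholds probabilities at 0.5 and reports
sensitivity TP/(TP+FN), precision TP/(TP+FP), accuracy (TP+TN)/N and
F1 = 2TP/(2TP+FP+FN), plus the ROC curve and trapezoidal AUC. Undefined
metrics (zero denominators) are reported as `NaN` and flagged, never
silently zeroed. The suite checks the AUC against the Mann–Whitney
normalisation and an independent implementation (`pROC`).

## Attribution

`compute_shap()` produces Shapley attributions whose local accuracy —
base value plus contributions equals the model output — is asserted by the
tests at 1e-6 for tree-exact paths:

* **Random forests**: the installed R stack has no tree-Shapley
  implementation, so the package ships a compiled path-dependent
  tree-Shapley kernel operating on parsed `ranger` forests, with node covers
  taken from the bootstrap in-bag counts (which makes leaf values and
  cover-weighted expectations mutually consistent). It is verified against
  exhaustive-subset Shapley values on small forests and against xgboost's
  exact attribution on identically parsed trees. Attributions are on the
  probability scale.
* **Gradient boosting**: xgboost's built-in exact attribution
  (log-odds margin scale, stated in the output).
* **SVM / logistic**: sampling-based Shapley against the training-mean
  reference (2,048 permutations by default, fixed seed). Because each
  permutation telescopes, contributions sum exactly to
  `f(x) − f(reference)` at any permutation count; only the per-feature
  split is stochastic.

`summarize_attribution()` ranks features by mean |SHAP| and calls each one
*favourable* or *unfavourable* by the Pearson correlation between feature
values and attributions (±0.2 by default, configurable; constant features
are indeterminate, and direction calls require at least 20 samples).
`interaction_summary()` returns exact pairwise interaction values for tree
models — the forest kernel recomputes attributions conditioned on each
feature being always-known/always-unknown and differences them — and
refuses non-tree models with a typed error. The reference choice
(training-split feature means) is the smallest-variance conventional
option; tree paths use cover-weighted expectations instead, which is what
makes them exact.

## Motif linking

`kmer_to_pwm()` encodes a salient k-mer as a position weight matrix
(consensus probability 0.997), `export_meme()`/`read_meme()` round-trip
MEME minimal format so external motif tools can consume the features, and
`match_pwm()` is a Tomtom-style comparator: every database motif is scored
in both orientations at all offsets with at least 5 aligned columns
(allowing one-column slop for 6-mer queries without admitting trivial
overlaps) by mean per-column Pearson correlation, with an empirical p-value
from shuffling the query's columns. Matches are ranked by score, then
overlap length, then p-value — deliberately not p-first, because for short
or internally repetitive queries (`ATATAT` has only a handful of distinct
column orders, many equivalent to the original) the shuffle null is nearly
degenerate: a perfect self-match can carry a *large* p-value while a random
decoy gets a small one, so the p-value is kept as a significance annotation
rather than the ranking key. Alignment ties prefer the longer overlap and
then the smaller offset, so a full-length self-match always outranks a
shifted partial match. The exact significance machinery of the
external tool is deliberately not reimplemented — the MEME export exists
precisely so the real tool can be run where its databases are available —
and no significance threshold is asserted as the published one, since that
threshold is unstated.

## Screening

`build_report()` merges sequence scores, optional chromatin scores and any
number of per-dataset fold changes by gene id; absent chromatin data stays
absent rather than becoming zero. `apply_high_confidence_rule()` implements
the combined rule: sequence score ≥ 0.6 and fold change ≥ 2 in at least two
datasets, with chromatin score ≥ 0.6 additionally required under the mouse
rule. Species without chromatin data simply skip that clause (the default
rule); under the mouse rule a missing chromatin score fails the gene and the
trace records why. All thresholds are arguments; the rule evaluator is
tested against brute-force clause enumeration at the threshold boundaries.

## The synthetic generator, and what passing tests do and do not show

`generate_genome()` lays one gene per 20 kb slot on a single synthetic
chromosome (alternating strands, i.i.d. bases at the target GC), which makes
the non-overlap of all analysis windows trivially true. `plant_motifs()`
writes Poisson-distributed copies of the planted k-mers (defaults `TATATA`
and `ATTAAT`, mirroring the TA-rich preference the published models report;
means 8 per positive flank pair vs 1 per negative) at uniform,
non-overlapping positions — rejection placement keeps the expected-count
oracle exact. `simulate_expression()` uses near-silent (0.1 TPM) maternal
templates and strong (20 TPM) activation-stage templates for ZGA genes,
clearing every ruleset threshold with margin, with multiplicative lognormal
noise (TPM is positive); profiles whose noisy draw would flip the label are
resampled, never silently emitted. `simulate_chip_signal()` adds Gaussian
bumps (amplitude 5, FWHM 600 bp, centre TSS−150) for active marks on ZGA
genes and for the repressive mark on non-ZGA genes over a 0.5 background,
at 50 bp interval resolution so binning is exact and bedGraph round-trips
bit-for-bit up to float formatting.

These defaults are the study conditions for the package's own validation;
they are deliberately easy in ways real data is not. The generator does not
produce transcriptome-wide correlation structure, GC/repeat composition
biases, alternative TSSs, overlapping genes, read-level noise or
batch effects. Passing the recovery suites therefore demonstrates that the
*machinery* is correct — the caller matches its rule table, featurization is
strand-exact, selection finds informative columns, the classifiers separate
what is separable, attribution recovers planted sign structure — not that
any particular AUC will transfer to real embryos.

## Numerical choices and problem sizes

* Ratio denominators are floored at 0.5 TPM; fold changes use a 0.01
  pseudocount; the decision threshold for confusion counts is 0.5.
* Ties in feature selection go to fewer features; ties in grid search go to
  the earlier grid row; both make reruns deterministic under a fixed seed.
* Random-forest Shapley values are double-precision exact (the suite
  asserts 1e-10–1e-6); xgboost attributions are float32-limited, so the
  margin-scale identity is asserted at 1e-5.
* The validation studies use 400 genes (sequence model) and 200 genes
  (chromatin model) with 10 seeds for the recovery rates — sizes chosen so
  the planted effects dominate sampling noise while the whole suite stays
  quick on one CPU.
* `match_pwm` p-values use 200–1,000 column-shuffle permutations depending
  on context; with a 6-column query the permutation space is 720, so
  p-values below ~1/720 are not resolvable — fine for ranking, stated here
  for honesty.

## Known limitations

* The caller takes one expression value per gene and stage; replicate
  handling beyond a configurable mean, and statistical testing of
  differential expression, are out of scope (fold change here is a
  screening ratio, not a DE test).
* Chromatin quantification starts from coverage tracks; alignment and
  fragment-level processing are upstream of this package.
* Sampling-based Shapley for SVM/LR trades exactness for reproducibility;
  interaction values are tree-only.
* The Tomtom-style comparator ranks sensibly but its empirical p-values are
  permutation-limited (above) and not calibrated against the external
  tool's null model.
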