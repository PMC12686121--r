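# zgakit

Tools for identifying and modelling **zygotic genome activation (ZGA)
genes** — the genes an early mammalian embryo switches on when it hands
control from maternal transcripts to its own genome. The package is aimed at
computational biologists working on preimplantation development who want a
reproducible desk pipeline from staged expression tables to interpretable
sequence/chromatin classifiers and genome-wide screening reports.

## What it implements

**Rule-based calling.** ZGA genes are called from gene × stage TPM tables by
species-specific ratio rules; e.g. for mouse, a gene is ZGA when any of

```
early2C/1C > 2.5,  late2C/1C > 3,  early2C/MII > 3,
late2C/MII > 3,    late2C/early2C > 3
```

holds, with ratio denominators floored at 0.5 TPM (a "gate" reading of the
maternal-TPM clause is available as an option). Presets cover mouse,
human/pig and bovine/goat stage systems. Non-ZGA genes are those with
summed TPM < 2 across preimplantation stages.

**Sequence model.** Each gene is represented by the frequency spectrum of
all 4^k k-mers (k = 6 by default) in its TSS (−2, +1 kb) and TES (−1, +2 kb)
flanks, extracted strand-aware. Features are ranked by the maximal
information coefficient (MIC), pruned by incremental feature selection
under 10-fold CV, and fed to one of four classifiers (SVM, random forest,
L2 logistic regression, gradient boosting) tuned by grid-searched 10-fold
cross-validation on a balanced 80/20 split.

**Chromatin model.** Per-mark signal tracks are binned into 20 × 300 bp
FPKM-normalised windows spanning TSS ± 3 kb (`mark_i` columns, bin 1 most
upstream of transcription) and classified the same way.

**Attribution.** Trained models are interpreted with Shapley values:
an exact compiled tree-Shapley kernel for random forests (plus xgboost's
exact attribution for boosting, sampling-based Shapley for SVM/LR), global
mean-|SHAP| rankings with favourable/unfavourable direction calls, per-gene
explanations, and exact pairwise interaction values for tree models.

**Motif linking and screening.** Salient k-mers become PWMs, export to MEME
minimal format, and match against motif databases with a Tomtom-style
correlation comparator. Genome-wide score tables combine with expression
fold changes into a high-confidence rule (sequence score ≥ 0.6, fold change
≥ 2 in ≥ 2 datasets, chromatin score ≥ 0.6 additionally for mouse).

**Synthetic data.** A generator produces coupled genome/annotation/
expression/ChIP fixtures with *planted* structure — enriched k-mers in
positive flanks, class-specific chromatin bumps, rule-consistent expression
— so the whole pipeline validates end to end without downloads.

## Worked example

```r
library(zgakit)

study <- run_sequence_study(n_genes = 400, seed = 1,
                            enrich_pos = 8, enrich_neg = 1, k = 6)
study$eval$auc
#> [1] 1
study$selected
#> [1] "ATTAAT" "TATATA" "ATATAT" "ATATAC"
head(study$attribution, 3)
#>   feature mean_abs_shap rank  direction direction_stat
#> 1  ATTAAT    0.26567396    1 favourable      0.8980027
#> 2  TATATA    0.19686208    2 favourable      0.8997985
#> 3  ATATAT    0.02268954    3 favourable      0.8426066
```

The study plants two TA-rich 6-mers (Poisson mean 8 copies per ZGA flank
pair vs 1 per non-ZGA), simulates staged expression that the ratio caller
resolves back to the truth labels (`study$call_accuracy` is 1), and trains a
tuned random forest on MIC-selected k-mer frequencies. Here the held-out
AUC is 1, selection kept the planted k-mers (plus two overlap-correlated
neighbours), and the planted words are the top-ranked favourable
predictors — high frequency pushes a gene toward the ZGA class.

The chromatin counterpart:

```r
epi <- run_epigenome_study(n_genes = 200, seed = 1)
epi$eval$auc
#> [1] 1
subset(epi$attribution, feature %in% c("H3K9ac_10", "H3K27me3_10"))
#>        feature mean_abs_shap rank    direction direction_stat
#> 1    H3K9ac_10    0.06472994    1   favourable      0.9925289
#> 13 H3K27me3_10    0.01500000   13 unfavourable     -0.9888043
```

Active-mark bins near the TSS come out favourable, the repressive
H3K27me3 near-TSS bin unfavourable — the planted regulatory syntax.

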