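---
title: "Selecting predictive and generalizable genes for multi-drug response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting predictive and generalizable genes for multi-drug response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxen)
```

## The problem

General anti-cancer drug response prediction models are trained on the
screening results of many drugs against panels of cancer cell lines (CCLs):
each training example pairs a CCL's gene expression profile with a drug's
molecular descriptors, and the target is the normalized area under that
(CCL, drug) dose-response curve. Transcriptomes carry ~20,000 genes, far
more than such panels can support, so a gene selection step is essential.

Co-expression extrapolation (COXEN) selects genes that are (i) predictive of
drug response in the dataset where responses are known ("dataset 1") and
(ii) *generalizable*, meaning each gene's co-expression pattern with the
other predictive genes is preserved in the dataset whose responses are to be
predicted ("dataset 2"). Preserved co-expression is read as evidence that
the transcriptional regulation surrounding the gene operates the same way in
the new cancer cases, so a model built on that gene is more likely to
transfer.

The classic COXEN selector is single-drug. This package implements a
multi-drug generalization together with the original selector, the
dose-response AUC preparation, and the evaluation machinery needed to
compare selectors fairly.

## The selectors

Both selectors take two expression matrices over a shared gene universe, a
long-format response table on dataset-1 CCLs, and two integers
N1 > N2 > 1.

**Step 1 — predictive candidates.** The prediction power measure (PPM) of a
gene for a drug is the absolute Pearson correlation between the gene's
expression and the AUC values of the CCLs treated by that drug
(`predictionPower`). The *enhanced* path ranks all genes per drug
(`rankGenesForDrug`) and pools the union of per-drug top-l lists: l starts
at ceiling(N1/D) for D drugs and grows by one until the union holds at
least N1 genes (`buildCandidatePoolEnhanced`). The resulting pool of L >= N1
genes contains genes predictive for *some* drug rather than genes correlated
with the overall drug-to-drug response differences. The *original* path
ignores the drug difference: expression rows are replicated once per
experiment, correlated against the pooled AUC vector, and the top N1 genes
form the pool (`buildCandidatePoolOriginal`). This replication reading is
the only one under which a single PPM per gene exists across multiple
drugs; whether per-drug standardization of AUC should precede pooling is
not settled, and the package pools raw AUC values.

**Step 2 — generalization scores.** For each pool gene, its vector of
Pearson correlations with the other L-1 pool genes is computed in each
dataset (`coexpressionVector`); the generalization score is the agreement
between the two vectors (`generalizationScores`). Scoring operates on the
full L-gene pool, not an N1-gene trim, since the pool as a whole is the
candidate set. The enhanced selector measures agreement with Lin's
concordance correlation coefficient,

$$\mathrm{CCC}(c_1, c_2) =
  \frac{2\,\mathrm{cov}(c_1, c_2)}
       {\mathrm{var}(c_1) + \mathrm{var}(c_2) + (\bar c_1 - \bar c_2)^2},$$

with population (divide-by-n) moments, Lin's original convention; Pearson
correlation is scale-free, so the convention only affects the mean-difference
penalty. CCC penalizes any deviation of the point cloud from the identity
line, so it demands that correlations be *reproduced*, not merely linearly
related; it equals 1 only for identical vectors and never exceeds the
Pearson correlation in magnitude. The original selector uses plain Pearson
agreement.

**Step 3 — selection.** The N2 pool genes with the highest generalization
scores are returned (`selectGenes`).

With a single drug and Pearson agreement the two paths coincide, which the
test suite verifies.

### Numerical conventions

Correlations of constant vectors are undefined; the package maps every such
degenerate case to 0 (and CCC of two equal constant vectors to 1), keeping
rankings total. Identical vectors score exactly 1, avoiding floating-point
round-off in the ubiquitous "dataset 2 equals dataset 1" identity case. All
ties — in PPM rankings, at the pool cutoff, among generalization scores —
break by stable first-appearance order, so a run is reproducible across
platforms. The same-seed, same-input determinism of the full pipeline is
tested.

## Dose-response preparation

Raw screens report relative tumor cell growth at several doses. The package
fits the three-parameter Hill (sigmoid) model with the upper asymptote fixed
at 1 (untreated control growth):

$$g(d) = E_\infty + \frac{1 - E_\infty}
  {1 + 10^{\,h\,(\log_{10} d - \log_{10}\mathrm{EC}_{50})}}.$$

Fitting is bounded Levenberg-Marquardt least squares from a deterministic
3 x 3 x 3 multi-start grid over $E_\infty \in [-0.5, 1.1]$,
$\log_{10}\mathrm{EC}_{50} \in [-12, -2]$, $h \in [0.05, 10]$; the start
with the lowest residual sum of squares wins, and a flat-curve fallback (with
a warning) covers total optimizer failure. On noiseless curves sampled at 8
doses the fit recovers parameters to ~1e-12.

The prediction target is the AUC of the clipped curve over
$\log_{10} d \in [-10, -4]$ (molar), normalized by the 6-decade range:
0 is complete response, 1 is no response. Integration uses the log-dose
scale — a "dose range" spanning six decades is only meaningful
logarithmically, and this matches common practice for [0, 1]-normalized
screening AUCs — with curve values clipped to [0, 1] first so the bounds
hold even for fits with $E_\infty < 0$. A fixed 1001-point trapezoidal grid
makes the value deterministic; doubling the grid moves it by < 1e-6 for
$h \le 10$. Both the integration scale and the clipping are deliberate
choices where screening pipelines differ, and both are configurable at the
call site.

Expression values are never transformed by the package; the analysis scale
(raw or log) is the caller's choice. The low-expression filter takes an
explicit keep-count (or quantile) rather than a threshold, reproducing
"drop the smallest average expression" deterministically.

## Evaluating selectors

Because drugs differ far more in mean response than CCLs do, overall R^2 of
a multi-drug model mostly reflects the drug descriptors. Two tools expose
what gene selection itself contributes:

* **Variance decomposition** (`variationDecomposition`): the total sum of
  squares of AUC values splits exactly into between-class and within-class
  parts, with drugs or CCLs as classes; the ratio of the two between-class
  components (`betweenClassRatio`) quantifies drug dominance. Published
  summaries of the three large public screens (CCLE, GCSI, GDSC) give
  ratios of 8.78, 5.48 and 8.96, the regime the synthetic generator mimics.
* **PIP** (`performanceImprovement`): the gain of the enhanced selector over
  a baseline selector, as a percentage of the baseline's own gain over a
  descriptors-only model — the improvement relative to the baseline's "pure"
  expression contribution. PIP is meaningful only when the baseline clearly
  beats the descriptors-only model; a near-zero denominator makes the ratio
  ill-conditioned, which is why the synthetic benchmark reports the plain
  R^2 gap alongside.

`makeCVPlan` builds the repeated cross-validation layout: per repeat, CCLs
(not experiments) are shuffled and dealt into folds, so folds never share a
CCL and every experiment travels with its cell line — the setting that
simulates predicting response for *new* cancer cases. Each fold tests once
per repeat; the validation fold is the next fold cyclically (an arbitrary
but deterministic rotation, since only "one fold validates, one tests" is
structurally required). `runBenchmark` then runs each trial with the
training folds as dataset 1 and the validation + test folds combined as
dataset 2, trains the regressor on concatenated selected-gene expressions
and drug descriptors with early stopping on the validation fold, and scores
R^2 on the test experiments. Arms include the enhanced and original
selectors, fresh per-trial random gene draws (from all genes or from a
provided landmark-style list), a fixed gene list, and always a
descriptors-only reference. A trial in which any arm fails is excluded with
a warning; more than 10% failures aborts, so a report can never silently
rest on a biased subset of trials. Paired two-sided t-tests with
Benjamini-Hochberg correction (`pairedTTestsBH`) compare the enhanced arm
against each baseline; the correction family is the comparison set of one
report, the narrowest defensible choice.

The regressor is pluggable. The default is gradient-boosted trees
(`xgboostRegressor`, squared-error objective, 1500 rounds with patience 150
by default; a large-data profile would raise both). Boosting internals are
not part of any contract — the selectors, not the regressor, are under
study — and a fast linear baseline (`linearRegressor`) is provided for
plumbing tests.

## The synthetic benchmark

`generateSyntheticDataset` builds everything the selectors assume, with
known ground truth:

* **Co-expression** comes from latent-factor modules: each module has one
  standard-normal factor per CCL, gene loadings are uniform on [0.5, 1], and
  idiosyncratic noise scales genes to unit variance. Dataset 2 draws new
  factor values (its samples differ) but keeps the loadings of a
  `preservedFraction` of modules; the other modules' genes are regenerated
  independently, destroying exactly the structure that Step 2 rewards.
* **Responses**: per drug, AUC = clip to [0, 1] of
  (drug mean + effectSize x weighted mean of the drug's planted genes +
  noise). Planted sets share a controllable fraction of genes across drugs;
  weights are uniform on [0.5, 1].
* **Descriptors** carry the drug mean in one column (drug identity is
  recoverable, as Dragon-style descriptors make it in real data) plus
  standard-normal noise columns.

Defaults — 500 genes in 25 modules, 200 + 100 CCLs, 5 drugs with 20 planted
genes each (25% shared), 60% of modules preserved, effect size 0.25, noise
0.05, drug-mean spread 0.15 — were fixed once from variance bookkeeping:
the within-drug signal-to-noise matches what expression plausibly explains
in CCL panels, and the drug-mean spread was calibrated so the
drug-dominance ratio of the demo seed falls inside the published 5-9 band
(about 6.3 at seed 42), which a regression test freezes. One master seed
expands into per-stage substreams (structure, expression 1, expression 2,
responses, descriptors), so the generator is bit-reproducible and stages
are independently reproducible.

What the generator does *not* emulate: real CCL covariance (single-factor
blocks are far simpler), dose-level measurement error, missing (CCL, drug)
pairs, or expression batch effects. Passing tests therefore demonstrate the
algorithmic properties of the selectors — recovery of planted,
structure-preserved signal under drug-dominated response variation — not
performance on any real screen.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use desk-scale instances chosen
to exercise every code path at comfortable margins: 1000 random vector
pairs for the concordance-correlation oracle, 200 random instances (up to
50 genes, 6 drugs) for the union-depth exhaustive check, 1000 fuzz cases
for the variance-decomposition identity, 100 noiseless curves for Hill
recovery, 20 replicate synthetic datasets for planted-gene recovery, and a
2 x 5-fold benchmark with a 300/30 boosting schedule matched to the
synthetic problem size.

## Known limitations

* PPM ships as absolute Pearson only; the interface admits other measures
  but none are implemented.
* Per-drug PPM uses exactly the CCLs with a recorded response for that drug;
  there is no treatment of missing-at-random response patterns.
* The original-path pooled correlation is sensitive to between-drug AUC
  offsets by design (that is the phenomenon it illustrates); no per-drug
  standardization option is currently exposed.
* Generalization scores of two-gene pools are degenerate (length-1
  co-expression vectors) and map to 0 with a warning rather than a value.
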