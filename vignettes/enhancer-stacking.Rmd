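---
title: "Stacked enhancer prediction: methods and design notes"
author: "enhancerStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked enhancer prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enhancers are distal cis-regulatory elements: tissue-specific, often tens of
kilobases from the genes they activate, and marked by characteristic histone
modifications (H3K4me1, H3K27ac) rather than by sequence conservation.
Genome-wide they are rare — on the order of 2% of 200-bp windows — so the
prediction task is a heavily imbalanced binary classification over a tiling
of the genome, with ChIP-seq peak signal (or DNA k-mer composition) as
features and EP300 binding sites or CAGE-defined enhancer catalogues as
proxy labels.

Single classifiers trained on one tissue generalize poorly to others,
because the association between any one proxy label and true enhancer
activity varies across tissues. `enhancerStack` therefore implements a
*stacked* (hybrid) design: one random-forest base classifier per training
tissue, whose soft outputs are combined by an RBF-kernel SVM
meta-classifier that makes the final call.

## The model

**Windows.** Every chromosome is tiled from position 0 into consecutive
fixed-width bins (default 200 bp, the resolution of the preprocessed
histone data this design targets). A chromosome tail shorter than the width
is kept as a truncated final bin — dropping it would silently discard
labels at chromosome ends. All internal coordinates are BED-convention
0-based half-open at the file boundary and `GRanges` 1-based in memory.

**Features.** For each mark, a window's raw feature is the maximum
`signalValue` of the peaks overlapping it by at least 1 bp (0 when none).
Maximum rather than sum or mean because peak signal is an enrichment
statistic: the strongest overlapping call is the least sensitive to how a
peak caller fragments a region. Sum, mean and per-window peak *count* are
available as alternative aggregations (`mapSignal(aggregate=)`), the count
mode reflecting the other reading of data preprocessed by counting peaks
per window. Each feature column is min-max normalized,

$$x_i' = \frac{x_i - x_{\min}}{x_{\max} - x_{\min}},$$

fitted **on the 60% training portion only** and applied to held-out and
test data with clipping into [0,1], so no test information leaks into the
scaling. A constant column (x_max = x_min) maps to zeros: the formula is
undefined there, and a constant feature carries no information either way.

**Labels.** A window is an enhancer when a single label interval (EP300
peak, CAGE enhancer call) covers at least 50% of the window's own width
(configurable). The 50% rule is a deliberate middle ground: 1-bp touching
would label windows only grazed by a label, full containment would drop
every label straddling a window boundary. Truncated end-of-chromosome
windows are judged against their own shorter width.

**Class-imbalance reduction.** With ~2% positives, training on the raw
tiling makes any learner collapse onto the majority class. All positives
are kept and negatives are sub-sampled to a 1:10 positive:negative ratio —
but not uniformly: negatives are first k-means-clustered (default k = 8,
5 seeded restarts, lowest within-cluster sum of squares kept) on their
normalized features, and the draw is allocated to clusters proportionally
to cluster size with largest-remainder rounding, uniform within a cluster.
This preserves the feature diversity of the negative class — the stated
motivation for combining sub-sampling with clustering — instead of letting
the sample concentrate in the densest background mode. Clustering runs on
normalized features (the scale-free choice; the alternative is not
meaningfully defined when marks live on different signal scales).

**Base classifiers.** One random forest per tissue, trained on a
stratified 60/40 split of the balanced dataset. The forest is the classic
ensemble: bootstrap resamples, trees grown with binary threshold splits
chosen over a random feature subset per node. The information-gain
primitives the tree criterion is built on,

$$\mathrm{info}(D) = -\sum_i p_i \log_2 p_i, \qquad
  \mathrm{gain}(A) = \mathrm{info}(D) - \mathrm{info}_A(D),$$

are exposed and tested as `entropyBits()` / `infoGain()`. Forest fitting
itself is delegated to the `randomForest` package (Breiman's reference
implementation); the package's own contribution is the ensemble's soft
output, the **confidence score**
$$\mathrm{confidence} = \frac{\#\text{trees voting enhancer}}{\#\text{trees}},$$
which `confidenceScores()` guarantees to be exactly the tree-vote fraction
(the test suite re-derives it by enumerating the stored trees). Defaults
are the standard ones: 100 trees, ⌈√p⌉ candidate features per split,
unlimited depth, minimum split size 2 — surfaced in `forestConfig()`
because the published design used library defaults rather than tuned
values. The 60/40 split is stratified; an unstratified split risks
fold-to-fold prevalence drift at these positive counts.

**Meta-features and the main classifier.** Each base model's held-out 40%
yields an F-score at cut-off 0.5; the meta-feature of window *i* under
base *j* is

$$m_{ij} = \mathrm{confidence}_j(i) \times F_j,$$

so a weak base classifier's votes are attenuated. The meta-classifier is
trained on the *pooled* held-out windows of all tissues, and every base
model scores every pooled window — the only construction that yields a
complete matrix (scoring only one's own tissue would leave the rest of the
column undefined). An undefined held-out F-score (no predicted positives)
is stored as 0 so the meta-column stays defined; the full report keeps the
`NA`.

The main classifier is a soft-margin SVM with the RBF kernel
$k(x,x') = \exp(-\gamma\|x-x'\|^2)$, solved by libsvm via `e1071` at
tolerance 1e-3 with uniform class weights (imbalance is already handled
upstream). (C, γ) are chosen by exhaustive grid search under seeded
stratified 10-fold cross-validation, minimizing the balanced error rate

$$\mathrm{BER} = 1 - \tfrac{1}{2}(\mathrm{sensitivity} + \mathrm{specificity}),$$

the natural criterion under residual imbalance (accuracy would reward the
all-negative predictor). Default grids are C ∈ {2, 4, …, 50} and
γ ∈ {2, 4, …, 200}. The conventional printed grids for this design start
at 0, but C = 0 removes the misclassification penalty and γ = 0 collapses
the kernel to a constant — both degenerate — so the grids here start at 2.
Ties in CV BER break toward the smallest C, then the smallest γ: the least
complex model, deterministically. Prediction applies the decision function
sgn(wᵀφ(x) + b); decision values are returned as ranking scores for ROC
analysis, oriented so that label 1 ⇔ score > 0.

**Evaluation.** `confusionCounts()` / `classifierMetrics()` implement the
six headline metrics (precision, recall, specificity, sensitivity,
F-score, accuracy). Accuracy is (TP+TN)/(TP+TN+FP+FN), the standard
definition. A metric with a zero denominator is reported as `NA`
("undefined"), not an error, and the F-score inherits undefinedness from
precision/recall. `rocCurve()` sweeps the cut-off over all distinct scores
(ties collapse into a single step) and integrates AUC by the trapezoidal
rule; with this tie handling the trapezoidal AUC coincides with the
Mann–Whitney pairwise statistic, which the tests verify to 1e-12. The
default headline cut-off on confidence/decision scores is 0.5,
configurable — no single published value exists.

## Tunable parameters

| Parameter | Default | Where | Why this default |
|---|---|---|---|
| window width | 200 bp | `makeWindows()` | resolution of the preprocessed histone data; widths 400–1000 appear upstream, so it is a parameter, not a constant |
| label overlap | 0.5 of window | `labelWindows()` | symmetric middle ground (see above) |
| aggregation | max signal | `mapSignal()` | scale-stable for enrichment statistics |
| ratio | 10 neg/pos | `samplingConfig()` | the published 1:10 balance |
| k (k-means) | 8 | `samplingConfig()` | unpublished; small enough to be stable at a few thousand negatives, large enough to span background modes |
| trees | 100 | `forestConfig()` | library default the design relied on |
| C, γ grids | {2..50}, {2..200} step 2 | `svmConfig()` | published grids minus the degenerate 0 |
| CV folds | 10 | `svmConfig()` | published procedure |
| cut-off | 0.5 | evaluation | unpublished; the neutral choice on a [0,1] score |

## The synthetic-data generator

`synthSpec()` / `simulateExperiment()` emit valid broadPeak, BED, FASTA
and chrom.sizes files (plus a window-level truth table) with the
statistical structure the classifier assumes:

* ~2% of windows are enhancers (`enhancerFraction = 0.02`), drawn from a
  pool shared across tissues plus tissue-specific pools
  (`sharedEnhancerFraction`, default 0.5) — the tissue-specificity dial.
* Every mark emits background peaks at rate 0.15 per window with
  lognormal signal (lognormal because enrichment statistics are positive
  and right-skewed). A mark with enrichment effect *e* additionally peaks
  over enhancer windows with probability 1 − (1 − rate)·e^(−e) and signal
  meanlog shifted by log(1+e). At *e* = 0 positives are *exactly*
  exchangeable with background, so the null regime (AUC ≈ 0.5) is
  reachable by construction and calibrates the whole pipeline.
* Enriched peaks coincide with the enhancer window's footprint, because
  the emulated upstream data is already binned at window resolution;
  letting enrichment bleed onto windows the truth table calls negative
  would make the ground truth itself inconsistent at the stated
  resolution. Background peaks keep the configured width distribution
  (default 200–1000 bp).
* The default mark panel is two strong enhancer-associated marks
  (H3K4me1, H3K27ac analogues, effect 3), one weaker promoter-associated
  mark (effect 1.5) and one uninformative repressive mark (effect 0).
  A per-tissue effect matrix (`effects=`) supports complementary-marks
  designs in which each tissue's information lives in a different mark.
* `simulateSequences()` produces uniform ACGT background with a
  tetranucleotide motif planted in enhancer windows, making k-mer
  features informative for the DNA-sequence feature mode.

What the generator does **not** emulate: read-level noise and peak-caller
artifacts, correlated mark co-occurrence, sequence composition biases
(GC/CpG structure), replication timing, or any real genome's coordinates.
Passing tests on this generator therefore demonstrate that the pipeline's
machinery is correct and well-calibrated — not that a given biological
accuracy will be attained on real ENCODE/Roadmap/FANTOM5 data, where label
noise and cross-tissue heterogeneity dominate.

## Problem sizes and numerical choices

The test-suite and acceptance fixtures use 0.3–10 Mb synthetic genomes
(1,500–50,000 windows), 2–6 tissues, and a reduced 3×3 (C, γ) grid — sizes
chosen so each statistical check runs in seconds while keeping ≥30
positives per tissue, enough for the binomial checks to have power. The
full default grid (25 × 100 pairs × 10 folds) is a production setting.

Numerical details worth knowing:

* Stratified splits and folds are seeded; all pipeline randomness derives
  from one top-level seed, and every seeded routine restores the caller's
  RNG state.
* k-means initial centers are drawn from the *unique* negative rows
  (duplicate rows would make the initializer degenerate); an empty-cluster
  quota is impossible under largest-remainder allocation capped by cluster
  size.
* Equal-gain splits inside `randomForest` follow that library's own
  deterministic tie-breaking under a fixed seed.
* `predictMeta()` re-orients libsvm's decision values (whose sign follows
  the order classes appear in training data) so that positive always means
  enhancer; the dual-form expansion Σ αᵢyᵢ k(xᵢ,x) + b is verified in the
  tests.
* Degenerate inputs fail loudly and early: single-class datasets, fewer
  than two tissues, mismatched feature columns, windows sets that do not
  coincide at evaluation, malformed interval lines (reported with their
  line number).

## Limitations

* The stacking advantage is a property of complementary base classifiers;
  when one tissue dominates the signal, the meta-classifier can only match
  its best base, not beat it.
* The meta-classifier sees only regions of meta-feature space populated by
  the pooled held-out windows; a test tissue whose base-confidence profile
  is qualitatively unlike every training tissue (e.g. all bases
  simultaneously confident where training positives excited exactly one)
  is extrapolation, and RBF decision values decay toward the bias there.
* Peak calling, read processing and cross-assembly liftover are out of
  scope: inputs are peak-level broadPeak/BED on one assembly.
* Probability calibration of the SVM decision values (Platt scaling) is
  not implemented; scores are rankings, not probabilities.
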