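---
title: "Median-supplement balancing for imbalanced binary classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-supplement balancing for imbalanced binary classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediansupp)
```

## The problem

Binary classification tables in biomedicine are rarely balanced. In a
receptor-status study the positive phenotype may account for a seventh of the
samples; in a protein-localization table one compartment dominates. A
classifier fitted to such data absorbs the imbalance: the naive Bayes prior
P(C_j) is the empirical class frequency, and a random forest's leaves and
votes are populated mostly by majority-class instances. The practical symptom
is low minority-class sensitivity — precisely the class one usually cares
about.

## The median-supplement procedure

`balance()` equalizes the class counts by augmenting the training table with
synthetic instances derived from attribute medians:

1. **Medians.** For each attribute j, compute the median over the training
   instances (by default over *all* instances; see "Median scope" below).
2. **Supplement.** Draw an m × n matrix U of i.i.d. uniform random numbers on
   [0, 1), where m is the difference between the two class counts and n the
   number of attributes, and set S[i, j] = median_j · U[i, j]. Every
   synthetic value therefore lies between 0 and its attribute median
   (sign-aware when a median is negative).
3. **Append.** S is appended to the original table, labeled with the
   *minority* class, giving equal class counts. Original rows are preserved
   unmodified and in order; synthetic rows carry an `is_synthetic` flag so
   they can always be audited or removed.
4. **Model.** The classifier is fitted to the balanced table.

The minority label on the supplement is forced by the purpose of the
procedure: only that choice yields equal counts. The supplement is a pure
function of (medians, m, seed); two runs with the same seed are
bit-identical.

The procedure implies a geometric assumption worth stating plainly: the
supplement occupies the box [0, median_j] per attribute, so it reinforces the
minority class only where the minority class actually lives in the
low-intensity region below the attribute medians. For data where the minority
class sits *above* the medians, the supplement would populate foreign
territory and harm the fit. The fixture generator (below) and the direction
tests respect this premise.

### Median scope

The default computes medians over all instances, the literal reading of the
procedure. Because majority instances dominate the pooled median, the
supplement then reaches up to majority-typical values. A `median_scope =
"minority"` option computes medians over minority instances only, confining
the supplement to the minority's own range. Both are tested; the default is
the literal behaviour.

## Classifier backends

**Gaussian naive Bayes** (`fit_nb()`). The posterior for class C_j given
attribute vector g is P(C_j | g) ∝ P(C_j) ∏ᵢ P(gᵢ | C_j), with the evidence
term omitted as class-constant. Class-conditional densities are univariate
Gaussians — the standard convention for continuous attributes; the location
is the sample mean and the scale the unbiased (n−1) standard deviation.
Scales are floored at `variance_floor` (default `1e-9 · (var(all values) +
1)`) so constant attributes yield finite densities instead of errors. All
computation is in log space with log-sum-exp normalization; posterior rows
sum to 1 within 1e-12. Exact posterior ties resolve to the lexicographically
first class level, making predictions deterministic.

**Random forest** (`fit_forest()`). B trees (default 500) are grown on
bootstrap resamples (same size as the table, drawn with replacement). At each
node, `mtry` candidate attributes are drawn without replacement — default
⌊√n⌋, the standard choice for classification forests — and the
(attribute, threshold) pair minimizing the weighted Gini impurity of the two
children is selected. Thresholds are midpoints between consecutive distinct
sorted values; impurity ties break to the lowest attribute index, then the
lowest threshold. Nodes stop splitting when pure, at or below
`min_node_size` (default 1), or unsplittable (all candidate attributes
constant); leaves carry their majority class, ties to the first level.
Prediction is by majority vote across trees, vote ties again to the first
level. With B = 1, no bootstrap and mtry = n the forest reproduces the
single deterministic tree exactly — a degenerate-equivalence property the
test suite exercises. The tree grower is implemented in C++ (via Rcpp) and
uses R's own RNG stream, so forests are a pure function of
(data, hyperparameters, seed).

## Evaluation protocol

- **Classification rate** (`classification_rate()`): correctly classified
  test instances over total test instances — the single performance measure.
- **Confusion matrix** (`confusion_matrix()`): predicted classes in rows,
  truth in columns. `class_sensitivity()` reads per-class sensitivity off it.
- **Independent test** (`independent_test()`): balancing (for MS methods) is
  applied to the training table only; the test set is never touched.
- **Cross-validation** (`kfold_cv()`): folds are *stratified* by class —
  with 14 minority instances in 10 folds, unstratified assignment can
  produce minority-free folds — and balancing happens inside each training
  split, never before splitting, so synthetic instances cannot leak into
  held-out folds. The returned `details` table records per-fold synthetic
  counts for auditing. One rate per held-out fold; repeats (default 10) use
  derived seeds, giving k · repeats rates.
- **Mann–Whitney U** (`mann_whitney()`): two-sided comparison of two rate
  samples; exact rank-enumeration p-value when the smaller sample has ≤ 8
  observations and there are no ties, otherwise the normal approximation
  with tie and continuity corrections. The exact branch is verified in the
  tests against full enumeration of all rank assignments up to 6 × 6.

## The synthetic-data generator

Real deposited datasets are external downloads, so the package carries
generators that emulate their shape:

- `her2_like_pair()`: a 100-instance training table (86 "Negative" / 14
  "Positive") and a 62-instance test table (51 / 11), mirroring a
  receptor-status study. Five expression-like features; majority means drawn
  from U(50, 500); minority means at a U(0.2, 0.4) fraction of them;
  within-class sd 0.65 × the majority mean; values truncated below at 0.
- `subcellular_like()`: 2635 instances × 126 percentage-like features, split
  1589 "plasma-membrane" / 1046 "nucleus", with mild separation.
- `simulate_table()` / `fixture_spec()`: the general form.

The HER2-like parameters were calibrated against two anchors from the
application domain rather than convenience: (a) plain classifiers should
score in the high-80s-to-low-90s percent range, the scale reported for real
receptor-status panels — with many independent informative features the task
becomes near-separable, the class prior stops mattering, and balancing has
nothing to correct; and (b) the minority class must occupy the low-intensity
region below the pooled attribute medians, the geometric premise of the
supplement. At five features with this overlap, the imbalance visibly costs
minority sensitivity and median-supplement naive Bayes recovers part of it,
while the two forest variants score within a few points of each other —
the qualitative pattern expected of the method.

What the generator does *not* emulate: correlation between attributes
(real expression data is heavily co-expressed; features here are drawn
independently), heavy tails, batch structure, or measurement noise models.
Passing tests on these fixtures therefore demonstrate the mechanics and the
direction of the balancing effect, not performance on any real dataset.

## Numerical and design choices

- Class levels are ordered lexicographically everywhere; all tie-breaks
  (posterior ties, vote ties, leaf majorities, minority-class selection when
  counts are equal) resolve to the first level, for determinism.
- Even-count medians are the arithmetic mean of the two middle order
  statistics (`stats::median`).
- Uniform draws are on the half-open interval [0, 1).
- One supplement is generated per model fit (not per tree).
- Missing values are a hard error, not imputed; non-numeric attribute
  columns are unsupported and rejected with the offending column named.
- Table values are serialized with 17 significant digits (`%.17g`), so
  write/read round-trips — including forest serialization — are bit-exact.
- Cross-validation problem sizes used by the tests and the acceptance script
  (30 fixture draws for the independent-test protocol; 10-fold × 10-repeat
  CV) were chosen as the smallest sizes at which the rate distributions are
  stable enough to compare.

## Limitations

- Binary classification only; more than two classes is an error at train
  time.
- The supplement assumes non-negative, low-region minority data; it is
  applied verbatim (between 0 and the median) even when medians are
  negative, but the geometric rationale weakens there.
- No probability calibration, ROC/AUC, variable importance, or out-of-bag
  error; the evaluation protocol is deliberately limited to classification
  rate and its comparisons.
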