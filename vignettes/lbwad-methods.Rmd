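---
title: "Low-birth-weight screening as nested one-class anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-birth-weight screening as nested one-class anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low birth weight is defined by the WHO thresholds <2500 g (LBW), <1500 g
(very low, VLBW) and <1000 g (extreme, ELBW). The three classes are nested
and increasingly rare — at study scale roughly 11.6%, 1.3% and 0.5% of
pregnancies. Supervised classifiers handle this imbalance by oversampling or
undersampling, which either distorts the decision boundary or discards
information. `lbwad` instead treats each threshold as a *one-class* problem:
an anomaly detector is fitted exclusively on pregnancies labelled normal for
that threshold and ranks held-out pregnancies by an anomaly score
$S(x) = \phi(x)$, where higher means more deviant from the normal class.
Detection quality is read off the ranking (AUCROC, AUCPR), never from a
hard decision threshold.

## Preprocessing pipeline

Input is one row per pregnancy: mixed numeric / Yes-No / categorical
first-trimester features plus a `weight` outcome column in grams.

1. **Stratification.** `lbw = weight < 2500`, `vlbw = weight < 1500`,
   `elbw = weight < 1000`, all strict inequalities, computed on the full
   sample so the label vectors are nested. Rows with missing or non-positive
   weight are dropped and counted.
2. **Imputation.** Numeric columns by the observed mean; binary and
   categorical columns by the observed mode, ties broken by the
   lexicographically smallest value so replay is deterministic.
3. **Encoding.** Yes/No to 1/0; categoricals to a full set of k indicator
   columns in lexicographic level order (no dropped level — attribution
   later perturbs a feature's whole indicator block, which requires all
   levels to be present).
4. **Scaling.** Min-max to [0, 1] per encoded column; constant columns map
   to 0; values outside the fitted range at apply time are clipped into
   [0, 1].

The transform is fitted once on the full cohort by default (`mode =
"global"`), which is the conventional pipeline but lets test-fold statistics
leak into the imputation values and scaling ranges. `mode = "fold-safe"`
refits the transform per fold on the training-fold *normal* rows only; the
clipping rule exists so fold-safe scaling still lands in [0, 1]. Both modes
are first-class; the default favours comparability with common practice,
and a unit test verifies the fold-safe mode ignores values planted outside
the training rows.

## Detectors

Six scorers are implemented natively behind one contract (`ad_spec()`,
`ad_fit()`, `ad_score()`; higher = more anomalous; deterministic under the
spec seed):

* **iforest** — isolation forest, 100 trees, subsample $\psi = 256$ (capped
  at n), height limit $\lceil \log_2 \psi \rceil$. Split feature uniform
  among columns that still vary; split point uniform in (min, max). Path
  length $h(x,T)$ = edges traversed + $c(\text{leaf size})$, with
  $c(m) = 2H(m-1) - 2(m-1)/m$ evaluated from the exact harmonic sum
  ($c(1) = 0$, $c(2) = 1$); score $2^{-\bar h(x)/c(\psi)}$.
* **hbos** — per-feature equal-width histograms, $\lceil\sqrt n\rceil$ bins
  over the training range; score $\sum_j -\log(\max(\text{bin mass}, 0.1/n))$.
  Queries outside the range are treated as empty-bin hits.
* **ecod** — per-feature two-sided empirical tail
  $\min(P(X \le x), P(X \ge x))$ floored at $1/(n+1)$, aggregated as
  $\sum_j -\log(\text{tail})$. The original method's skewness-based side
  selection is deliberately simplified to the symmetric min-tail rule.
* **knn** — Euclidean distance to the k-th nearest training row, k = 5;
  tie-stable and computed row-by-row so batched and single scoring agree
  bitwise.
* **gmm** — negative log-likelihood under a Gaussian mixture; one component
  (closed form) by default, EM with k-means initialisation and a 1e-6
  diagonal ridge for k > 1.
* **pca** — squared reconstruction error after projecting the centred query
  onto the fewest principal components explaining 90% of training variance.

Everything else from the wider detector families (OCSVM, LOF, LODA, SOS,
SUOD, ABOD, CBLOF, KDE, ...) enters through `register_adapter()`: an
arbitrary fit/score pair plus an *explicit* orientation declaration;
inverted ("higher = more normal") conventions are negated so the contract
holds uniformly. Registration without an orientation is refused, and
duplicate names are an error.

## Evaluation protocol

`make_folds()` builds a 2x5 repeated stratified partition: positives are
shuffled and dealt round-robin so every test fold holds at least one
positive (hence a hard error when a category has fewer positives than
folds). Per repeat x fold, detectors are fitted on the *normal rows of the
training folds* and score *every* row of the held-out fold; AUCROC
(Mann-Whitney form, ties credited 0.5, computed from average ranks) and
AUCPR (average precision — the mean of precision at each positive's rank
under a stable descending sort; chance level equals the prevalence) are
recorded and averaged over the 10 folds. Average precision is used rather
than trapezoidal PR interpolation, which is biased for rare positives.

Cross-detector comparison uses a one-way ANOVA F-test per category and
metric: groups are each detector's 10 fold-level values. The statistic is
computed from the between/within sums of squares directly (and cross-checked
against `stats::oneway.test` in the tests); the degenerate all-equal case is
defined as F = 0, p = 1.

## Attribution

Two per-instance methods explain a fitted scorer:

* **Mean-substitution perturbation** (model-agnostic): for source feature i,
  replace its encoded columns by baseline means $\mu_i$, re-score, and report
  $\Delta S_i = S_o - S_{m,i}$. With the higher-is-more-anomalous contract a
  positive $\Delta S_i$ means the observed value *raised* the anomaly score;
  the sign is reported as the formula produces it, and rankings use
  $|\Delta S_i|$ with average-rank ties.
* **Local depth-based importance** (isolation forest only):
  $I_i = \frac{1}{|T|}\sum_T |h(x,T) - h(x_i',T)|$ with the same
  substitution; features unused by every tree get exactly 0.

The baseline defaults to means over the *training-normal* rows — this avoids
test-set leakage; test-set means are available via `provenance = "test-set"`
for compatibility with pipelines that compute them there. Categorical
features are perturbed as a block: all k indicators move to their fractional
baseline means together. This is the literal mean-substitution rule; its
known cost is that the perturbed point leaves the one-hot manifold, which
inflates the apparent importance of categorical features under the
depth-based method at weak signal strengths (trees that split indicator
columns always see a changed coordinate). Rankings aggregated over outlier
points (`average_feature_ranks()`, lower mean rank = more influential)
remain able to separate injected signal features from nuisance features
under the recovery conditions exercised in the tests; substituting the modal
category's exact indicator vector would stay on-manifold and is a reasonable
alternative for heavily categorical data.

Outlier membership for aggregation is by labelled positives by default, or
top-k by score — the choice is explicit because an unsupervised deployment
has no labels.

## Synthetic cohort generator

No compatible public dataset exists, so `generate_cohort()` emulates the
*shape* of a first-trimester cohort: 3509 rows and 22 features by default
(12 numeric, 6 binary, 4 categorical with 3-5 levels, under suggestive
clinical names with simple parametric marginals). Each row draws a latent
standard-normal risk; birth weight is a strictly decreasing piecewise-linear
map of risk whose knots sit at the normal quantiles of the configured
prevalences (0.116 / 0.0128 / 0.0054 by default), so thresholding the weight
reproduces those fractions up to binomial noise and the three labels are
nested *by construction*. Six informative features (default: `bmi`,
`hemoglobin`, `fundal_height`, `papp_a`, `smoking`,
`chronic_hypertension`) are shifted in anomalous rows by `severity` (in
feature standard deviations; default 1.5), scaled 1x / 1.5x / 2x for
LBW-only / VLBW-only / ELBW rows so deeper tiers are more extreme — the
generator-level analogue of detection degrading for less extreme cases.
The other 16 features are pure nuisance, keeping attribution recovery
non-trivial. Missingness is MCAR at rate 0.05 by default (the mechanism
simplest to pair with mean/mode imputation; the rate is a placeholder, not
an estimate of any real cohort), and never touches the weight column.

What the generator does **not** emulate: realistic obstetric marginals or
correlations between features, informative missingness, longitudinal
structure, or measurement error in the outcome. Tests passing on this
generator therefore demonstrate correctness of the machinery and
recoverability of planted signal — not clinical performance.

## Numerical and design choices

* One top-level seed per run; every stage derives its own stream through the
  fixed rule `stage_seed(seed, k) = (seed + 10007 k) mod (2^31 - 1)`, so
  adding a stage never shifts another stage's draws and reruns are
  byte-identical.
* Mode-imputation ties: lexicographic minimum. Score ties in ranking for
  average precision: stable original-index order. kNN distance ties:
  stable sort order.
* Empty histogram bins and out-of-tail queries are handled by the smoothing
  floors above; singular mixture covariances by the diagonal ridge; constant
  columns by the map-to-zero rule.
* Problem sizes in the test suite are the package's own choices: metric
  oracles run at n <= 50 against exhaustive enumeration; attribution
  recovery uses 20 replicate cohorts at the default 3509 x 22 scale;
  the severity-response check uses a 0/1/2/3 grid with 20 seeds at
  n = 1000, averaging AUCROC over all six native detectors.

## Known limitations

* The global preprocessing default leaks test statistics into the transform
  (use `mode = "fold-safe"` when that matters).
* Native ECOD omits skewness-based side selection; native GMM uses full
  covariances with a fixed ridge rather than model selection over
  covariance structures.
* Hyperparameters are exposed but not searched; no tuning loop is provided.
* Attribution signs follow the score contract literally; domain
  interpretation ("protective" vs "risk") requires the reader to keep the
  higher-is-anomalous orientation in mind.
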