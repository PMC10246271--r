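---
title: "Multi-site connectivity neuromarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site connectivity neuromarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmarker)
```

# The problem

Resting-state functional connectivity (FC) — the Fisher z-transformed
Pearson correlation between the time series of every pair of brain
parcels — is a candidate substrate for psychiatric diagnostic markers.
Two obstacles dominate practice: data are pooled across imaging sites
whose scanners imprint additive and multiplicative edge-wise artefacts,
and case/control cohorts are imbalanced. `fcmarker` implements the full
chain from ROI time series to a validated marker: edge bookkeeping,
empirical-Bayes site harmonization, an ensemble of sparse logistic
classifiers, permutation inference, cross-dataset consistency statistics,
network enrichment, and cross-disorder mapping — together with a synthetic
multi-site generator so every stage is testable without clinical data.

# Connectivity construction

A subject's connectome is the vector of
$z_v = \operatorname{atanh}(r_v)$ over all $m = R(R-1)/2$ unordered ROI
pairs, ordered row-major over the strict upper triangle (0-based;
`edge_index()` / `edge_roi_pair()` are the bijection and its inverse). At
the reference parcellation of $R = 379$ regions this gives
$m = 71{,}631$ edges. Correlations are clipped to $|r| \le 1 - 10^{-7}$
before `atanh` so degenerate pairs stay finite.

Stage order for raw time series (`ts_pipeline()`): nuisance regression
(intercept and linear trend are part of the design), band-pass filtering
of the residuals, motion scrubbing, correlation. Filtering precedes
censoring because filtering a gapped series would smear discontinuities
into neighbouring frames. The band-pass is a second-order Butterworth
band-pass (0.008–0.1 Hz) applied forward–backward (zero phase), with
steady-state initial conditions; the testable commitment is the response
contract — at TR = 2 s, a 0.05 Hz sinusoid loses less than 1 dB while
0.2 Hz is attenuated by more than 20 dB — not the realization. Frames
with framewise displacement strictly above 0.5 mm are censored. The
minimum-surviving-frames floor (default 50) is a configurable stand-in:
published exclusion rules vary and the reference protocol's exact floor
is not public.

# Site harmonization

`harmonize()` implements the parametric empirical-Bayes location/scale
model (ComBat),

$$ y_{ijv} = \alpha_v + X_{ij}\beta_v + \gamma_{iv} + \delta_{iv}\,\varepsilon_{ijv}, $$

for site $i$, subject $j$, edge $v$, with diagnosis, age and sex as
protected covariates. Estimation follows the standard three steps:
standardization with site intercepts constrained to a sample-size-weighted
zero sum; normal and inverse-gamma priors across edges with
method-of-moments hyperparameters; iterated conditional posterior means
for $\gamma^*_{iv}, \delta^{*2}_{iv}$ (convergence at max-abs change
$< 10^{-4}$, at most 100 iterations). Adjusted values re-add the
covariate effects unchanged. Choices worth knowing:

* **Parametric EB**, not the nonparametric variant — the conventional
  default; which variant the reference analyses used is not stated, so
  this is recorded as a limitation rather than an inference.
* **Harmonization is strictly per dataset**: discovery and each
  validation cohort are corrected separately, never jointly.
* **Single-site data pass through unchanged** with a warning; a site
  containing only controls is allowed (its diagnosis coefficient is
  identified by the remaining sites) and warned about, matching discovery
  cohorts that include patient-free sites.
* **In-sample limits.** After harmonization of the very data used to
  estimate the site effects, per-edge site-ANOVA F statistics deflate
  toward zero (the estimated means are removed almost exactly; shrinkage
  is negligible at ~150 subjects/site). Residual site signal therefore
  falls to or below chance, but the post-harmonization p-values are *not*
  uniform — they pile up near 1. A calibration check that expects
  KS-uniformity of these in-sample p-values will fail for any faithful
  ComBat; the meaningful check, asserted in the test-suite, is that the
  fraction of edges with site p < 0.05 drops from ~1 to ≤ 0.05.

# The marker ensemble

`train_ensemble()` builds the neuromarker: `n_subsamples` random
undersamples of the majority class to a 1:1 ratio, each split into
`k_folds` stratified outer folds; per outer fold, an inner 5-fold CV over
a 30-value penalty grid (log-spaced over three decades below the smallest
all-zero penalty) selects the LASSO penalty by minimum mean validation
deviance, ties resolved toward the sparser model; one L1-penalized
logistic classifier is fitted per outer fold with per-edge z-scoring
computed inside its own training data. The default 10 × 10 geometry
yields 100 classifiers. The undersampling scheme and the use of
out-of-fold probabilities for discovery-set performance are design
choices: the reference protocol's schematic is not public, and
resubstitution estimates would be optimistic.

A subject's *diagnostic probability* is the mean logistic output over all
classifiers; the label is positive iff it strictly exceeds 0.5 (a subject
at exactly 0.5 counts as control). Performance is summarized by accuracy,
sensitivity, specificity, MCC (defined 0 when a confusion marginal is
empty) and the rank-based AUC with ties counted one half. Fits use
`glmnet` with convergence threshold $10^{-5}$ (rather than $10^{-7}$):
coefficient differences are ~$10^{-4}$ on standardized features,
invisible at ensemble level, and permutation budgets need the speed.

# Permutation inference

Both significance machines shuffle the discovery labels and retrain the
*full* ensemble with the identical configuration at every iteration
(`permutation_engine()`); p-values use the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so $p > 0$ always
and $B \ge 20$ is needed before $p < 0.05$ is attainable.

* **Performance** (`performance_permutation_test()`): AUC and MCC of each
  permuted ensemble on the out-of-fold discovery predictions and on every
  validation set (validation labels intact; only the discovery labels are
  permuted — the reading of the reference text adopted here).
  Holm–Bonferroni controls the familywise error across validation
  datasets, separately per metric.
* **Discriminative edges** (`identify_discriminative_fcs()`): the
  observed statistic per edge is its selection count — the number of
  classifiers giving it a nonzero weight; the null records the *maximum*
  count over all edges per iteration, which makes the threshold
  familywise-error controlling. Counts run over all classifiers (folds ×
  subsamples) in both the observed and null ensembles, for internal
  consistency. Each iteration re-draws its subsamples from the iteration
  seed. Significant edges are hyper-connections when their mean weight
  (over all classifiers, zeros included) is positive, hypo-connections
  when negative.

# Consistency, enrichment, cross-disorder mapping

Mass-univariate diagnosis effects are pooled-variance two-sample t-values
(patient minus control; Welch behind a flag). Cross-dataset
reproducibility is the Pearson correlation of t-vectors with a one-sided
permutation test shuffling only the second dataset's labels. Sign
consistency counts edges with one strict sign across all datasets (zeros
break consistency), and its enrichment within the discriminative set is
the exact binomial upper tail $P(X \ge x)$ at the whole-connectome
consistency rate — exact because $n$ is small, and the $\ge$ convention
is the standard one-sided test (the reference text does not state it).

Network enrichment uses the hypergeometric tail exactly as printed in the
reference formula, $P = 1 - \mathrm{hygecdf}(x, M, K, n) = P(X > x)$,
which is never anti-conservative relative to $P(X \ge x)$; the
conventional tail is exposed via `tail = "geq"`. Bonferroni divides by
(number of categories × 2) since hyper- and hypo-sets are tested
separately.

Cross-disorder mapping projects foreign patients onto a marker's
probability axis: sensitivity is the fraction above 0.5, its null the
sensitivities of label-permuted ensembles; two-marker planes assign
quadrants by strict comparison to 0.5 per axis (boundary points go to the
low side). All markers share one training configuration — how the
secondary markers' configurations differed in the reference analyses is
not public.

# The synthetic world

`simulate_fc_dataset()` generates exactly the structure the analysis
assumes:

$$ y = \text{baseline}_v + \text{dx}\cdot d_v \sigma_\varepsilon + \text{age}\,\beta_{a,v} + \text{sex}\,\beta_{s,v} + \gamma_{iv} + \delta_{iv}\varepsilon, $$

with per-edge site effects $\gamma_{iv} \sim N(0, \tau_a^2)$,
$\delta_{iv} \sim U(0.8, 1.25)$ — per edge, not per site, matching the
harmonization model — and a sparse set of signed diagnosis effects of
$d_v$ residual-sd units. Defaults (the "desk-scale world"): $R = 50$
($m = 1{,}225$, ~1.7% of the reference edge count), three sites of 110
controls / 36 patients each (the reference cohort's 550/180 imbalance at
~1/5 size), 30 effect edges at $|d| = 0.8$, additive site sd 0.5 *equal
to* the residual sd 0.5 — site effects comparable to between-subject
variability, the pairing at which the package's site-detectability
calibration is specified — baseline $N(0.25, 0.25^2)$ (typical Fisher-z
magnitudes), and age/sex slopes of 0.005 z/year and 0.1 z on 50 edges
each. Every simulated object carries its generating truth for recovery
tests. `simulate_family()` derives validation cohorts (fresh sites and
subjects, per-cohort effect attenuation, per-edge sign retention with
probability `sign_share`); `simulate_disorders()` builds two disorders
with a controlled effect-edge overlap and an identical shared control
group.

What the generator does *not* emulate: spatial autocorrelation between
parcels, non-Gaussian tails, scanner drift, motion-connectivity coupling,
site-by-diagnosis interactions. A green recovery test therefore
establishes that the pipeline's statistics behave as designed under the
model's own assumptions — not that the effect sizes or accuracies seen on
synthetic data transfer to clinical cohorts.

# Numerical and runtime choices

* Ages exactly 12 belong to neither the child (< 12) nor adolescent
  (12 < age < 18) stage — the printed bounds are strict; ages exactly 18
  are adults.
* Fisher-z clipping at $|r| \le 1 - 10^{-7}$; binomial/hypergeometric
  tails via `stats::pbinom`/`stats::phyper` (exact); Holm implemented
  directly and cross-checked against `stats::p.adjust`.
* All randomness derives from one base seed through a deterministic
  per-stage scheme; identical configs reproduce identical outputs
  bit-for-bit (the pipeline manifest records md5 hashes).
* Heavy permutation checks run with reduced ensemble geometry (e.g.
  5 folds × 1–2 subsamples) and, for null-calibration experiments,
  reduced problem sizes: retraining 100 permuted 100-classifier
  ensembles at desk scale would take ~40 minutes on one CPU. The reduced
  geometry changes compute, not the stated generative worlds or
  thresholds.

# Known limitations

* ComBat variant (parametric), undersampling scheme, and out-of-fold
  discovery metrics are reasoned defaults where the reference protocol is
  not public; each is flagged above.
* In-sample post-harmonization p-values are not uniform (see above).
* Harmonization idempotence is approximate: re-harmonizing changes values
  by well under 1% of the data spread (the residual is re-estimation
  noise of the per-site scale factors, proportional to the data scale).
* The pipeline assumes complete cases; missing ages are dropped at stage
  splitting with a warning, not imputed.
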