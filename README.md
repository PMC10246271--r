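# fcmarker

Diagnostic neuromarkers from multi-site resting-state functional
connectivity, in R.

Case-control resting-state fMRI studies pool participants across imaging
sites. Each site imprints additive and multiplicative artefacts on every
connectome edge, cohorts are imbalanced (many more controls than
patients), and a marker is only credible if it generalizes to independent
sites and survives permutation testing. `fcmarker` implements that whole
workflow for researchers building or stress-testing connectivity-based
classifiers:

* **Edge bookkeeping and containers** — `fc_dataset()` joins a
  participant table (site, diagnosis, age, sex) to a subjects × edges
  matrix of Fisher-z correlations; edges are indexed row-major over the
  strict upper triangle (`edge_index()`, 0-based), so a 379-ROI atlas has
  `edge_count(379)` = 71,631 edges.
* **Connectivity construction** — nuisance regression → 0.008–0.1 Hz
  zero-phase Butterworth band-pass → censoring of frames with framewise
  displacement > 0.5 mm → Fisher-z correlation (`ts_pipeline()`).
* **Harmonization** — `harmonize()` fits the parametric empirical-Bayes
  location/scale (ComBat) model
  `y_ijv = α_v + X β_v + γ_iv + δ_iv ε_ijv`
  per dataset, removing site effects `γ*`, `δ*` while protecting
  diagnosis, age and sex.
* **The marker** — `train_ensemble()` builds an ensemble of L1-penalized
  logistic classifiers (majority-class undersampling × stratified outer
  folds, inner 5-fold CV over a 30-value λ grid; the default 10 × 10
  geometry gives 100 classifiers). The mean logistic output is a
  subject's *diagnostic probability*; label positive iff > 0.5.
  `compute_metrics()` reports accuracy, sensitivity, specificity, MCC and
  rank AUC.
* **Inference** — `performance_permutation_test()` retrains the full
  ensemble on label-shuffled data for AUC/MCC nulls
  (Holm–Bonferroni across validation sets);
  `identify_discriminative_fcs()` finds edges whose LASSO selection count
  beats the familywise max-count permutation null, split into hyper-/
  hypo-connections by mean weight sign.
* **Consistency & enrichment** — per-edge diagnosis t-values
  (`diagnosis_t()`), cross-dataset t-correlations with permutation
  p-values, sign-consistency counts and the exact binomial test
  (`binomial_consistency_test()`); resting-state-network enrichment via
  the hypergeometric tail `P = 1 − hygecdf(x, M, K, n)`
  (`network_enrichment()`).
* **Cross-disorder mapping** — `cross_sensitivity()`,
  `dimensional_map()` and `spatial_overlap()` project other disorders
  onto a marker's axis and quantify marker overlap.
* **Synthetic multi-site data** — `simulate_fc_dataset()`,
  `simulate_family()` and `simulate_disorders()` generate imbalanced
  multi-site cohorts with planted site effects, covariate slopes, and
  sparse diagnosis effects (with controlled cross-dataset sign
  consistency and cross-disorder overlap), each carrying its generating
  truth for recovery tests.

`run_pipeline()` chains everything — simulate/ingest → per-dataset
harmonization → training → validation → permutation tests →
discriminative edges → consistency → enrichment — deterministically from
one seed, and returns a manifest with md5 hashes of all written outputs.

## Worked example

Simulate the default desk-scale world (50 ROIs → 1,225 edges; three
sites of 110 controls / 36 patients; 30 edges carrying a |d| = 0.8
diagnosis effect; site effects comparable to subject variability), plus
one independent validation cohort; harmonize each separately; train a
reduced 5 × 2 ensemble; validate and identify discriminative edges:

```r
library(fcmarker)

sim <- sim_config(seed = 7)
fam <- simulate_family(sim, n_validation = 1)
harmonized <- lapply(fam, function(d) harmonize(d)$dataset)

marker <- train_ensemble(harmonized$discovery, k_folds = 5,
                         n_subsamples = 2, seed = 7)
marker
cat("discovery (out-of-fold): ")
print(oof_metrics(marker))               # discovery, out-of-fold

pred <- predict(marker, harmonized$validation1)
cat("validation: ")
print(compute_metrics(harmonized$validation1$participants$diagnosis,
                      pred$probability)) # independent validation

edges <- identify_discriminative_fcs(harmonized$discovery, marker,
                                     B = 30, seed = 8)
edges
```

Output (verbatim):

```
<marker_ensemble 'discovery'> 10 classifiers (5 folds x 2 subsamples), 1225 edges, median 79 nonzero weights
discovery (out-of-fold): accuracy 0.970 | sensitivity 0.981 | specificity 0.967 | MCC 0.924 | AUC 0.996
validation: accuracy 0.959 | sensitivity 0.889 | specificity 0.982 | MCC 0.888 | AUC 0.989
<discriminative_fc_set> 23 significant edges (14 hyper / 9 hypo) at p < 0.05, B = 30
```

Reading it: the marker separates patients from controls almost perfectly
on held-out discovery subjects (out-of-fold AUC) and generalizes to the
validation cohort with fresh sites, because the planted diagnosis effect
is strong and shared; the discriminative-edge test recovers a subset of
the 30 planted edges at familywise error control — its selection-count
threshold comes from the max-count permutation null (B = 30 here, so the
smallest attainable p is 1/31). Real data, with weaker and less
consistent effects, sit far from these numbers.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline on the default synthetic world from the given
seed — simulation, per-dataset harmonization, ensemble training,
validation, permutation significance, discriminative edges, consistency
and enrichment — prints the metrics it computed, and writes the JSON
report. The study that motivates this package reports its headline
classification figures on restricted consortium data, so the report
carries no numeric targets; the script's value is the reproducible
end-to-end computation.

## Documentation

The methods vignette (`vignettes/neuromarker-methods.Rmd`) documents the
models, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, numerical choices, and
known limitations.
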