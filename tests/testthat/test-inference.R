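test_that("Holm step-down matches hand-worked cases and stats::p.adjust", {
  r1 <- holm_bonferroni(c(a = 0.01, b = 0.04))
  expect_true(all(r1$reject))            # 0.01 < 0.025 then 0.04 < 0.05

  r2 <- holm_bonferroni(c(0.03, 0.04))
  expect_false(any(r2$reject))           # 0.03 > 0.025 stops the procedure

  expect_true(holm_bonferroni(0.049)$reject)
  expect_false(holm_bonferroni(0.051)$reject)

  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    res <- holm_bonferroni(p)
    expect_equal(res$p_adjusted, stats::p.adjust(p, "holm"), tolerance = 1e-12)
    expect_false(is.unsorted(res$p_adjusted[order(p)]))  # monotone
  }
  expect_error(holm_bonferroni(numeric(0)), "empty")
  expect_error(holm_bonferroni(c(0.2, 0)), "0, 1")
})

test_that("permutation p-values follow the add-one rule and are never zero", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(fcmarker:::perm_pvalue(10, null), 1 / 6)   # beats all nulls
  expect_equal(fcmarker:::perm_pvalue(3, null), 4 / 6)    # ties count
  expect_equal(fcmarker:::perm_pvalue(0, null), 1)
  # monotone nonincreasing in the observed value
  ps <- vapply(0:6, function(x) fcmarker:::perm_pvalue(x, null), numeric(1))
  expect_false(is.unsorted(rev(ps)))
  expect_true(all(ps > 0))
})

test_that("performance permutation test separates signal from chance", {
  cfg <- fast_sim(R = 10, n0 = 25, n1 = 25, n_effect = 10, d = 1.5, seed = 50)
  fam <- simulate_family(cfg, n_validation = 1)
  hd <- fam$discovery; hv <- fam$validation1
  ens <- fast_train(hd, k_folds = 3, n_subsamples = 2, seed = 2)
  res <- performance_permutation_test(hd, ens, list(validation1 = hv),
                                      B = 19, seed = 6)
  # strong planted effect: observed AUC beats every label-shuffled null
  expect_equal(res$discovery$AUC$p, 1 / 20, tolerance = 1e-12)
  expect_equal(res$validation1$AUC$p, 1 / 20, tolerance = 1e-12)
  expect_identical(res$validation1$AUC$B, 19L)
  expect_true(all(res$holm$AUC$p > 0))

  # a budget too small to ever reach alpha is flagged
  expect_warning(
    performance_permutation_test(hd, ens, list(), B = 10, seed = 1,
                                 null_stats = list(stats = matrix(
                                   runif(20), 10, 2,
                                   dimnames = list(NULL, c("perf.discovery.AUC",
                                                           "perf.discovery.MCC"))))),
    "cannot reach")
})

test_that("observed score below the null median gives large p", {
  obs <- 0.4
  null <- seq(0.3, 0.7, length.out = 99)
  expect_gt(fcmarker:::perm_pvalue(obs, null), 0.5)
})

test_that("discriminative edges recover planted effects with FWE control machinery", {
  cfg <- fast_sim(R = 10, n0 = 30, n1 = 30, n_effect = 6, d = 1.5, seed = 52)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, k_folds = 3, n_subsamples = 2, seed = 3)
  # precomputed null maxima exercise the p-value rule without retraining
  null_max <- c(rep(1, 90), rep(2, 10))
  dfc <- identify_discriminative_fcs(ds, ens, null_max = null_max)
  counts <- selection_counts(ens)
  expect_identical(dfc$table$count, counts)
  # an edge selected by every classifier, never matched by the null: p = 1/(B+1)
  if (any(counts == 6)) {
    expect_equal(min(dfc$table$p), 1 / 101, tolerance = 1e-12)
  }
  # p monotone nonincreasing in count
  ord <- order(dfc$table$count)
  expect_false(is.unsorted(-dfc$table$p[ord]))
  # hyper/hypo labels match mean-weight signs
  sig <- dfc$significant
  mw <- mean_weights(ens)
  expect_identical(dfc$table$class[sig + 1] == "hyper", mw[sig + 1] > 0)
  # planted edges dominate the significant set
  tr <- attr(ds, "truth")
  expect_gt(length(intersect(sig, tr$effect_edges)) / max(1, length(sig)), 0.5)
})

test_that("permuted ensembles echo the observed training configuration", {
  cfg <- fast_sim(R = 8, n0 = 10, n1 = 10, seed = 53)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, seed = 4)
  eng <- permutation_engine(ds, ens, B = 2, seed = 5,
    list(echo = function(pens, labels) {
      expect_identical(pens$config[c("k_folds", "n_subsamples", "inner_folds",
                                     "n_lambda", "thresh")],
                       ens$config[c("k_folds", "n_subsamples", "inner_folds",
                                    "n_lambda", "thresh")])
      c(max = max(selection_counts(pens)))
    }))
  expect_identical(nrow(eng$stats), 2L)
})

test_that("the significant set is invariant to edge relabeling", {
  cfg <- fast_sim(R = 8, n0 = 20, n1 = 20, n_effect = 4, d = 1.5, seed = 54)
  ds <- simulate_fc_dataset(cfg)
  # tight optimizer tolerance so borderline coefficients cannot flip with
  # the coordinate order
  ens <- train_ensemble(ds, k_folds = 3, n_subsamples = 1, inner_folds = 2,
                        n_lambda = 10, thresh = 1e-11, seed = 6)
  counts <- selection_counts(ens)
  set.seed(9)
  perm <- sample(ncol(ds$fc))
  ds2 <- ds
  ds2$fc <- ds$fc[, perm]
  colnames(ds2$fc) <- colnames(ds$fc)
  ens2 <- train_ensemble(ds2, k_folds = 3, n_subsamples = 1, inner_folds = 2,
                         n_lambda = 10, thresh = 1e-11, seed = 6)
  counts2 <- selection_counts(ens2)
  expect_identical(counts2, counts[perm])
})
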