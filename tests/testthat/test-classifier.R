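test_that("performance metrics match their closed-form oracles", {
  # perfect separation
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$accuracy, 1); expect_equal(m$mcc, 1); expect_equal(m$auc, 1)

  # TP=9 TN=8 FP=2 FN=1 -> MCC = 70/sqrt(9900)
  labels <- c(rep(1, 9), rep(0, 8), rep(0, 2), rep(1, 1))
  probs  <- c(rep(.9, 9), rep(.1, 8), rep(.9, 2), rep(.1, 1))
  m2 <- compute_metrics(labels, probs)
  expect_identical(c(m2$tp, m2$tn, m2$fp, m2$fn), c(9L, 8L, 2L, 1L))
  expect_equal(m2$mcc, 70 / sqrt(9900), tolerance = 1e-12)
  expect_equal(m2$sensitivity, 0.9)
  expect_equal(m2$specificity, 0.8)

  # AUC = 2/3 by exhaustive concordant-pair count
  m3 <- compute_metrics(c(1, 1, 0, 1), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(m3$auc, 2 / 3, tolerance = 1e-12)

  # empty marginal: MCC defined as 0
  m4 <- compute_metrics(c(0, 0, 1), c(0.1, 0.2, 0.3))
  expect_identical(m4$mcc, 0)

  # one-class input: AUC undefined, the rest still computed
  expect_warning(m5 <- compute_metrics(c(1, 1), c(0.9, 0.2)), "one class")
  expect_true(is.na(m5$auc))
  expect_equal(m5$sensitivity, 0.5)
})

test_that("rank AUC equals the exhaustive pairwise-concordance oracle", {
  concordance_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(10)
  for (i in 1:500) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(compute_metrics(y, s)$auc, concordance_auc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("MCC symmetries hold", {
  set.seed(11)
  for (i in 1:50) {
    y <- c(0, 1, rbinom(10, 1, 0.5))
    s <- runif(12)
    m <- compute_metrics(y, s)$mcc
    # swapping both labels and predictions leaves MCC unchanged
    expect_equal(compute_metrics(1 - y, 1 - s, threshold = 0.5 - 1e-12)$mcc,
                 m, tolerance = 1e-9)
    # inverting predictions flips the sign
    expect_equal(compute_metrics(y, 1 - s, threshold = 0.5 - 1e-12)$mcc,
                 -m, tolerance = 1e-9)
  }
})

test_that("ensemble geometry, determinism and sparsity are as configured", {
  cfg <- fast_sim(R = 8, n0 = 12, n1 = 12, n_effect = 5, d = 1.2, seed = 30)
  ds <- simulate_fc_dataset(cfg)
  ens <- train_ensemble(ds, k_folds = 4, n_subsamples = 3, inner_folds = 3,
                        n_lambda = 12, seed = 77)
  expect_length(ens$classifiers, 12L)
  expect_identical(vapply(ens$classifiers, `[[`, 0L, "subsample"),
                   rep(1:3, each = 4))

  ens2 <- train_ensemble(ds, k_folds = 4, n_subsamples = 3, inner_folds = 3,
                         n_lambda = 12, seed = 77)
  expect_identical(lapply(ens$classifiers, `[[`, "weights"),
                   lapply(ens2$classifiers, `[[`, "weights"))
  expect_identical(ens$oof_prob, ens2$oof_prob)
  ens3 <- train_ensemble(ds, k_folds = 4, n_subsamples = 3, inner_folds = 3,
                         n_lambda = 12, seed = 78)
  expect_false(identical(ens$oof_prob, ens3$oof_prob))

  # sparse selection: typical model uses a small fraction of edges
  nz <- vapply(ens$classifiers, function(cl) sum(cl$weights != 0), numeric(1))
  expect_lt(stats::median(nz), ens$m / 4)
})

test_that("undersampling balances classes within each subsample", {
  cfg <- fast_sim(R = 8, n0 = 30, n1 = 10, seed = 5)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, k_folds = 2, n_subsamples = 2, seed = 3)
  for (cl in ens$classifiers) {
    y_tr <- ds$participants$diagnosis[cl$train_rows]
    expect_lte(abs(sum(y_tr == 0) - sum(y_tr == 1)), 1)
  }
  # every subject still receives an out-of-fold probability
  expect_true(all(is.finite(ens$oof_prob)))
})

test_that("prediction averages classifiers and labels by the strict 0.5 rule", {
  cfg <- fast_sim(R = 8, n0 = 12, n1 = 12, n_effect = 5, d = 1.2, seed = 31)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, seed = 9)
  # all classifiers identical -> ensemble mean equals the single model
  single <- ens
  single$classifiers <- rep(ens$classifiers[1], 4)
  pr_single <- predict(single, ds)
  cl <- ens$classifiers[[1]]
  manual <- fcmarker:::logistic(
    as.numeric(sweep(sweep(ds$fc, 2, cl$mu), 2, cl$sd, "/") %*% cl$weights) +
      cl$intercept)
  expect_equal(pr_single$probability, manual, tolerance = 1e-12)

  # probability exactly 0.5 is labeled control
  expect_identical(as.integer(0.5 > 0.5), 0L)
  fake <- data.frame(probability = c(0.5, 0.5 + 1e-9))
  expect_identical(as.integer(fake$probability > 0.5), c(0L, 1L))

  expect_error(predict(ens, ds$fc[, 1:10]), "dimension error")
})

test_that("resubstitution is at least as optimistic as out-of-fold", {
  cfg <- fast_sim(R = 10, n0 = 25, n1 = 25, n_effect = 8, d = 0.8, seed = 41)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, k_folds = 3, n_subsamples = 2, seed = 4)
  auc_oof <- oof_metrics(ens)$auc
  auc_resub <- compute_metrics(ds$participants$diagnosis,
                               predict(ens, ds)$probability)$auc
  expect_gte(auc_resub, auc_oof)
})

test_that("permuted labels yield chance-level out-of-fold AUC", {
  aucs <- vapply(1:5, function(s) {
    cfg <- fast_sim(R = 10, n0 = 30, n1 = 30, n_effect = 8, d = 1, seed = s)
    ds <- simulate_fc_dataset(cfg)
    set.seed(1000 + s)
    ds$participants$diagnosis <- sample(ds$participants$diagnosis)
    oof_metrics(fast_train(ds, seed = s))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("training preconditions are enforced", {
  ds <- tiny_dataset(6, 6)
  ds$participants$diagnosis <- rep(0L, 12)
  expect_error(train_ensemble(ds), "both diagnostic classes")
  ds2 <- tiny_dataset(12, 4)
  expect_error(train_ensemble(ds2, k_folds = 10), "stratification error")
})

test_that("ensembles survive a JSON round trip", {
  cfg <- fast_sim(R = 8, n0 = 12, n1 = 12, n_effect = 5, d = 1.2, seed = 30)
  ds <- simulate_fc_dataset(cfg)
  ens <- fast_train(ds, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(ens, path)
  back <- read_ensemble_json(path)
  expect_equal(predict(back, ds)$probability, predict(ens, ds)$probability,
               tolerance = 1e-12)
  expect_identical(length(back$classifiers), length(ens$classifiers))
})
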