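# stratified fold assignment: each class is shuffled and dealt round-robin
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("stratification error: class ", cls, " has ", length(idx),
           " subjects but ", k, " folds were requested", call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# log-spaced penalty grid: n values over `decades` decades below the
# smallest lambda that zeroes every coefficient
lambda_grid <- function(Xs, y, n_lambda, decades = 3) {
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * 10^(-decades)), length.out = n_lambda))
}

bin_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# glmnet warns about small per-class counts on every tiny inner fold; the
# fold sizes are intentional, so that specific warning is muffled.
quiet_glmnet <- function(...) {
  withCallingHandlers(glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Fit one LASSO logistic classifier on (X, y): per-edge z-scoring from the
# training data, inner stratified CV over a shared log-spaced lambda grid
# (deviance loss, ties broken toward the larger = sparser lambda), final
# fit at the selected penalty. Returns weights on the standardized scale.
fit_lasso_cv <- function(X, y, inner_folds = 5, n_lambda = 30, thresh = 1e-5) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  lam <- lambda_grid(Xs, y, n_lambda)
  fold <- stratified_folds(y, inner_folds)
  dev <- matrix(NA_real_, inner_folds, n_lambda)
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    mu_f <- colMeans(X[tr, , drop = FALSE])
    sd_f <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_f[sd_f == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu_f), 2, sd_f, "/")
    Xva <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu_f), 2, sd_f, "/")
    fit <- quiet_glmnet(Xtr, y[tr], family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = thresh)
    pr <- stats::predict(fit, Xva, type = "response")
    # glmnet may stop early on a degenerate path; align by fitted lambdas
    cols <- match(signif(fit$lambda, 8), signif(lam, 8))
    for (j in seq_along(cols))
      if (!is.na(cols[j])) dev[f, cols[j]] <- bin_deviance(y[!tr], pr[, j])
  }
  mdev <- colMeans(dev)
  ok <- which(is.finite(mdev))
  sel <- ok[which.min(mdev[ok])]   # grid is decreasing: first min = largest lambda
  fit <- quiet_glmnet(Xs, y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = thresh)
  j <- match(signif(lam[sel], 8), signif(fit$lambda, 8))
  if (is.na(j)) j <- which.min(abs(fit$lambda - lam[sel]))
  w <- as.numeric(fit$beta[, j])
  if (all(w == 0) && all(as.matrix(fit$beta) == 0))
    warning("degenerate penalty path: every model is empty; keeping the sparsest")
  list(weights = w, intercept = fit$a0[j], lambda = lam[sel], mu = mu, sd = sd_)
}

#' Train an ensemble of sparse logistic classifiers
#'
#' The neuromarker: `n_subsamples` class-balanced undersamples of the
#' majority class, each split into `k_folds` stratified outer folds; per
#' outer fold an inner `inner_folds`-fold cross-validation over a
#' log-spaced penalty grid selects the LASSO penalty (minimum mean
#' deviance, ties toward the sparser model) and one L1-penalized logistic
#' classifier is fitted on the outer-training portion with per-edge
#' z-scoring from its own training data. The default 10 folds x 10
#' subsamples yields 100 classifiers. Every discovery subject receives
#' out-of-fold diagnostic probabilities: within a subsample, each subject
#' is scored by the fold classifiers whose training set excluded it, and
#' probabilities are averaged across subsamples.
#'
#' @param dataset An [fc_dataset()] containing both classes.
#' @param k_folds Outer folds per subsample.
#' @param n_subsamples Number of majority-class undersamples.
#' @param inner_folds Inner CV folds for penalty selection.
#' @param n_lambda Penalty grid size (3 decades below the null-model
#'   penalty).
#' @param thresh glmnet convergence threshold.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `marker_ensemble`: list with `classifiers` (each holding
#'   sparse `weights`, `intercept`, `lambda`, training standardization
#'   `mu`/`sd`, and subsample/fold provenance), `oof_prob` (per-subject
#'   out-of-fold diagnostic probability), `labels`, `config`, `m`.
#' @export
train_ensemble <- function(dataset, k_folds = 10, n_subsamples = 10,
                           inner_folds = 5, n_lambda = 30, thresh = 1e-5,
                           seed = 1) {
  y_all <- dataset$participants$diagnosis
  if (length(unique(y_all)) < 2)
    stop("both diagnostic classes must be present", call. = FALSE)
  X_all <- dataset$fc
  n <- nrow(X_all)
  config <- list(k_folds = k_folds, n_subsamples = n_subsamples,
                 inner_folds = inner_folds, n_lambda = n_lambda,
                 thresh = thresh, seed = seed)
  classifiers <- vector("list", k_folds * n_subsamples)
  prob_sum <- matrix(0, n, n_subsamples)
  prob_cnt <- matrix(0L, n, n_subsamples)
  ci <- 0L
  for (s in seq_len(n_subsamples)) {
    sub_idx <- with_seed(derive_seed(seed, 10 * s), {
      i0 <- which(y_all == 0); i1 <- which(y_all == 1)
      if (length(i0) > length(i1)) i0 <- sort(sample(i0, length(i1)))
      else if (length(i1) > length(i0)) i1 <- sort(sample(i1, length(i0)))
      sort(c(i0, i1))
    })
    y <- y_all[sub_idx]
    X <- X_all[sub_idx, , drop = FALSE]
    fold <- with_seed(derive_seed(seed, 10 * s + 1), stratified_folds(y, k_folds))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      model <- with_seed(derive_seed(seed, 1000 * s + f),
                         fit_lasso_cv(X[tr, , drop = FALSE], y[tr],
                                      inner_folds, n_lambda, thresh))
      model$subsample <- s
      model$fold <- f
      model$train_rows <- sub_idx[tr]
      ci <- ci + 1L
      classifiers[[ci]] <- model
      # score every subject outside this classifier's training set
      out_rows <- setdiff(seq_len(n), sub_idx[tr])
      Xo <- sweep(sweep(X_all[out_rows, , drop = FALSE], 2, model$mu), 2,
                  model$sd, "/")
      pr <- logistic(as.numeric(Xo %*% model$weights) + model$intercept)
      prob_sum[out_rows, s] <- prob_sum[out_rows, s] + pr
      prob_cnt[out_rows, s] <- prob_cnt[out_rows, s] + 1L
    }
  }
  oof_sub <- prob_sum / pmax(prob_cnt, 1L)
  oof_sub[prob_cnt == 0] <- NA_real_
  oof <- rowMeans(oof_sub, na.rm = TRUE)
  structure(list(classifiers = classifiers, oof_prob = oof,
                 labels = y_all, subject_id = dataset$participants$subject_id,
                 config = config, m = ncol(X_all), name = dataset$name),
            class = "marker_ensemble")
}

#' @export
print.marker_ensemble <- function(x, ...) {
  nz <- vapply(x$classifiers, function(cl) sum(cl$weights != 0), numeric(1))
  cat(sprintf("<marker_ensemble '%s'> %d classifiers (%d folds x %d subsamples), %d edges, median %d nonzero weights\n",
              x$name, length(x$classifiers), x$config$k_folds,
              x$config$n_subsamples, x$m, as.integer(stats::median(nz))))
  invisible(x)
}

#' Diagnostic probabilities from a marker ensemble
#'
#' Applies every classifier of the ensemble to each subject and averages
#' the logistic outputs; the mean is the diagnostic probability, and a
#' subject is labeled positive iff it strictly exceeds 0.5 (a subject at
#' exactly 0.5 is labeled control).
#'
#' @param object A `marker_ensemble`.
#' @param dataset An [fc_dataset()] (or plain matrix) with the same edge
#'   count as the ensemble.
#' @param ... Unused.
#' @return A data.frame with `subject_id`, `probability`, `label`.
#' @export
predict.marker_ensemble <- function(object, dataset, ...) {
  X <- if (inherits(dataset, "fc_dataset")) dataset$fc else as.matrix(dataset)
  if (ncol(X) != object$m)
    stop("dimension error: dataset has ", ncol(X), " edges; ensemble expects ",
         object$m, call. = FALSE)
  # fold per-classifier standardization into the linear coefficients so all
  # classifiers are applied in a single matrix product
  V <- vapply(object$classifiers, function(cl) cl$weights / cl$sd,
              numeric(object$m))
  b0 <- vapply(object$classifiers,
               function(cl) cl$intercept - sum(cl$weights * cl$mu / cl$sd),
               numeric(1))
  P <- logistic(sweep(X %*% V, 2, b0, "+"))
  prob <- rowMeans(P)
  data.frame(subject_id = if (!is.null(rownames(X))) rownames(X)
                          else seq_len(nrow(X)),
             probability = prob, label = as.integer(prob > 0.5),
             stringsAsFactors = FALSE)
}

#' Classification performance metrics
#'
#' Confusion counts at a strict probability threshold plus accuracy,
#' sensitivity, specificity, the Matthews correlation coefficient (defined
#' as 0 when any marginal is empty) and the rank-based AUC (ties counted
#' one half).
#'
#' @param labels 0/1 vector of true classes.
#' @param probabilities Scores in the same order.
#' @param threshold Decision threshold; predicted positive iff strictly
#'   greater.
#' @return A list of class `performance_metrics`: `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `mcc`, `auc` (`NA` with a
#'   warning when only one class is present).
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / length(labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    auc <- NA_real_
  } else {
    r <- rank(probabilities)          # average ranks handle ties as 1/2
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
                 sensitivity = sens, specificity = spec, mcc = mcc, auc = auc),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | MCC %.3f | AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc, x$auc))
  invisible(x)
}

#' Out-of-fold performance of an ensemble on its discovery set
#' @param ensemble A `marker_ensemble`.
#' @param labels Optional labels (defaults to the training labels).
#' @return A `performance_metrics` list.
#' @export
oof_metrics <- function(ensemble, labels = ensemble$labels) {
  compute_metrics(labels, ensemble$oof_prob)
}

#' Per-edge selection counts of an ensemble
#' @param ensemble A `marker_ensemble`.
#' @return Integer vector, length `m`: number of classifiers with a nonzero
#'   weight on each edge.
#' @export
selection_counts <- function(ensemble) {
  counts <- integer(ensemble$m)
  for (cl in ensemble$classifiers)
    counts <- counts + (cl$weights != 0)
  counts
}

#' Per-edge mean weights over all classifiers (zeros included)
#' @param ensemble A `marker_ensemble`.
#' @return Numeric vector of length `m` (standardized-feature scale).
#' @export
mean_weights <- function(ensemble) {
  W <- vapply(ensemble$classifiers, `[[`, numeric(ensemble$m), "weights")
  rowMeans(W)
}
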