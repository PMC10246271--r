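perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Retrain label-permuted ensembles and collect summary statistics
#'
#' The shared engine behind every permutation test that requires retrained
#' classifiers: at each of `B` iterations the discovery labels are
#' shuffled, a full ensemble is retrained with the identical configuration
#' as the observed one, and each supplied evaluator reduces the permuted
#' ensemble to named numbers (max selection count, validation AUC/MCC,
#' foreign-patient sensitivity, ...). Permuted ensembles are never kept in
#' memory.
#'
#' @param discovery The discovery [fc_dataset()].
#' @param ensemble The observed `marker_ensemble` (its `config` is reused
#'   verbatim, including the ensemble geometry).
#' @param B Number of permutations.
#' @param seed Integer seed; iteration b uses seeds derived from it.
#' @param evaluators Named list of functions `f(perm_ensemble, perm_labels)`
#'   returning a named numeric vector.
#' @return A list with `stats` (B x k matrix, columns named by the
#'   evaluators' outputs) and `config` echo.
#' @export
permutation_engine <- function(discovery, ensemble, B, seed,
                               evaluators) {
  cfg <- ensemble$config
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    perm <- discovery
    perm$participants$diagnosis <- with_seed(
      derive_seed(seed, 2 * b), sample(discovery$participants$diagnosis))
    pens <- train_ensemble(perm, k_folds = cfg$k_folds,
                           n_subsamples = cfg$n_subsamples,
                           inner_folds = cfg$inner_folds,
                           n_lambda = cfg$n_lambda, thresh = cfg$thresh,
                           seed = derive_seed(seed, 2 * b + 1))
    stopifnot(identical(pens$config[names(pens$config) != "seed"],
                        cfg[names(cfg) != "seed"]))
    rows[[b]] <- unlist(lapply(evaluators, function(f)
      f(pens, perm$participants$diagnosis)))
  }
  list(stats = do.call(rbind, rows), config = cfg, B = B, seed = seed)
}

new_permutation_null <- function(metric, observed, null) {
  structure(list(metric = metric, B = length(null), null = null,
                 observed = observed, p = perm_pvalue(observed, null)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("%s = %.4f, permutation p = %.4g (B = %d)\n",
              x$metric, x$observed, x$p, x$B))
  invisible(x)
}

#' Permutation significance of marker performance
#'
#' Tests observed AUC and MCC on the discovery set (out-of-fold) and on
#' each validation dataset against nulls obtained by shuffling the
#' discovery labels and retraining the full ensemble at every iteration;
#' validation labels stay intact. P-values use the standard add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + B)` and are Holm-Bonferroni
#' adjusted across the validation datasets, separately per metric.
#'
#' @param discovery The discovery [fc_dataset()].
#' @param ensemble The observed `marker_ensemble` trained on `discovery`.
#' @param validations Named list of validation [fc_dataset()]s (may be
#'   empty).
#' @param B Number of permutations (the reference design uses 500; smaller
#'   budgets are supported for desk-scale runs).
#' @param seed Integer seed.
#' @param null_stats Optional precomputed [permutation_engine()] output to
#'   reuse (its columns must cover the datasets tested).
#' @return A list with per-dataset `permutation_null` pairs (`$AUC`,
#'   `$MCC`), plus `holm`: the step-down decisions across validation
#'   datasets per metric.
#' @export
performance_permutation_test <- function(discovery, ensemble, validations =
                                           list(), B = 500, seed = 1,
                                         null_stats = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (1 / (1 + B) > 0.05)
    warning("B = ", B, " cannot reach p < 0.05 (minimum attainable p = ",
            signif(1 / (1 + B), 3), ")")
  evals <- list(perf = function(ens, perm_labels) {
    out <- c(discovery.AUC = NA_real_, discovery.MCC = NA_real_)
    mm <- compute_metrics(perm_labels, ens$oof_prob)
    out["discovery.AUC"] <- mm$auc; out["discovery.MCC"] <- mm$mcc
    for (nm in names(validations)) {
      pr <- predict(ens, validations[[nm]])
      mv <- compute_metrics(validations[[nm]]$participants$diagnosis,
                            pr$probability)
      out[paste0(nm, ".AUC")] <- mv$auc
      out[paste0(nm, ".MCC")] <- mv$mcc
    }
    out
  })
  if (is.null(null_stats))
    null_stats <- permutation_engine(discovery, ensemble, B, seed, evals)
  S <- null_stats$stats
  colnames(S) <- sub("^perf\\.", "", colnames(S))

  observed <- list(discovery = oof_metrics(ensemble))
  for (nm in names(validations)) {
    pr <- predict(ensemble, validations[[nm]])
    observed[[nm]] <- compute_metrics(validations[[nm]]$participants$diagnosis,
                                      pr$probability)
  }
  out <- list()
  for (nm in names(observed)) {
    out[[nm]] <- list(
      AUC = new_permutation_null("AUC", observed[[nm]]$auc,
                                 S[, paste0(nm, ".AUC")]),
      MCC = new_permutation_null("MCC", observed[[nm]]$mcc,
                                 S[, paste0(nm, ".MCC")]))
  }
  vnames <- names(validations)
  holm <- NULL
  if (length(vnames)) {
    holm <- lapply(c(AUC = "AUC", MCC = "MCC"), function(metric) {
      p <- vapply(vnames, function(nm) out[[nm]][[metric]]$p, numeric(1))
      holm_bonferroni(p)
    })
  }
  c(out, list(holm = holm, null_stats = null_stats))
}

#' Holm-Bonferroni step-down familywise-error control
#'
#' Sorts the p-values ascending and compares the k-th smallest with
#' `alpha / (m - k + 1)`, stopping at the first failure; also returns the
#' monotone adjusted p-values.
#'
#' @param pvalues Named numeric vector of raw p-values in (0, 1].
#' @param alpha Familywise error level.
#' @return A data.frame with columns `p`, `p_adjusted`, `reject`, in the
#'   input order.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value set", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]",
                                            call. = FALSE)
  k <- length(pvalues)
  o <- order(pvalues)
  adj <- cummax(pmin((k - seq_len(k) + 1) * pvalues[o], 1))
  thresh_ok <- pvalues[o] < alpha / (k - seq_len(k) + 1)
  # step-down: reject only up to the first failure
  reject_sorted <- cumprod(thresh_ok) == 1
  out <- data.frame(p = pvalues, p_adjusted = NA_real_, reject = NA)
  out$p_adjusted[o] <- adj
  out$reject[o] <- reject_sorted
  rownames(out) <- names(pvalues)
  out
}

#' Identify discriminative edges by the maximum-count permutation null
#'
#' For each edge, the observed statistic is the number of ensemble
#' classifiers that gave it a nonzero LASSO weight. At each permutation the
#' discovery labels are shuffled, the full ensemble retrained, and the
#' maximum selection count over all edges recorded; an edge's p-value is
#' `(1 + #\{null max >= count\}) / (1 + B)`. Using the maximum over edges
#' makes the threshold familywise-error controlling. Significant edges
#' (p < `alpha`) are labeled hyper-connections when their mean weight over
#' all classifiers (zeros included) is positive and hypo-connections when
#' negative.
#'
#' @param discovery The discovery [fc_dataset()].
#' @param ensemble The observed `marker_ensemble`.
#' @param B Permutations (the reference design uses 500 for the primary
#'   marker and 100 for secondary markers).
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @param null_max Optional precomputed vector of null maxima to reuse.
#' @return A `discriminative_fc_set`: list with `table` (per-edge
#'   data.frame: `edge`, `count`, `p`, `mean_weight`, `class`),
#'   `significant` (0-based edge indices), `hyper`, `hypo`, `null_max`,
#'   `B`, `alpha`.
#' @export
identify_discriminative_fcs <- function(discovery, ensemble, B = 500,
                                        seed = 1, alpha = 0.05,
                                        null_max = NULL) {
  counts <- selection_counts(ensemble)
  if (is.null(null_max)) {
    eng <- permutation_engine(discovery, ensemble, B, seed,
      list(max_count = function(ens, labels) c(max = max(selection_counts(ens)))))
    null_max <- as.numeric(eng$stats[, 1])
  }
  p <- vapply(counts, function(cc) perm_pvalue(cc, null_max), numeric(1))
  mw <- mean_weights(ensemble)
  sig <- which(p < alpha) - 1L
  cls <- rep(NA_character_, length(counts))
  cls[sig + 1L] <- ifelse(mw[sig + 1L] > 0, "hyper", "hypo")
  tab <- data.frame(edge = seq_along(counts) - 1L, count = counts, p = p,
                    mean_weight = mw, class = cls, stringsAsFactors = FALSE)
  structure(list(table = tab, significant = sig,
                 hyper = sig[cls[sig + 1L] == "hyper"],
                 hypo = sig[cls[sig + 1L] == "hypo"],
                 null_max = null_max, B = length(null_max), alpha = alpha),
            class = "discriminative_fc_set")
}

#' @export
print.discriminative_fc_set <- function(x, ...) {
  cat(sprintf("<discriminative_fc_set> %d significant edges (%d hyper / %d hypo) at p < %.2f, B = %d\n",
              length(x$significant), length(x$hyper), length(x$hypo),
              x$alpha, x$B))
  invisible(x)
}
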