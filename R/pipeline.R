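#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. All stochastic stages
#' derive their seeds from the single `seed`, so a config fully determines
#' the run.
#'
#' @param sim A [sim_config()] describing the synthetic world (the
#'   pipeline can equally start from datasets read with
#'   [read_fc_dataset()]; see `datasets`).
#' @param datasets Optional named list of pre-built datasets
#'   (`discovery` plus validations); overrides `sim`.
#' @param n_validation,attenuation,stages Passed to [simulate_family()]
#'   when simulating.
#' @param harmonization Apply per-dataset ComBat harmonization.
#' @param k_folds,n_subsamples,inner_folds,n_lambda,thresh Ensemble
#'   settings (see [train_ensemble()]).
#' @param B_perm Permutation budget shared by the performance test and the
#'   discriminative-edge null (0 skips both permutation stages).
#' @param B_t Permutation budget for cross-dataset t correlations.
#' @param alpha Significance level used throughout.
#' @param seed Master seed.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), datasets = NULL,
                            n_validation = 2, attenuation = 1,
                            stages = "adult", harmonization = TRUE,
                            k_folds = 10, n_subsamples = 10,
                            inner_folds = 5, n_lambda = 30, thresh = 1e-5,
                            B_perm = 100, B_t = 200, alpha = 0.05,
                            seed = 1, out_dir = NULL) {
  structure(list(sim = sim, datasets = datasets,
                 n_validation = n_validation, attenuation = attenuation,
                 stages = stages, harmonization = harmonization,
                 k_folds = k_folds, n_subsamples = n_subsamples,
                 inner_folds = inner_folds, n_lambda = n_lambda,
                 thresh = thresh, B_perm = B_perm, B_t = B_t,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full neuromarker analysis
#'
#' Stage order: simulate (or ingest) -> harmonize each dataset separately
#' -> train the ensemble on the discovery set -> apply it to every
#' validation set -> permutation significance of AUC/MCC with
#' Holm-Bonferroni across validation sets -> discriminative-edge
#' identification via the max-count null -> per-dataset diagnosis
#' t-vectors, cross-dataset correlations, sign consistency and the
#' binomial consistency test -> network enrichment of hyper/hypo sets.
#' One permutation run feeds both the performance null and the max-count
#' null (identical retraining construction).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the stage outputs and
#'   `manifest` (config echo, seed, and md5 hashes of any files written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # --- data ---------------------------------------------------------------
  if (is.null(config$datasets)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, 1)
    datasets <- simulate_family(sim, n_validation = config$n_validation,
                                attenuation = config$attenuation,
                                stages = config$stages)
  } else datasets <- config$datasets
  if (!"discovery" %in% names(datasets))
    stop("stage 'data' failed: no dataset named 'discovery'", call. = FALSE)

  # --- harmonization (always per dataset, never joint) --------------------
  harmonization_models <- NULL
  if (config$harmonization) {
    hm <- lapply(datasets, function(d) tryCatch(harmonize(d),
      error = function(e) stop("stage 'harmonize' failed: ",
                               conditionMessage(e), call. = FALSE)))
    harmonization_models <- lapply(hm, `[[`, "model")
    datasets <- lapply(hm, `[[`, "dataset")
  }
  discovery <- datasets$discovery
  validations <- datasets[setdiff(names(datasets), "discovery")]

  # --- marker -------------------------------------------------------------
  ensemble <- train_ensemble(discovery, k_folds = config$k_folds,
                             n_subsamples = config$n_subsamples,
                             inner_folds = config$inner_folds,
                             n_lambda = config$n_lambda,
                             thresh = config$thresh,
                             seed = derive_seed(config$seed, 2))
  metrics <- list(discovery = oof_metrics(ensemble))
  predictions <- list()
  for (nm in names(validations)) {
    pr <- predict(ensemble, validations[[nm]])
    predictions[[nm]] <- pr
    metrics[[nm]] <- compute_metrics(validations[[nm]]$participants$diagnosis,
                                     pr$probability)
  }

  # --- permutation inference ---------------------------------------------
  performance <- edges <- NULL
  if (config$B_perm > 0) {
    evals <- list(
      max_count = function(ens, labels) c(max = max(selection_counts(ens))),
      perf = function(ens, perm_labels) {
        mm <- compute_metrics(perm_labels, ens$oof_prob)
        out <- c(discovery.AUC = mm$auc, discovery.MCC = mm$mcc)
        for (nm in names(validations)) {
          pr <- predict(ens, validations[[nm]])
          mv <- compute_metrics(validations[[nm]]$participants$diagnosis,
                                pr$probability)
          out[paste0(nm, ".AUC")] <- mv$auc
          out[paste0(nm, ".MCC")] <- mv$mcc
        }
        out
      })
    eng <- permutation_engine(discovery, ensemble, config$B_perm,
                              derive_seed(config$seed, 3), evals)
    perf_stats <- eng
    perf_stats$stats <- eng$stats[, -1, drop = FALSE]
    performance <- performance_permutation_test(discovery, ensemble,
                                                validations,
                                                B = config$B_perm,
                                                null_stats = perf_stats)
    edges <- identify_discriminative_fcs(discovery, ensemble,
                                         alpha = config$alpha,
                                         null_max = as.numeric(eng$stats[, 1]))
  }

  # --- consistency --------------------------------------------------------
  effects <- lapply(datasets, diagnosis_t)
  correlations <- NULL
  if (config$B_t > 0 && length(validations)) {
    correlations <- lapply(names(validations), function(nm)
      cross_dataset_correlation(effects$discovery, validations[[nm]],
                                B = config$B_t,
                                seed = derive_seed(config$seed, 4)))
    names(correlations) <- names(validations)
  }
  consistency <- NULL
  if (length(effects) >= 2 && !is.null(edges) &&
      length(edges$significant) > 0) {
    K_whole <- sign_consistency(effects)
    x_set <- sign_consistency(effects, subset = edges$significant)
    consistency <- list(
      x_set = x_set, n_set = length(edges$significant),
      K_whole = K_whole, M_whole = ncol(discovery$fc),
      p = binomial_consistency_test(x_set, length(edges$significant),
                                    K_whole, ncol(discovery$fc)))
  }

  # --- enrichment ---------------------------------------------------------
  enrichment <- if (!is.null(edges))
    network_enrichment(edges, discovery$atlas, alpha = config$alpha)

  result <- list(datasets = datasets, harmonization = harmonization_models,
                 ensemble = ensemble, metrics = metrics,
                 predictions = predictions, performance = performance,
                 edges = edges, effects = effects,
                 correlations = correlations, consistency = consistency,
                 enrichment = enrichment)

  # --- outputs + manifest -------------------------------------------------
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(files, write_pipeline_outputs(result, config))
  }
  cfg_echo <- config
  cfg_echo$datasets <- NULL
  manifest <- list(seed = config$seed, config = cfg_echo,
                   files = if (length(files))
                     data.frame(path = unname(files),
                                md5 = unname(tools::md5sum(files)),
                                stringsAsFactors = FALSE)
                   else NULL)
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  result
}

write_pipeline_outputs <- function(result, config) {
  od <- config$out_dir
  files <- character(0)
  mj <- file.path(od, "metrics.json")
  jsonlite::write_json(lapply(result$metrics, unclass), mj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, mj)
  if (!is.null(result$edges)) {
    et <- file.path(od, "discriminative_edges.tsv")
    utils::write.table(result$edges$table, et, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, et)
  }
  if (!is.null(result$enrichment)) {
    en <- file.path(od, "enrichment.tsv")
    utils::write.table(result$enrichment, en, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, en)
  }
  if (!is.null(result$consistency)) {
    cj <- file.path(od, "consistency.json")
    jsonlite::write_json(result$consistency, cj, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, cj)
  }
  ej <- file.path(od, "ensemble.json")
  write_ensemble_json(result$ensemble, ej)
  files <- c(files, ej)
  files
}

#' Serialize / restore a marker ensemble as JSON
#'
#' Weights are stored as sparse (0-based index, value) pairs together with
#' the intercept, penalty, training standardization and the config echo.
#'
#' @param ensemble A `marker_ensemble`.
#' @param path Output / input path.
#' @return `write_ensemble_json()`: `path`, invisibly.
#'   `read_ensemble_json()`: a `marker_ensemble`.
#' @export
write_ensemble_json <- function(ensemble, path) {
  cls <- lapply(ensemble$classifiers, function(cl) {
    nz <- which(cl$weights != 0)
    list(edge = nz - 1L, weight = cl$weights[nz],
         intercept = as.numeric(cl$intercept), lambda = cl$lambda,
         mu = cl$mu, sd = cl$sd, subsample = cl$subsample, fold = cl$fold)
  })
  jsonlite::write_json(
    list(m = ensemble$m, name = ensemble$name, config = ensemble$config,
         labels = ensemble$labels, subject_id = ensemble$subject_id,
         oof_prob = ensemble$oof_prob, classifiers = cls),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  classifiers <- lapply(seq_len(nrow(j$classifiers)), function(i) {
    row <- j$classifiers[i, ]
    w <- numeric(j$m)
    w[unlist(row$edge) + 1L] <- unlist(row$weight)
    list(weights = w, intercept = row$intercept, lambda = row$lambda,
         mu = unlist(row$mu), sd = unlist(row$sd),
         subsample = row$subsample, fold = row$fold)
  })
  structure(list(classifiers = classifiers, oof_prob = j$oof_prob,
                 labels = j$labels, subject_id = j$subject_id,
                 config = as.list(j$config), m = j$m, name = j$name),
            class = "marker_ensemble")
}
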