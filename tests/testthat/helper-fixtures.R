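# Small fixtures shared across test files. Everything is built in code at
# test time; nothing is read from disk.

tiny_atlas <- function(R = 6) {
  fc_atlas(sprintf("r%02d", seq_len(R) - 1),
           rep_len(c("DMN", "visual", "subcortical"), R))
}

# hand-built dataset: deterministic fc values, two sites
tiny_dataset <- function(n0 = 4, n1 = 4, R = 6, seed = 1, n_sites = 2) {
  set.seed(seed)
  n <- n0 + n1
  m <- edge_count(R)
  participants <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    site = rep_len(sprintf("site%d", seq_len(n_sites)), n),
    diagnosis = c(rep(0L, n0), rep(1L, n1)),
    age = round(runif(n, 20, 50), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  fc <- matrix(rnorm(n * m, 0.2, 0.3), n, m)
  fc_dataset(participants, fc, tiny_atlas(R), "tiny")
}

# fast simulation config for classifier / inference tests: small edge count,
# one balanced site, optional planted effect
fast_sim <- function(R = 10, n0 = 20, n1 = 20, n_effect = 0, d = 1,
                     seed = 1, additive_sd = 0, mult = c(1, 1)) {
  sim_config(R = R,
             sites = list(sim_site("Z1", n0, n1, additive_sd = additive_sd,
                                   multiplicative_range = mult)),
             n_effect_edges = n_effect, effect_size = d,
             n_covariate_edges = 0, seed = seed)
}

# reduced ensemble settings used when a test needs many retrains
fast_train <- function(dataset, seed = 1, k_folds = 2, n_subsamples = 1,
                       inner_folds = 2, n_lambda = 10) {
  train_ensemble(dataset, k_folds = k_folds, n_subsamples = n_subsamples,
                 inner_folds = inner_folds, n_lambda = n_lambda, seed = seed)
}

# build a discriminative_fc_set by hand (for tests that need known sets)
fake_dfc <- function(hyper, hypo, m) {
  sig <- sort(c(hyper, hypo))
  tab <- data.frame(edge = seq_len(m) - 1L, count = 0L, p = 1,
                    mean_weight = 0, class = NA_character_,
                    stringsAsFactors = FALSE)
  tab$class[hyper + 1L] <- "hyper"; tab$mean_weight[hyper + 1L] <- 1
  tab$class[hypo + 1L] <- "hypo"; tab$mean_weight[hypo + 1L] <- -1
  structure(list(table = tab, significant = sig, hyper = hyper, hypo = hypo,
                 null_max = numeric(0), B = 0L, alpha = 0.05),
            class = "discriminative_fc_set")
}
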