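#' Per-edge diagnosis effect (two-sample t-values)
#'
#' Mass-univariate between-group difference at every edge: the two-sample
#' t-statistic with the sign convention patient minus control. The default
#' is the Student pooled-variance statistic; Welch's unequal-variance
#' variant is available behind `var_equal = FALSE`.
#'
#' @param dataset An [fc_dataset()] with >= 2 subjects per group.
#' @param var_equal Pooled-variance (TRUE, default) or Welch.
#' @return A list of class `effect_vector`: `t` (length m, patient minus
#'   control), `df`, `dataset` name, `flagged` (edges with zero variance in
#'   both groups, where t is set to 0).
#' @export
diagnosis_t <- function(dataset, var_equal = TRUE) {
  y <- dataset$participants$diagnosis
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("both groups need >= 2 subjects", call. = FALSE)
  X1 <- dataset$fc[y == 1, , drop = FALSE]
  X0 <- dataset$fc[y == 0, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(X0, 2, m0)^2) / (n0 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- unname((m1 - m0) / se)
  flagged <- which(unname(se) == 0)
  t[flagged] <- 0
  structure(list(t = t, df = df, dataset = dataset$name,
                 flagged = flagged - 1L),
            class = "effect_vector")
}

#' Cross-dataset correlation of diagnosis effects
#'
#' Pearson correlation between a reference per-edge t-vector and the
#' t-vector of a second dataset, with a one-sided permutation test: at
#' each iteration the second dataset's diagnosis labels are shuffled, its
#' t-vector recomputed, and correlated with the fixed reference;
#' `p = (1 + #\{null r >= observed\}) / (1 + B)`.
#'
#' @param a An `effect_vector` (e.g. from the discovery dataset).
#' @param b_dataset The second [fc_dataset()].
#' @param B Number of permutations (reference design: 1,000).
#' @param seed Integer seed.
#' @return A list `r` (observed), `p` (one-sided), `null` (length B),
#'   `B`.
#' @export
cross_dataset_correlation <- function(a, b_dataset, B = 1000, seed = 1) {
  tb <- diagnosis_t(b_dataset)
  if (length(a$t) != length(tb$t))
    stop("edge count mismatch between effect vectors", call. = FALSE)
  if (stats::sd(a$t) == 0 || stats::sd(tb$t) == 0)
    stop("degenerate (constant) t-vector", call. = FALSE)
  r_obs <- stats::cor(a$t, tb$t)
  null <- numeric(B)
  perm <- b_dataset
  for (b in seq_len(B)) {
    perm$participants$diagnosis <- with_seed(
      derive_seed(seed, b), sample(b_dataset$participants$diagnosis))
    null[b] <- stats::cor(a$t, diagnosis_t(perm)$t)
  }
  list(r = r_obs, p = perm_pvalue(r_obs, null), null = null, B = B)
}

#' Count edges with a consistent effect sign across datasets
#'
#' An edge is consistent when its t-value carries the same strict sign in
#' every supplied effect vector; a zero anywhere breaks consistency.
#'
#' @param effects List of `effect_vector`s (>= 2) of equal length.
#' @param subset Optional 0-based edge indices to restrict the count to.
#' @return Integer count of consistent edges.
#' @export
sign_consistency <- function(effects, subset = NULL) {
  if (length(effects) < 2) stop("need >= 2 effect vectors", call. = FALSE)
  lens <- vapply(effects, function(e) length(e$t), numeric(1))
  if (length(unique(lens)) != 1) stop("effect vectors differ in length",
                                      call. = FALSE)
  tmat <- vapply(effects, `[[`, numeric(lens[1]), "t")
  if (is.null(dim(tmat))) tmat <- matrix(tmat, nrow = 1)
  consistent <- rowSums(tmat > 0) == ncol(tmat) |
    rowSums(tmat < 0) == ncol(tmat)
  if (!is.null(subset)) consistent <- consistent[subset + 1L]
  sum(consistent)
}

#' Exact binomial test of sign-consistency enrichment
#'
#' Tests whether the number of sign-consistent edges within a
#' discriminative set exceeds what the whole-connectome consistency rate
#' predicts: the upper tail `P(X >= x_set)` for
#' `X ~ Binomial(n_set, K_whole / M_whole)`, computed exactly.
#'
#' @param x_set Consistent edges within the set.
#' @param n_set Size of the set.
#' @param K_whole Consistent edges over the whole connectome.
#' @param M_whole Total number of edges.
#' @return The exact upper-tail p-value.
#' @export
binomial_consistency_test <- function(x_set, n_set, K_whole, M_whole) {
  if (x_set < 0 || x_set > n_set) stop("need 0 <= x_set <= n_set",
                                       call. = FALSE)
  if (M_whole <= 0 || K_whole > M_whole || K_whole < 0)
    stop("need 0 <= K_whole <= M_whole, M_whole > 0", call. = FALSE)
  if (K_whole == 0) return(if (x_set > 0) 0 else 1)
  if (x_set == 0) return(1)
  stats::pbinom(x_set - 1, n_set, K_whole / M_whole, lower.tail = FALSE)
}
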