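#' Resting-state-network category of edges
#'
#' Maps each edge to the unordered pair of network labels of its two ROIs;
#' within-network edges get the pair `net-net`. Category labels are the
#' two sorted network names joined by `-`, so `DMN-visual` and
#' `visual-DMN` are the same category.
#'
#' @param edges 0-based edge indices.
#' @param atlas An [fc_atlas()].
#' @return Character vector of category labels.
#' @export
edge_category <- function(edges, atlas) {
  R <- nrow(atlas)
  pair <- edge_roi_pair(edges, R)
  ni <- atlas$network[pair[, "i"] + 1L]
  nj <- atlas$network[pair[, "j"] + 1L]
  if (anyNA(ni) || anyNA(nj)) stop("unlabeled ROI in atlas", call. = FALSE)
  paste(pmin(ni, nj), pmax(ni, nj), sep = "-")
}

#' Category of every edge of an atlas
#' @param atlas An [fc_atlas()].
#' @return Character vector of length `edge_count(nrow(atlas))`.
#' @export
edge_categories <- function(atlas) {
  edge_category(seq_len(edge_count(nrow(atlas))) - 1L, atlas)
}

#' Hypergeometric enrichment of an edge set in a network category
#'
#' Over-representation of a set of edges (e.g. the hyper-connections of a
#' marker) in one within- or between-network category, with the printed
#' tail convention `p = 1 - HypergeometricCDF(x; M, K, n) = P(X > x)`
#' where `x` is the overlap, `M` the total edge count, `K` the category
#' size and `n` the set size. This strict tail is never anti-conservative
#' relative to the conventional `P(X >= x)`; the latter is available via
#' `tail = "geq"`.
#'
#' @param edge_set 0-based edge indices.
#' @param category Category label (as produced by [edge_category()]).
#' @param atlas An [fc_atlas()].
#' @param tail `"greater"` for `P(X > x)` (default, printed convention) or
#'   `"geq"` for `P(X >= x)`.
#' @return A list of class `enrichment_result`: `category`, `x`, `M`, `K`,
#'   `n`, `p`.
#' @export
enrichment_test <- function(edge_set, category, atlas,
                            tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  cats <- edge_categories(atlas)
  M <- length(cats)
  K <- sum(cats == category)
  n <- length(edge_set)
  if (n > M || K > M) stop("parameter error: set larger than universe",
                           call. = FALSE)
  x <- sum(cats[edge_set + 1L] == category)
  q <- if (tail == "greater") x else x - 1
  p <- stats::phyper(q, K, M - K, n, lower.tail = FALSE)
  structure(list(category = category, x = x, M = M, K = K, n = n, p = p,
                 tail = tail),
            class = "enrichment_result")
}

#' Network enrichment of a discriminative edge set
#'
#' Runs [enrichment_test()] for every network category, separately for the
#' hyper- and hypo-connection sets, and applies a Bonferroni correction
#' over (categories x 2 classes).
#'
#' @param dfc A `discriminative_fc_set` (see
#'   [identify_discriminative_fcs()]).
#' @param atlas An [fc_atlas()].
#' @param alpha Familywise level before Bonferroni division.
#' @param tail Tail convention, as in [enrichment_test()].
#' @return A data.frame: `class`, `category`, `x`, `K`, `n`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
network_enrichment <- function(dfc, atlas, alpha = 0.05,
                               tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  cats <- sort(unique(edge_categories(atlas)))
  n_tests <- length(cats) * 2
  rows <- list()
  for (class_ in c("hyper", "hypo")) {
    set <- dfc[[class_]]
    for (cc in cats) {
      e <- enrichment_test(set, cc, atlas, tail)
      rows[[length(rows) + 1L]] <- data.frame(
        class = class_, category = cc, x = e$x, K = e$K, n = e$n, p = e$p,
        p_bonferroni = min(1, e$p * n_tests),
        significant = e$p < alpha / n_tests, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
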