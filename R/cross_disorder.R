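#' Sensitivity of a marker to another disorder's patients
#'
#' Applies the marker ensemble to the patients of a foreign disorder
#' (harmonized separately beforehand) and reports the fraction labeled
#' positive (mean diagnostic probability strictly above 0.5). Significance
#' comes from the permutation null: label-shuffled ensembles retrained on
#' the marker's own discovery data and applied to the same foreign
#' patients.
#'
#' @param ensemble The trained `marker_ensemble`.
#' @param foreign An [fc_dataset()] containing the foreign disorder
#'   (subjects with `diagnosis == 1` are used).
#' @param discovery The marker's discovery dataset (needed to retrain
#'   permuted ensembles unless `null_sens` is given).
#' @param B Permutations (reference design: 500).
#' @param seed Integer seed.
#' @param null_sens Optional precomputed null sensitivities to reuse.
#' @return A list: `sensitivity`, `p`, `null`, `n_patients`.
#' @export
cross_sensitivity <- function(ensemble, foreign, discovery = NULL, B = 500,
                              seed = 1, null_sens = NULL) {
  pat <- foreign$participants$diagnosis == 1
  if (!any(pat)) stop("foreign dataset has no patients", call. = FALSE)
  Xp <- foreign$fc[pat, , drop = FALSE]
  sens <- mean(predict(ensemble, Xp)$probability > 0.5)
  if (is.null(null_sens)) {
    if (is.null(discovery))
      stop("either 'discovery' or 'null_sens' must be supplied", call. = FALSE)
    eng <- permutation_engine(discovery, ensemble, B, seed,
      list(sens = function(ens, labels) c(s = mean(predict(ens, Xp)$probability > 0.5))))
    null_sens <- as.numeric(eng$stats[, 1])
  }
  list(sensitivity = sens, p = perm_pvalue(sens, null_sens),
       null = null_sens, n_patients = sum(pat))
}

#' Two-marker dimensional map
#'
#' Projects every subject of each supplied group onto the plane spanned by
#' two markers' diagnostic probabilities, assigns quadrants by strict
#' comparison to 0.5 on each axis (a subject exactly at 0.5 falls on the
#' low side), and reports per-group quadrant counts and the modal
#' quadrant.
#'
#' @param markerA,markerB Trained `marker_ensemble`s sharing the edge
#'   dimensionality of the data.
#' @param datasets Named list of [fc_dataset()]s (one per group; all
#'   subjects of each dataset are projected).
#' @return A list of class `cross_disorder_map`: `coordinates` (data.frame
#'   `group`, `subject_id`, `p_A`, `p_B`, `quadrant`), `quadrant_counts`
#'   (groups x 4 matrix), `modal_quadrant` (named character).
#' @export
dimensional_map <- function(markerA, markerB, datasets) {
  rows <- list()
  for (nm in names(datasets)) {
    pa <- predict(markerA, datasets[[nm]])$probability
    pb <- predict(markerB, datasets[[nm]])$probability
    quad <- ifelse(pa > 0.5,
                   ifelse(pb > 0.5, "high-high", "high-low"),
                   ifelse(pb > 0.5, "low-high", "low-low"))
    rows[[nm]] <- data.frame(group = nm,
                             subject_id = datasets[[nm]]$participants$subject_id,
                             p_A = pa, p_B = pb, quadrant = quad,
                             stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, rows)
  lv <- c("low-low", "low-high", "high-low", "high-high")
  counts <- t(vapply(names(datasets), function(nm)
    table(factor(rows[[nm]]$quadrant, levels = lv)), numeric(4)))
  colnames(counts) <- lv
  modal <- apply(counts, 1, function(x) lv[which.max(x)])
  structure(list(coordinates = coords, quadrant_counts = counts,
                 modal_quadrant = modal),
            class = "cross_disorder_map")
}

#' Correlation of diagnosis effects restricted to a marker's edges
#'
#' Within the hyper- (resp. hypo-) connections of a discriminative edge
#' set, correlates the per-edge diagnosis t-values of two disorders (each
#' against its own controls); significance by permuting the second
#' disorder's labels. A class with fewer than 3 edges is skipped with a
#' warning.
#'
#' @param dfc A `discriminative_fc_set` of the reference marker.
#' @param disA,disB [fc_dataset()]s of the two disorders.
#' @param B Permutations.
#' @param seed Integer seed.
#' @return A list with elements `hyper` and `hypo`, each `NULL` (skipped)
#'   or a list `r`, `p`, `n_edges`.
#' @export
effect_correlation_on_marker <- function(dfc, disA, disB, B = 1000, seed = 1) {
  tA <- diagnosis_t(disA)$t
  tB <- diagnosis_t(disB)$t
  out <- list()
  for (class_ in c("hyper", "hypo")) {
    edges <- dfc[[class_]]
    if (length(edges) < 3) {
      warning("class '", class_, "' has ", length(edges),
              " edges (< 3); skipped")
      out[[class_]] <- NULL
      next
    }
    r_obs <- stats::cor(tA[edges + 1L], tB[edges + 1L])
    null <- numeric(B)
    perm <- disB
    for (b in seq_len(B)) {
      perm$participants$diagnosis <- with_seed(
        derive_seed(seed, 500000 + b), sample(disB$participants$diagnosis))
      null[b] <- stats::cor(tA[edges + 1L], diagnosis_t(perm)$t[edges + 1L])
    }
    out[[class_]] <- list(r = r_obs, p = perm_pvalue(r_obs, null),
                          n_edges = length(edges))
  }
  out
}

#' Spatial overlap of two discriminative edge sets
#'
#' Counts shared edges and scores the overlap with the hypergeometric tail
#' used for network enrichment (`M` = total edges, `K` = \\|A\\|,
#' `n` = \\|B\\|).
#'
#' @param setA,setB `discriminative_fc_set`s or 0-based edge-index
#'   vectors over the same edge universe.
#' @param m Total number of edges (required when raw index vectors are
#'   given; inferred from `discriminative_fc_set`s).
#' @param tail Tail convention as in [enrichment_test()].
#' @return A list: `overlap` (count), `p`.
#' @export
spatial_overlap <- function(setA, setB, m = NULL,
                            tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  get <- function(s) if (inherits(s, "discriminative_fc_set"))
    list(e = s$significant, m = nrow(s$table)) else list(e = s, m = m)
  A <- get(setA); B <- get(setB)
  m <- unique(c(A$m, B$m)); m <- m[!is.na(m)]
  if (length(m) != 1)
    stop("edge universes differ (or 'm' missing)", call. = FALSE)
  x <- length(intersect(A$e, B$e))
  q <- if (tail == "greater") x else x - 1
  list(overlap = x,
       p = stats::phyper(q, length(A$e), m - length(A$e), length(B$e),
                         lower.tail = FALSE))
}
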