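#' Empirical-Bayes site-effect harmonization (ComBat)
#'
#' Removes per-site additive (location) and multiplicative (scale) effects
#' from every edge while preserving the covariates of interest (diagnosis,
#' age, sex), using the parametric empirical-Bayes location/scale model:
#' `y_ijv = alpha_v + X_ij beta_v + gamma_iv + delta_iv eps_ijv`.
#'
#' Fitting proceeds in the standard three steps: (1) feature-wise
#' standardization with the site intercepts constrained to a
#' sample-size-weighted zero sum; (2) parametric empirical Bayes with a
#' normal prior on the site locations `gamma_iv` and an inverse-gamma prior
#' on the site variances `delta_iv^2`, hyperparameters estimated across
#' edges by the method of moments; (3) iterated conditional posterior means
#' for the shrunk `gamma*`, `delta*^2` until the maximum absolute change
#' falls below `tol` (default 1e-4) or `max_iter` iterations. Adjusted
#' values are `y* = (sigma_v / delta*_iv) (z_ijv - gamma*_iv) + alpha_v +
#' X_ij beta_v`: covariate effects are re-added unchanged.
#'
#' Harmonization is a per-dataset operation: discovery and each validation
#' dataset must be harmonized separately, never jointly.
#'
#' A site whose subjects are all controls (or all patients) is allowed —
#' the diagnosis coefficient is then identified by the remaining sites —
#' but triggers a warning. A single-site dataset is returned unchanged with
#' a warning (there is no site effect to estimate).
#'
#' @param dataset An [fc_dataset()] with >= 2 sites of >= 2 subjects each.
#' @param covariates Character vector of participant columns to protect
#'   (default diagnosis, age, sex).
#' @param tol,max_iter Convergence control for the EB iterations.
#' @return A list with elements `dataset` (harmonized `fc_dataset`) and
#'   `model` (a `harmonization_model` holding `alpha`, `beta`, `sigma2`,
#'   naive `gamma_hat`/`delta2_hat`, shrunk `gamma_star`/`delta2_star`,
#'   per-site hyperparameters and convergence diagnostics).
#' @export
harmonize <- function(dataset, covariates = c("diagnosis", "age", "sex"),
                      tol = 1e-4, max_iter = 100) {
  p <- dataset$participants
  Y <- dataset$fc
  site <- factor(p$site)
  n <- nrow(Y); m <- ncol(Y)
  if (nlevels(site) < 2) {
    warning("single-site dataset '", dataset$name,
            "': returning data unchanged (no site effect to estimate)")
    return(list(dataset = dataset, model = structure(
      list(n_sites = 1L, identity = TRUE), class = "harmonization_model")))
  }
  tab <- table(site)
  if (any(tab < 2))
    stop("every site needs >= 2 subjects; offending site(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)

  miss <- setdiff(covariates, names(p))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  one_class <- tapply(p$diagnosis, site, function(d) length(unique(d)) == 1)
  if ("diagnosis" %in% covariates && any(one_class))
    warning("site(s) with a single diagnostic class (site effect still estimated): ",
            paste(names(one_class)[one_class], collapse = ", "))

  batch <- stats::model.matrix(~ site - 1)
  mod <- covariate_design(p, covariates)
  design <- cbind(batch, mod)
  q <- qr(design)
  if (q$rank < ncol(design))
    stop("covariates are collinear with site; cannot separate site effects",
         call. = FALSE)
  B_hat <- qr.coef(q, Y)                       # (n_sites + k) x m
  n_sites <- nlevels(site)
  n_i <- as.numeric(tab)
  alpha <- as.numeric(crossprod(n_i / n, B_hat[seq_len(n_sites), , drop = FALSE]))
  beta <- B_hat[-seq_len(n_sites), , drop = FALSE]
  fitted <- design %*% B_hat
  sigma2 <- colMeans((Y - fitted)^2)           # pooled MLE variance
  if (any(sigma2 <= 0))
    stop("degenerate (zero-variance) edge(s): ",
         paste(which(sigma2 <= 0) - 1L, collapse = ", "), call. = FALSE)

  stand_mean <- matrix(alpha, n, m, byrow = TRUE) +
    (if (ncol(mod)) mod %*% beta else 0)
  Z <- (Y - stand_mean) / matrix(sqrt(sigma2), n, m, byrow = TRUE)

  gamma_hat <- delta2_hat <- matrix(NA_real_, n_sites, m,
                                    dimnames = list(levels(site), NULL))
  for (i in seq_len(n_sites)) {
    Zi <- Z[site == levels(site)[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(Zi)
    delta2_hat[i, ] <- apply(Zi, 2, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  # inverse-gamma hyperparameters by method of moments
  dmean <- rowMeans(delta2_hat)
  dvar <- apply(delta2_hat, 1, stats::var)
  lambda <- (2 * dvar + dmean^2) / dvar        # shape
  theta <- (dmean * dvar + dmean^3) / dvar     # scale

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    Zi <- Z[site == levels(site)[i], , drop = FALSE]
    g <- gamma_hat[i, ]; d2 <- delta2_hat[i, ]
    for (it in seq_len(max_iter)) {
      g_new <- (n_i[i] * tau2[i] * gamma_hat[i, ] + d2 * gamma_bar[i]) /
        (n_i[i] * tau2[i] + d2)
      ss <- colSums((Zi - matrix(g_new, n_i[i], m, byrow = TRUE))^2)
      d2_new <- (theta[i] + 0.5 * ss) / (n_i[i] / 2 + lambda[i] - 1)
      change <- max(abs(g_new - g), abs(d2_new - d2))
      g <- g_new; d2 <- d2_new
      if (change < tol) break
    }
    iters[i] <- it
    gamma_star[i, ] <- g
    delta2_star[i, ] <- d2
  }

  idx <- as.integer(site)
  Y_adj <- (Z - gamma_star[idx, , drop = FALSE]) /
    sqrt(delta2_star[idx, , drop = FALSE]) *
    matrix(sqrt(sigma2), n, m, byrow = TRUE) + stand_mean

  model <- structure(list(
    n_sites = n_sites, sites = levels(site), n_per_site = n_i,
    covariates = covariates, alpha = alpha, beta = beta, sigma2 = sigma2,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta,
    iterations = iters, tol = tol, identity = FALSE),
    class = "harmonization_model")
  out <- dataset
  out$fc <- Y_adj
  list(dataset = out, model = model)
}

#' @export
print.harmonization_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<harmonization_model> identity (single site)\n")
  } else {
    cat(sprintf("<harmonization_model> %d sites, %d edges; EB iterations: %s\n",
                x$n_sites, length(x$alpha), paste(x$iterations, collapse = "/")))
  }
  invisible(x)
}

covariate_design <- function(p, covariates) {
  cols <- lapply(covariates, function(cv) {
    x <- p[[cv]]
    if (cv == "sex") sex_numeric(x) else as.numeric(x)
  })
  mod <- do.call(cbind, cols)
  if (is.null(mod)) mod <- matrix(0, nrow(p), 0)
  colnames(mod) <- covariates
  # drop constant covariates (e.g. single-sex toy data)
  keep <- apply(mod, 2, function(x) stats::var(x) > 0)
  mod[, keep, drop = FALSE]
}

#' Per-edge site-effect ANOVA
#'
#' Covariate-adjusted one-way ANOVA of each edge on site: an F-test
#' comparing the design with site terms against the covariate-only design.
#' Used as the diagnostic for how much site signal remains before/after
#' harmonization.
#'
#' @param dataset An [fc_dataset()] with >= 2 sites.
#' @param covariates Covariate columns to adjust for.
#' @return A data.frame with one row per edge: `edge` (0-based),
#'   `F`, `p`, and a `flagged` marker for degenerate edges.
#' @export
site_effect_summary <- function(dataset, covariates = c("diagnosis", "age", "sex")) {
  p <- dataset$participants
  site <- factor(p$site)
  if (nlevels(site) < 2) stop("need >= 2 sites", call. = FALSE)
  Y <- dataset$fc
  n <- nrow(Y)
  mod <- cbind(1, covariate_design(p, covariates))
  full <- cbind(stats::model.matrix(~ site - 1), mod[, -1, drop = FALSE])
  rss <- function(X) {
    q <- qr(X)
    colSums((Y - X %*% qr.coef(q, Y))^2)
  }
  rss0 <- rss(mod)
  rss1 <- rss(full)
  df1 <- qr(full)$rank - qr(mod)$rank
  df2 <- n - qr(full)$rank
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  flagged <- !is.finite(Fstat) | rss1 <= 0
  Fstat[flagged] <- NA_real_
  data.frame(edge = seq_len(ncol(Y)) - 1L, F = Fstat,
             p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
             flagged = flagged)
}
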