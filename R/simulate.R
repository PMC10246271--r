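#' Describe one imaging site for the simulator
#'
#' @param site_id Site label.
#' @param n_control,n_patient Subject counts (their sum must be >= 2; a
#'   patient-free site is allowed and mirrors real discovery cohorts whose
#'   control-only sites contribute no cases).
#' @param additive_sd Standard deviation of the per-edge additive site
#'   effect (the generative analogue of ComBat's location term).
#' @param multiplicative_range Length-2 positive bounds of the uniform draw
#'   for the per-edge residual scale factor (ComBat's scale term).
#' @return A `sim_site` list.
#' @export
sim_site <- function(site_id, n_control, n_patient, additive_sd = 0.5,
                     multiplicative_range = c(0.8, 1.25)) {
  if (n_control + n_patient < 2)
    stop("site '", site_id, "' needs at least 2 subjects", call. = FALSE)
  if (length(multiplicative_range) != 2 || any(multiplicative_range <= 0) ||
      diff(multiplicative_range) < 0)
    stop("multiplicative_range must be positive bounds (lo, hi)", call. = FALSE)
  if (additive_sd < 0) stop("additive_sd must be >= 0", call. = FALSE)
  structure(list(site_id = as.character(site_id),
                 n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 additive_sd = additive_sd,
                 multiplicative_range = multiplicative_range),
            class = "sim_site")
}

#' Simulation configuration for multi-site connectivity data
#'
#' The generative model per subject j at site i and edge v is
#' `y = baseline_v + diagnosis * d_v * noise_sd + age * beta_age_v +
#'  sex * beta_sex_v + gamma_iv + delta_iv * eps`, `eps ~ N(0, noise_sd^2)`,
#' with `gamma_iv ~ N(0, additive_sd_i^2)` and `delta_iv` uniform on the
#' site's multiplicative range — i.e. exactly the location/scale structure
#' that empirical-Bayes harmonization assumes, plus a sparse set of edges
#' carrying a signed diagnosis effect of `d_v` noise-sd units (Cohen's d at
#' unit scale factor).
#'
#' Defaults describe the desk-scale world used throughout the test-suite:
#' 50 ROIs (1,225 edges), three sites of 110 controls / 36 patients
#' (mirroring a 550/180-scale imbalanced multi-site cohort at ~1/5 size),
#' 30 effect edges at |d| = 0.8 with random signs, additive site sd 0.5
#' equal to the residual sd 0.5 (site effects comparable to between-subject
#' variability), and mild age/sex slopes on 50 edges each.
#'
#' @param R Number of ROIs.
#' @param sites List of [sim_site()] specs.
#' @param n_effect_edges,effect_size Number of edges carrying a diagnosis
#'   effect and its magnitude in noise-sd units (scalar, signs randomised;
#'   or a signed vector of length `n_effect_edges`).
#' @param sign_share Fraction of effect edges whose sign is preserved when
#'   deriving validation datasets with [simulate_family()].
#' @param n_covariate_edges Number of edges receiving age and sex slopes.
#' @param beta_age,beta_sex Covariate slope magnitudes (z units per year /
#'   per male).
#' @param noise_sd Residual standard deviation on the Fisher-z scale.
#' @param age_range Uniform age range for simulated adults.
#' @param seed Integer seed; every draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(R = 50,
                       sites = list(sim_site("S1", 110, 36),
                                    sim_site("S2", 110, 36),
                                    sim_site("S3", 110, 36)),
                       n_effect_edges = 30, effect_size = 0.8,
                       sign_share = 1,
                       n_covariate_edges = 50,
                       beta_age = 0.005, beta_sex = 0.1,
                       noise_sd = 0.5, age_range = c(18, 60), seed = 1) {
  m <- edge_count(R)
  if (n_effect_edges > m)
    stop("config error: more effect edges than edges (", n_effect_edges,
         " > ", m, ")", call. = FALSE)
  if (sign_share < 0 || sign_share > 1)
    stop("sign_share must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(effect_size) > 1 && length(effect_size) != n_effect_edges)
    stop("effect_size must be scalar or length n_effect_edges", call. = FALSE)
  structure(list(R = R, m = m, sites = sites,
                 n_effect_edges = as.integer(n_effect_edges),
                 effect_size = effect_size, sign_share = sign_share,
                 n_covariate_edges = as.integer(n_covariate_edges),
                 beta_age = beta_age, beta_sex = beta_sex,
                 noise_sd = noise_sd, age_range = age_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw the dataset-level truth (baseline, effect edges/sizes, covariate
# slopes) that is shared between a discovery dataset and its derivatives.
draw_truth <- function(config) {
  m <- config$m
  with_seed(derive_seed(config$seed, 1), {
    baseline <- stats::rnorm(m, 0.25, 0.25)
    effect_edges <- sort(sample.int(m, config$n_effect_edges)) - 1L
    d <- numeric(m)
    if (config$n_effect_edges > 0) {
      es <- config$effect_size
      if (length(es) == 1)
        es <- es * sample(c(-1, 1), config$n_effect_edges, replace = TRUE)
      d[effect_edges + 1L] <- es
    }
    beta_age <- beta_sex <- numeric(m)
    if (config$n_covariate_edges > 0) {
      age_edges <- sample.int(m, min(config$n_covariate_edges, m))
      sex_edges <- sample.int(m, min(config$n_covariate_edges, m))
      beta_age[age_edges] <- config$beta_age *
        sample(c(-1, 1), length(age_edges), replace = TRUE)
      beta_sex[sex_edges] <- config$beta_sex *
        sample(c(-1, 1), length(sex_edges), replace = TRUE)
    }
    list(baseline = baseline, effect_edges = effect_edges, d = d,
         beta_age = beta_age, beta_sex = beta_sex)
  })
}

# Generate subjects for one site given the dataset truth.
gen_site <- function(site, truth, config, seed, id_prefix) {
  n <- site$n_control + site$n_patient
  with_seed(seed, {
    gamma <- stats::rnorm(config$m, 0, site$additive_sd)
    delta <- stats::runif(config$m, site$multiplicative_range[1],
                          site$multiplicative_range[2])
    diagnosis <- c(rep(0L, site$n_control), rep(1L, site$n_patient))
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    eps <- matrix(stats::rnorm(n * config$m, 0, config$noise_sd), n, config$m)
    fc <- matrix(truth$baseline, n, config$m, byrow = TRUE) +
      outer(diagnosis, truth$d * config$noise_sd) +
      outer(age, truth$beta_age) +
      outer(sex_numeric(sex), truth$beta_sex) +
      matrix(gamma, n, config$m, byrow = TRUE) +
      eps * matrix(delta, n, config$m, byrow = TRUE)
    participants <- data.frame(
      subject_id = sprintf("%s%s_%03d", id_prefix, site$site_id, seq_len(n)),
      site = site$site_id, diagnosis = diagnosis, age = age, sex = sex,
      stringsAsFactors = FALSE)
    list(participants = participants, fc = fc, gamma = gamma, delta = delta)
  })
}

#' Simulate one multi-site connectivity dataset
#'
#' Draws the generative truth (see [sim_config()]) and subject-level data,
#' and attaches the truth — effect edges and sizes, per-site location/scale
#' effects, covariate slopes and the seed — as `attr(dataset, "truth")` so
#' downstream recovery tests can score against it.
#'
#' @param config A [sim_config()].
#' @param name Dataset name.
#' @return An [fc_dataset()] with a `"truth"` attribute.
#' @export
simulate_fc_dataset <- function(config, name = "discovery") {
  truth <- draw_truth(config)
  parts <- lapply(seq_along(config$sites), function(k)
    gen_site(config$sites[[k]], truth, config, derive_seed(config$seed, 100 + k),
             paste0(name, "_")))
  participants <- do.call(rbind, lapply(parts, `[[`, "participants"))
  fc <- do.call(rbind, lapply(parts, `[[`, "fc"))
  ds <- fc_dataset(participants, fc, default_atlas(config$R), name)
  truth$gamma <- do.call(rbind, lapply(parts, `[[`, "gamma"))
  truth$delta <- do.call(rbind, lapply(parts, `[[`, "delta"))
  rownames(truth$gamma) <- rownames(truth$delta) <-
    vapply(config$sites, `[[`, "", "site_id")
  truth$seed <- config$seed
  truth$config <- config
  attr(ds, "truth") <- truth
  ds
}

#' Simulate a discovery dataset plus independent validation datasets
#'
#' Validation datasets share the discovery effect edges but get fresh sites
#' (new location/scale effects), fresh subjects, per-dataset attenuation of
#' the effect sizes (e.g. weaker effects in younger cohorts), and keep the
#' discovery sign on each effect edge independently with probability
#' `sign_share` (flipping it otherwise) — the planted analogue of diagnosis
#' effects that reproduce across cohorts.
#'
#' @param config A [sim_config()]; `config$sign_share` governs sign
#'   preservation.
#' @param n_validation Number of validation datasets (>= 1).
#' @param attenuation Effect-size multipliers, recycled to `n_validation`.
#' @param stages Developmental stage per validation dataset
#'   (`"adult"`, `"adolescent"` or `"child"`), controlling the age range.
#' @return Named list of [fc_dataset()]s: `discovery`,
#'   `validation1`, ...; each carries its own `"truth"`.
#' @export
simulate_family <- function(config, n_validation = 2, attenuation = 1,
                            stages = "adult") {
  stopifnot(n_validation >= 1)
  attenuation <- rep_len(attenuation, n_validation)
  stages <- rep_len(stages, n_validation)
  discovery <- simulate_fc_dataset(config, "discovery")
  truth <- attr(discovery, "truth")
  out <- list(discovery = discovery)
  for (k in seq_len(n_validation)) {
    vname <- paste0("validation", k)
    vcfg <- config
    vcfg$seed <- derive_seed(config$seed, 1000 + k)
    vcfg$age_range <- switch(stages[k], child = c(6, 11.9),
                             adolescent = c(12.1, 17.9), config$age_range)
    vtruth <- truth[c("baseline", "effect_edges", "d", "beta_age", "beta_sex")]
    vtruth$d <- vtruth$d * attenuation[k]
    flip <- with_seed(derive_seed(vcfg$seed, 7), {
      stats::runif(length(truth$effect_edges)) > config$sign_share
    })
    vtruth$d[truth$effect_edges + 1L][flip] <- -vtruth$d[truth$effect_edges + 1L][flip]
    vtruth$flipped_edges <- truth$effect_edges[flip]
    parts <- lapply(seq_along(vcfg$sites), function(j)
      gen_site(vcfg$sites[[j]], vtruth, vcfg, derive_seed(vcfg$seed, 100 + j),
               paste0(vname, "_")))
    participants <- do.call(rbind, lapply(parts, `[[`, "participants"))
    fc <- do.call(rbind, lapply(parts, `[[`, "fc"))
    ds <- fc_dataset(participants, fc, discovery$atlas, vname)
    vtruth$gamma <- do.call(rbind, lapply(parts, `[[`, "gamma"))
    vtruth$delta <- do.call(rbind, lapply(parts, `[[`, "delta"))
    vtruth$seed <- vcfg$seed
    attr(ds, "truth") <- vtruth
    out[[vname]] <- ds
  }
  out
}

#' Simulate two disorders with partially overlapping edge effects
#'
#' Disorder B's effect-edge set shares a fraction `overlap` of disorder A's
#' set (with the same signs on the shared edges); the remainder is drawn
#' disjointly from A's. The control group is identical across the two
#' returned datasets, matching designs where one shared control cohort
#' serves several patient groups.
#'
#' @param config A [sim_config()] (its effect spec describes disorder A).
#' @param overlap Fraction in \[0, 1\] of A's effect edges shared by B.
#' @param n_effect_edges_B Size of B's effect set (default: same as A's).
#' @param effect_size_B Magnitude of B's effects (default: A's scalar size).
#' @return Named list of two [fc_dataset()]s (`A`, `B`) with identical
#'   control subjects; each carries its `"truth"` including the shared and
#'   disorder-specific edge sets.
#' @export
simulate_disorders <- function(config, overlap = 0, n_effect_edges_B = NULL,
                               effect_size_B = NULL) {
  if (overlap < 0 || overlap > 1)
    stop("overlap must lie in [0, 1]", call. = FALSE)
  truthA <- draw_truth(config)
  nA <- length(truthA$effect_edges)
  nB <- if (is.null(n_effect_edges_B)) nA else as.integer(n_effect_edges_B)
  n_shared <- round(overlap * min(nA, nB))
  if (nB - n_shared > config$m - nA)
    stop("config error: disorder B needs ", nB - n_shared,
         " disjoint edges but only ", config$m - nA, " are free", call. = FALSE)
  esB <- if (is.null(effect_size_B)) {
    if (length(config$effect_size) == 1) config$effect_size
    else mean(abs(config$effect_size))
  } else effect_size_B
  truthB <- truthA[c("baseline", "beta_age", "beta_sex")]
  with_seed(derive_seed(config$seed, 5), {
    shared <- if (n_shared > 0) sort(sample(truthA$effect_edges, n_shared))
              else integer(0)
    free <- setdiff(0:(config$m - 1L), truthA$effect_edges)
    own <- if (nB - n_shared > 0) sort(sample(free, nB - n_shared))
           else integer(0)
    truthB$effect_edges <- sort(c(shared, own))
    dB <- numeric(config$m)
    dB[shared + 1L] <- sign(truthA$d[shared + 1L]) * esB
    dB[own + 1L] <- esB * sample(c(-1, 1), length(own), replace = TRUE)
    truthB$d <- dB
    truthB$shared_edges <- shared
  })

  # one control pool + per-disorder patients, same sites and site effects;
  # controls generated once from disorder-A truth (d only affects patients)
  ctrl_sites <- lapply(seq_along(config$sites), function(k) {
    site <- config$sites[[k]]
    csite <- site; csite$n_patient <- 0L
    gen_site(csite, truthA, config, derive_seed(config$seed, 200 + k), "ctl_")
  })
  pat_sites <- function(truth, label, base) {
    lapply(seq_along(config$sites), function(k) {
      site <- config$sites[[k]]
      if (site$n_patient == 0) return(NULL)
      psite <- site; psite$n_control <- 0L
      g <- with_seed(derive_seed(config$seed, 200 + k), {
        # reuse the site's gamma/delta draws, then fresh patient draws
        gamma <- stats::rnorm(config$m, 0, site$additive_sd)
        delta <- stats::runif(config$m, site$multiplicative_range[1],
                              site$multiplicative_range[2])
        list(gamma = gamma, delta = delta)
      })
      n <- site$n_patient
      with_seed(derive_seed(config$seed, base + k), {
        age <- stats::runif(n, config$age_range[1], config$age_range[2])
        sex <- sample(c("F", "M"), n, replace = TRUE)
        eps <- matrix(stats::rnorm(n * config$m, 0, config$noise_sd), n, config$m)
        fc <- matrix(truth$baseline, n, config$m, byrow = TRUE) +
          matrix(truth$d * config$noise_sd, n, config$m, byrow = TRUE) +
          outer(age, truth$beta_age) +
          outer(sex_numeric(sex), truth$beta_sex) +
          matrix(g$gamma, n, config$m, byrow = TRUE) +
          eps * matrix(g$delta, n, config$m, byrow = TRUE)
        list(participants = data.frame(
               subject_id = sprintf("%s_%s_%03d", label, site$site_id, seq_len(n)),
               site = site$site_id, diagnosis = 1L, age = age, sex = sex,
               stringsAsFactors = FALSE),
             fc = fc, gamma = g$gamma, delta = g$delta)
      })
    })
  }
  assemble <- function(truth, label, base) {
    pats <- Filter(Negate(is.null), pat_sites(truth, label, base))
    participants <- rbind(do.call(rbind, lapply(ctrl_sites, `[[`, "participants")),
                          do.call(rbind, lapply(pats, `[[`, "participants")))
    fc <- rbind(do.call(rbind, lapply(ctrl_sites, `[[`, "fc")),
                do.call(rbind, lapply(pats, `[[`, "fc")))
    ds <- fc_dataset(participants, fc, default_atlas(config$R), label)
    truth$seed <- config$seed
    attr(ds, "truth") <- truth
    ds
  }
  list(A = assemble(truthA, "A", 300), B = assemble(truthB, "B", 400))
}

#' Simulate ROI time series with a target correlation structure
#'
#' Draws stationary Gaussian frames with the requested correlation matrix
#' and a framewise-displacement trace whose spikes exceed the 0.5 mm
#' censoring threshold with the stated probability. The truth (target
#' matrix, spike frames) is attached for recovery tests.
#'
#' @param target_correlation Symmetric positive semidefinite matrix.
#' @param n_frames Number of frames.
#' @param fd_spike_prob Per-frame probability of a >0.5 mm spike.
#' @param seed Integer seed.
#' @param tr_seconds Repetition time in seconds.
#' @return A `roi_timeseries` (see [roi_timeseries()]) with a `"truth"`
#'   attribute listing `target` and `spike_frames`.
#' @export
simulate_roi_timeseries <- function(target_correlation, n_frames = 200,
                                    fd_spike_prob = 0, seed = 1,
                                    tr_seconds = 2) {
  S <- as.matrix(target_correlation)
  if (!isSymmetric(S, tol = 1e-8))
    stop("target correlation must be symmetric", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("target correlation must be positive semidefinite", call. = FALSE)
  vals <- pmax(ev$values, 0)
  sqrtS <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
  R <- nrow(S)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_frames * R), n_frames, R)
    X <- Z %*% sqrtS
    fd <- stats::runif(n_frames, 0.02, 0.3)
    spikes <- which(stats::runif(n_frames) < fd_spike_prob)
    fd[spikes] <- stats::runif(length(spikes), 0.55, 1.5)
    ts <- roi_timeseries(X, tr_seconds = tr_seconds, fd_trace = fd)
    attr(ts, "truth") <- list(target = S, spike_frames = spikes, seed = seed)
    ts
  })
}
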