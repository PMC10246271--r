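test_that("simulation is reproducible from its seed", {
  cfg <- fast_sim(n_effect = 5, seed = 33)
  a <- simulate_fc_dataset(cfg)
  b <- simulate_fc_dataset(cfg)
  expect_identical(a$fc, b$fc)
  expect_identical(a$participants, b$participants)
  expect_identical(attr(a, "truth")$effect_edges, attr(b, "truth")$effect_edges)
  cfg2 <- cfg; cfg2$seed <- 34L
  expect_false(identical(simulate_fc_dataset(cfg2)$fc, a$fc))
})

test_that("with no site or diagnosis effects, per-edge t-values follow the central t law", {
  # distributional oracle: pure N(0, noise_sd^2) noise => pooled two-sample
  # t per edge ~ t(n-2); check via KS on the probability transform
  cfg <- sim_config(R = 33, sites = list(sim_site("O1", 250, 250,
                                                  additive_sd = 0,
                                                  multiplicative_range = c(1, 1))),
                    n_effect_edges = 0, n_covariate_edges = 0, seed = 11)
  ds <- simulate_fc_dataset(cfg)
  tv <- diagnosis_t(ds)
  expect_gte(length(tv$t), 500)
  u <- pt(tv$t, df = tv$df[1])
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("planted effect edges carry larger |t| than null edges", {
  cfg <- fast_sim(R = 20, n0 = 100, n1 = 100, n_effect = 20, d = 1, seed = 2)
  ds <- simulate_fc_dataset(cfg)
  tr <- attr(ds, "truth")
  tv <- abs(diagnosis_t(ds)$t)
  expect_gt(mean(tv[tr$effect_edges + 1]), mean(tv[-(tr$effect_edges + 1)]))
})

test_that("validation datasets reproduce, attenuate, or flip the planted effects", {
  cfg <- sim_config(R = 15, sites = list(sim_site("F1", 60, 60)),
                    n_effect_edges = 20, effect_size = 1, sign_share = 1,
                    n_covariate_edges = 0, seed = 5)
  fam <- simulate_family(cfg, n_validation = 1, attenuation = 1)
  ee <- attr(fam$discovery, "truth")$effect_edges + 1
  td <- diagnosis_t(fam$discovery)$t
  tv <- diagnosis_t(fam$validation1)$t
  expect_gt(cor(td[ee], tv[ee]), 0)

  # attenuation 0: validation effect edges look null
  fam0 <- simulate_family(cfg, n_validation = 1, attenuation = 0)
  tv0 <- abs(diagnosis_t(fam0$validation1)$t)
  expect_lt(mean(tv0[ee]), mean(abs(td[ee])) / 2)
  expect_lt(abs(mean(tv0[ee]) - mean(tv0[-ee])), 0.5)

  # sign_share = 0.5 flips each effect edge with probability 1/2:
  # Monte-Carlo over 50 seeds, 40 effect edges each
  cfg2 <- sim_config(R = 10, sites = list(sim_site("F1", 5, 5)),
                     n_effect_edges = 40, effect_size = 1, sign_share = 0.5,
                     n_covariate_edges = 0, seed = 1)
  flips <- vapply(1:50, function(s) {
    cfg2$seed <- s
    fam <- simulate_family(cfg2, n_validation = 1)
    length(attr(fam$validation1, "truth")$flipped_edges)
  }, numeric(1))
  # X ~ Bi(40, .5) per seed: mean 20, sd of the 50-seed mean = 3.16/sqrt(50)
  expect_lt(abs(mean(flips) - 20), 1.5)
})

test_that("disorder pairs share the requested edge overlap and control group", {
  cfg <- sim_config(R = 15, sites = list(sim_site("D1", 20, 10)),
                    n_effect_edges = 40, effect_size = 1,
                    n_covariate_edges = 0, seed = 8)
  two <- simulate_disorders(cfg, overlap = 0.5)
  eA <- attr(two$A, "truth")$effect_edges
  eB <- attr(two$B, "truth")$effect_edges
  expect_identical(length(intersect(eA, eB)), 20L)
  # shared edges keep disorder A's sign
  sh <- intersect(eA, eB)
  expect_identical(sign(attr(two$A, "truth")$d[sh + 1]),
                   sign(attr(two$B, "truth")$d[sh + 1]))

  ctrlA <- two$A$participants$diagnosis == 0
  ctrlB <- two$B$participants$diagnosis == 0
  expect_identical(two$A$fc[ctrlA, ], two$B$fc[ctrlB, ])

  expect_identical(attr(simulate_disorders(cfg, overlap = 1)$B, "truth")$effect_edges, eA)
  expect_length(intersect(
    attr(simulate_disorders(cfg, overlap = 0)$B, "truth")$effect_edges, eA), 0)
  expect_error(simulate_disorders(cfg, overlap = 0,
                                  n_effect_edges_B = cfg$m),
               "config error")
})

test_that("simulated ROI time series honour target correlation and spike rate", {
  ts <- simulate_roi_timeseries(diag(8), n_frames = 2000, fd_spike_prob = 0,
                                seed = 3)
  r <- cor(ts$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  expect_true(all(ts$fd_trace <= 0.5))

  ts2 <- simulate_roi_timeseries(diag(8), n_frames = 2000, fd_spike_prob = 0,
                                 seed = 3)
  expect_identical(ts$data, ts2$data)

  ts3 <- simulate_roi_timeseries(diag(4), n_frames = 500, fd_spike_prob = 0.2,
                                 seed = 4)
  spikes <- attr(ts3, "truth")$spike_frames
  expect_identical(which(ts3$fd_trace > 0.5), spikes)
  expect_gt(length(spikes), 50)

  bad <- matrix(c(1, 2, 2, 1), 2)  # not PSD
  expect_error(simulate_roi_timeseries(bad, 100), "semidefinite")
})

test_that("planted additive site effects are detectable before harmonization", {
  # site separability at additive_sd = noise_sd, 50 subjects/site
  cfg <- sim_config(R = 20, sites = list(sim_site("P1", 25, 25, additive_sd = 0.5),
                                         sim_site("P2", 25, 25, additive_sd = 0.5),
                                         sim_site("P3", 25, 25, additive_sd = 0.5)),
                    n_effect_edges = 0, n_covariate_edges = 0,
                    noise_sd = 0.5, seed = 14)
  ds <- simulate_fc_dataset(cfg)
  se <- site_effect_summary(ds)
  expect_gt(mean(se$p < 0.05, na.rm = TRUE), 0.9)
})

test_that("without planted effects, single-edge discrimination is at chance", {
  cfg <- fast_sim(R = 15, n0 = 150, n1 = 150, n_effect = 0, seed = 21)
  ds <- simulate_fc_dataset(cfg)
  y <- ds$participants$diagnosis
  aucs <- vapply(sample.int(ncol(ds$fc), 30), function(v)
    compute_metrics(y, ds$fc[, v])$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
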