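test_that("coupling specs validate stability and self-edges", {
  expect_error(coupling_spec(3, data.frame(source = 1, target = 1,
                                           strength = 0.5)), "self-edges")
  expect_error(coupling_spec(2, data.frame(source = c(1, 2), target = c(2, 1),
                                           strength = 0.9),
                             ar_coeff = 0.9), "spectral radius")
})

test_that("VAR simulation is seeded, stationary and role-tagged", {
  spec <- plant_hub_network(seed = 101, n_samples = 3000L)
  r1 <- simulate_var(spec)
  r2 <- simulate_var(spec)
  expect_identical(r1$data, r2$data)
  expect_identical(attr(r1, "roles"), attr(spec, "roles"))
  expect_lt(max(abs(r1$data)), 50)      # no divergence
  spec2 <- spec; spec2$seed <- 999L
  expect_false(identical(simulate_var(spec2)$data, r1$data))
})

test_that("edge-free networks yield mutually independent channels", {
  spec <- coupling_spec(3, n_samples = 10000, seed = 102)
  rec <- simulate_var(spec)
  cm <- connectivity_matrix(rec, analysis_config(seed = 102))
  expect_lt(max(cm$weights), 0.01)
})

test_that("a single planted edge is recovered in the correct direction", {
  wins <- 0
  for (s in 1:10) {
    spec <- coupling_spec(2, data.frame(source = 1, target = 2, strength = 0.8),
                          n_samples = 10000, seed = 200 + s)
    rec <- simulate_var(spec)
    cfg <- analysis_config(seed = 200 + s)
    fwd <- nte(rec$data[2, ], rec$data[1, ], cfg)
    rev <- nte(rec$data[1, ], rec$data[2, ], cfg)
    wins <- wins + (fwd > rev)
  }
  expect_gte(wins, 9)
})

test_that("planted hub networks have the stated degree structure", {
  spec <- plant_hub_network(15, 2, 1, seed = 103)
  roles <- attr(spec, "roles")
  expect_identical(sum(roles == "source"), 2L)
  expect_identical(sum(roles == "sink"), 1L)
  e <- spec$edges
  strong <- max(e$strength)
  for (s in which(roles == "source"))
    expect_identical(sum(e$source == s & e$strength == strong), 7L)
  snk <- which(roles == "sink")
  snk_in <- e[e$target == snk & e$source %in% which(roles == "background"), ]
  expect_gte(nrow(snk_in), 7)
  expect_error(plant_hub_network(5, 3, 2), "smaller than n_nodes")

  # background-only variant has no planted imbalance
  spec0 <- plant_hub_network(10, 0, 0, seed = 104)
  expect_true(all(attr(spec0, "roles") == "background"))
  expect_identical(nrow(spec0$edges), sum(!duplicated(spec0$edges[1:2])))
})

test_that("regime schedules switch the coupling at recorded boundaries", {
  specA <- plant_hub_network(seed = 105, n_samples = 6000L)
  eB <- specA$edges
  eB[c("source", "target")] <- eB[c("target", "source")]
  specB <- coupling_spec(specA$n_nodes, eB, ar_coeff = specA$ar_coeff,
                         seed = specA$seed, n_samples = specA$n_samples,
                         fs = specA$fs)
  rec <- simulate_regime_switch(specA, specB, 0.3, seed = 105)
  expect_identical(attr(rec, "switch_sample"), as.integer(floor(0.3 * 6000) + 1))
  expect_identical(n_samples(rec), 6000L)
  rec2 <- simulate_regime_switch(specA, specB, 0.3, seed = 105)
  expect_identical(rec$data, rec2$data)
  expect_error(simulate_regime_switch(specA, coupling_spec(4, seed = 1), 0.5),
               "differ in dimension")

  sched <- data.frame(regime = c("B", "A", "B"), fraction = c(0.4, 0.2, 0.4))
  rec3 <- simulate_regime_schedule(specA, specB, sched, seed = 105)
  expect_identical(attr(rec3, "boundaries"), c(1L, 2401L, 3601L))

  # identical regimes: statistically stationary hub counts
  recn <- simulate_regime_switch(specA, specA, 0.5, seed = 106)
  dyn <- hub_dynamics(recn, analysis_config(seed = 106))
  halves <- dyn$counts$start_s < max(dyn$counts$start_s) / 2
  pv <- wilcox.test(dyn$counts$n_HD[halves], dyn$counts$n_HD[!halves],
                    exact = FALSE)$p.value
  expect_gt(pv, 0.01)
})

test_that("microstate EEG simulation respects dwell, SNR and determinism", {
  tpl <- orthogonal_templates(4, 12, seed = 107)
  expect_error(microstate_sim_spec(tpl, snr = 0), "positive")
  expect_error(microstate_sim_spec(tpl[1, , drop = FALSE]), "at least 2")

  spec <- microstate_sim_spec(tpl, mean_dwell_ms = 100, snr = 5, fs = 250,
                              duration_s = 60, seed = 107)
  sim <- simulate_microstate_eeg(spec)
  runs <- rle(sim$labels)
  expect_equal(mean(runs$lengths) / 250 * 1000, 100, tolerance = 0.1)
  sim2 <- simulate_microstate_eeg(spec)
  expect_identical(sim2$recording$data, sim$recording$data)
  expect_identical(sim2$labels, sim$labels)

  # near-noiseless limit: backfitting the true templates recovers all labels
  quiet <- simulate_microstate_eeg(
    microstate_sim_spec(tpl, snr = 1e6, fs = 250, duration_s = 10, seed = 108))
  model <- structure(list(templates = t(tpl), gev = 1, k = 4),
                     class = "microstate_model")
  colnames(model$templates) <- LETTERS[1:4]
  seq_ <- backfit(quiet$recording, model)
  expect_identical(seq_$labels, quiet$labels)
})

test_that("switching-label sequences are faster inside designated windows", {
  ws <- data.frame(window = 1:10, start_s = seq(0, 45, by = 5),
                   n_HD = 0, n_HC = 0, n_HN = 0)
  class(ws) <- c("window_series", "data.frame")
  lab <- simulate_switching_labels(5000, 100, ws, fast_windows = c(2, 7),
                                   window_length_s = 5, seed = 109)
  expect_true(all(lab %in% 1:4))
  in_fast <- c(501:1000, 3001:3500)
  r_fast <- mean(diff(lab[in_fast]) != 0)
  r_slow <- mean(diff(lab[-in_fast]) != 0)
  expect_gt(r_fast, 2 * r_slow)
})
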