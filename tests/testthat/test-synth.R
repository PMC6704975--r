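test_that("generated templates are average-referenced, unit-norm, separated and deterministic", {
  maps <- generate_templates(6, 110, min_separation = 0.5, seed = 9)
  expect_equal(dim(maps), c(110L, 6L))
  expect_lt(max(abs(colMeans(maps))), 1e-12)
  expect_equal(unname(sqrt(colSums(maps^2))), rep(1, 6), tolerance = 1e-12)
  r <- abs(cor(maps)); diag(r) <- 0
  expect_lte(max(r), 0.5)
  expect_identical(maps, generate_templates(6, 110, min_separation = 0.5, seed = 9))
  expect_false(identical(maps, generate_templates(6, 110, seed = 10)))
})

test_that("a single template is well-formed and infeasible requests fail loudly", {
  one <- generate_templates(1, 110, seed = 2)
  expect_equal(ncol(one), 1L)
  expect_lt(abs(mean(one)), 1e-12)
  expect_equal(sum(one^2), 1, tolerance = 1e-12)
  expect_error(generate_templates(8, 8, seed = 1), "infeasible")
  expect_error(generate_templates(0, 10), ">= 1")
})

test_that("state sequences have the right length, no self-transitions, and dwell mean near target", {
  cfg <- simulation_config(duration_s = 300, fs = 125, K_true = 6,
                           mean_dwell_ms = 100, seed = 21)
  s <- generate_state_sequence(cfg)
  expect_length(s$labels, 37500L)
  expect_true(all(s$segments$class[-1] != s$segments$class[-nrow(s$segments)]))
  expect_identical(rep.int(s$segments$class, s$segments$length), s$labels)
  # empirical mean dwell within 10% of the planted mean, averaged over seeds
  mean_dwell <- vapply(1:6, function(sd) {
    cfg_i <- simulation_config(duration_s = 300, fs = 125, K_true = 6,
                               mean_dwell_ms = 100, seed = sd)
    seg <- generate_state_sequence(cfg_i)$segments
    mean(seg$length) / 125 * 1000
  }, numeric(1))
  expect_lt(abs(mean(mean_dwell) - 100), 10)
})

test_that("K_true = 1 yields one unbroken segment and sub-sample dwells are rejected", {
  cfg <- simulation_config(duration_s = 2, fs = 100, K_true = 1, seed = 1)
  s <- generate_state_sequence(cfg)
  expect_identical(s$labels, rep.int(1L, 200L))
  expect_equal(nrow(s$segments), 1L)
  cfg_bad <- simulation_config(duration_s = 2, fs = 100, mean_dwell_ms = 5, seed = 1)
  expect_error(generate_state_sequence(cfg_bad), "sample period")
})

test_that("synthesized EEG is average-referenced, honours the SNR definition, and is deterministic", {
  cfg <- simulation_config(n_channels = 30, duration_s = 10, K_true = 4,
                           snr = 2, seed = 7)
  tpl <- generate_templates(4, 30, seed = 3)
  lab <- generate_state_sequence(cfg)$labels
  out <- synthesize_eeg(tpl, lab, cfg)
  expect_lt(max(abs(colMeans(out$recording$data))), 1e-12)
  out2 <- synthesize_eeg(tpl, lab, cfg)
  expect_identical(out$recording$data, out2$recording$data)
  # reconstruct the rms ratio: noiseless signal from the same seed stream
  noiseless <- synthesize_eeg(tpl, lab,
                              simulation_config(n_channels = 30, duration_s = 10,
                                                K_true = 4, snr = Inf, seed = 7))
  S <- noiseless$recording$data
  N <- out$recording$data - S
  expect_equal(sqrt(mean(S^2)) / sqrt(mean(N^2)), 2, tolerance = 1e-6)
})

test_that("ground-truth per-class metrics satisfy coverage = occurrence x duration", {
  sim <- small_sim(duration_s = 30, seed = 13)
  m <- sim$truth$metrics
  expect_equal(sum(m$coverage), 1, tolerance = 1e-12)
  # identity holds within edge-truncation tolerance
  expect_equal(m$coverage,
               m$occurrence_per_s * m$duration_ms / 1000,
               tolerance = 0.1)
})

test_that("noiseless output backfits to the planted labels at every sample", {
  cfg <- simulation_config(n_channels = 24, duration_s = 10, K_true = 4,
                           snr = Inf, seed = 17)
  sim <- simulate_recording(cfg)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(average_reference(sim$recording), model)
  expect_identical(seg$labels, sim$truth$labels)
})

test_that("pure noise is poorly explained by the true templates", {
  gevs <- vapply(1:20, function(sd) {
    cfg <- simulation_config(n_channels = 24, duration_s = 20, K_true = 6,
                             snr = 0, seed = 100 + sd)
    sim <- simulate_recording(cfg)
    model <- model_from_maps(sim$truth$templates)
    rec <- average_reference(sim$recording)
    seg <- backfit(rec, model)
    compute_gev(rec, model, seg)$gev_total
  }, numeric(1))
  expect_true(all(gevs < 0.5))
})

test_that("recoverability of planted maps is monotone in SNR", {
  mean_corr <- vapply(c(0.5, 1, 2, 4), function(snr) {
    per_seed <- vapply(1:3, function(sd) {
      cfg <- simulation_config(n_channels = 24, duration_s = 30, K_true = 4,
                               snr = snr, seed = 200 + sd)
      sim <- simulate_recording(cfg)
      rec <- average_reference(sim$recording)
      m <- modified_kmeans(peak_maps(rec), 4, n_restarts = 10, seed = sd)
      mean(match_maps(m$maps, sim$truth$templates)$abs_correlation)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(mean_corr) >= -1e-6))
})
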