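# Brute-force per-sample backfit: compute all K Pearson correlations with
# stats::cor and take the argmax of the absolute value, lowest index on ties.
brute_backfit <- function(rec, model) {
  vapply(seq_len(ncol(rec$data)), function(t) {
    r <- abs(vapply(seq_len(model$K), function(k)
      stats::cor(rec$data[, t], model$maps[, k]), numeric(1)))
    which(r == max(r))[1]
  }, integer(1))
}

# Brute-force evaluation of the smoothing objective for a full label vector.
smoothing_energy <- function(L, D, lambda, b) {
  n <- length(L)
  sum(vapply(seq_len(n), function(t) {
    w <- max(1, t - b):min(n, t + b)
    D[t, L[t]] - lambda * sum(L[w] == L[t])
  }, numeric(1)))
}

test_that("spatial correlation matches hand values and flags degenerate maps", {
  m1 <- c(1, -1, 0, 0); m2 <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(m1, m1), 1)
  expect_equal(spatial_correlation(m1, -m1), -1)
  expect_lt(abs(spatial_correlation(m1, m2)), 1e-10)
  expect_error(spatial_correlation(m1, rep(1, 4)), "zero-variance")
  expect_error(spatial_correlation(m1, c(1, 2)), "channel counts")
})

test_that("a recording made of one model map backfits to that class at any amplitude or sign", {
  maps <- generate_templates(4, 12, seed = 3)
  model <- model_from_maps(maps)
  amp <- c(0.3, -2, 5, -0.1, 1)
  rec <- recording_from_labels(maps, rep(2L, 5), amp = amp)
  seg <- backfit(rec, model)
  expect_identical(seg$labels, rep(2L, 5))
  expect_equal(seg$corr_trace, rep(1, 5), tolerance = 1e-10)
})

test_that("backfit equals the brute-force per-sample scan on random recordings", {
  set.seed(27)
  maps <- generate_templates(3, 10, seed = 5)
  model <- model_from_maps(maps)
  X <- matrix(rnorm(10 * 40), 10)
  rec <- average_reference(eeg_recording(X, 125))
  seg <- backfit(rec, model)
  expect_identical(seg$labels, brute_backfit(rec, model))
  # segments partition the samples with no adjacent repeats
  expect_equal(sum(seg$segments$length), 40)
  cls <- seg$segments$class
  if (length(cls) > 1) expect_true(all(cls[-1] != cls[-length(cls)]))
})

test_that("lambda = 0 smoothing is the identity", {
  sim <- small_sim(n_channels = 12, duration_s = 5, K = 3, snr = 1, seed = 15)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(rec, model)
  gfp <- compute_gfp(rec)
  sm <- smooth_labels(seg, gfp, model, besag_factor = 0)
  expect_identical(sm$labels, seg$labels)
})

test_that("a one-sample blip with equal data terms is absorbed, lowering the smoothing energy", {
  # 21 samples of class 1 with a blip of class 2 at the centre; both classes
  # correlate equally with every sample so only the penalty decides.
  maps <- generate_templates(2, 8, seed = 7)
  blend <- (maps[, 1] + maps[, 2]) / sqrt(2)   # equal |corr| with both maps
  rec <- eeg_recording(matrix(rep(blend, 21), ncol = 21), 125,
                       channel_labels = rownames(maps))
  model <- model_from_maps(maps)
  seg0 <- backfit(rec, model)
  L <- rep(1L, 21); L[11] <- 2L
  seg <- microstater:::make_segmentation(L, 125, 2, seg0$corr)
  gfp <- compute_gfp(rec)
  sm <- smooth_labels(seg, gfp, model, window_half_size = 3, besag_factor = 10)
  expect_identical(sm$labels, rep(1L, 21))
  # energy oracle: the returned labeling is at most the blip labeling's energy
  v <- gfp$values^2
  U <- v * (1 - seg$corr^2)
  e <- sum(U[cbind(1:21, L)]) / (21 * (nrow(maps) - 1))
  D <- U / (2 * max(e, .Machine$double.eps) * (nrow(maps) - 1))
  expect_lt(smoothing_energy(sm$labels, D, 10, 3),
            smoothing_energy(L, D, 10, 3))
})

test_that("the smoothed labeling is a fixed point of per-sample exhaustive minimization", {
  sim <- small_sim(n_channels = 12, duration_s = 5, K = 3, snr = 1, seed = 33)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(rec, model)
  gfp <- compute_gfp(rec)
  sm <- smooth_labels(seg, gfp, model, window_half_size = 3, besag_factor = 10)
  v <- gfp$values^2
  n <- length(sm$labels)
  U <- v * (1 - seg$corr^2)
  e <- sum(U[cbind(seq_len(n), seg$labels)]) / (n * (nrow(model$maps) - 1))
  D <- U / (2 * e * (nrow(model$maps) - 1))
  L <- sm$labels
  b <- 3; lambda <- 10
  ok <- vapply(seq_len(n), function(t) {
    w <- max(1, t - b):min(n, t + b)
    # candidate cost with the window count taken over the current labels
    costs <- vapply(1:3, function(k) D[t, k] - lambda * sum(L[w] == k),
                    numeric(1))
    L[t] == which(costs == min(costs))[1]
  }, logical(1))
  expect_true(all(ok))
})

test_that("mean segment duration is non-decreasing in the Besag factor", {
  sim <- small_sim(n_channels = 16, duration_s = 20, K = 4, snr = 1, seed = 51)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(rec, model)
  gfp <- compute_gfp(rec)
  mean_dur <- vapply(c(0, 1, 5, 10), function(lam) {
    sm <- smooth_labels(seg, gfp, model, besag_factor = lam)
    mean(sm$segments$length)
  }, numeric(1))
  expect_true(all(diff(mean_dur) >= 0))
})

test_that("smoothing preserves length, class alphabet and segmentation invariants", {
  sim <- small_sim(n_channels = 12, duration_s = 10, K = 3, snr = 1, seed = 61)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(rec, model)
  sm <- smooth_labels(seg, compute_gfp(rec), model)
  expect_length(sm$labels, length(seg$labels))
  expect_true(all(sm$labels %in% 1:3))
  expect_equal(sum(sm$segments$length), length(sm$labels))
  cls <- sm$segments$class
  if (length(cls) > 1) expect_true(all(cls[-1] != cls[-length(cls)]))
})

test_that("global sign flip leaves segmentation and metrics unchanged", {
  sim <- small_sim(n_channels = 16, duration_s = 10, K = 3, snr = 2, seed = 71)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  run <- function(r) {
    seg <- smooth_labels(backfit(r, model), compute_gfp(r), model)
    list(seg = seg, met = compute_metrics(seg),
         gev = compute_gev(r, model, seg))
  }
  flipped <- rec; flipped$data <- -flipped$data
  a <- run(rec); b <- run(flipped)
  expect_identical(a$seg$labels, b$seg$labels)
  expect_equal(a$met, b$met, tolerance = 1e-12)
  expect_equal(a$gev, b$gev, tolerance = 1e-12)
})
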