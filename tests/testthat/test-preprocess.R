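make_rec <- function(f, fs = 250, dur = 20, n_ch = 4, amp = 1) {
  tt <- (0:(fs * dur - 1)) / fs
  X <- matrix(rep(amp * sin(2 * pi * f * tt), each = n_ch), nrow = n_ch)
  X <- X * (1 + 0.5 * seq_len(n_ch))          # distinct channel gains
  eeg_recording(X, fs)
}

interior <- function(rec, margin_s = 2) {
  n <- n_samples(rec)
  m <- round(margin_s * rec$fs)
  rec$data[, (m + 1):(n - m), drop = FALSE]
}

test_that("band-pass removes DC and passes/attenuates per its own frequency response", {
  fs <- 250
  dc <- eeg_recording(matrix(1, 4, fs * 20), fs)
  out <- bandpass_filter(dc, 1, 40)
  expect_lt(max(abs(interior(out))), 1e-2)

  # 10 Hz in-band tone: steady-state amplitude matches the analytic gain (~1)
  tone <- make_rec(10, fs = fs)
  out10 <- interior(bandpass_filter(tone, 1, 40))
  gain10 <- bandpass_gain(1, 40, fs, 10)
  ratio <- max(abs(out10[1, ])) / max(abs(interior(tone)[1, ]))
  expect_equal(ratio, gain10, tolerance = 0.01)
  expect_lt(abs(ratio - 1), 0.05)

  # 50 Hz out-of-band tone: attenuated at least as much as the designed response
  tone50 <- make_rec(50, fs = fs)
  out50 <- interior(bandpass_filter(tone50, 1, 40))
  gain50 <- bandpass_gain(1, 40, fs, 50)
  ratio50 <- max(abs(out50[1, ])) / max(abs(interior(tone50)[1, ]))
  expect_lt(ratio50, gain50 * 1.05)
  expect_lt(ratio50, 0.5)
})

test_that("band edges are validated with the offending edge named", {
  rec <- make_rec(10)
  expect_error(bandpass_filter(rec, 0, 40), "low_hz")
  expect_error(bandpass_filter(rec, 10, 5), "high_hz")
  expect_error(bandpass_filter(rec, 1, 200), "Nyquist")
})

test_that("downsampling decimates by integer ratios with anti-aliasing", {
  fs <- 1000
  tt <- (0:9999) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 5 * tt), cos(2 * pi * 5 * tt)), fs)
  out <- downsample(rec, 125)
  expect_equal(out$fs, 125)
  expect_equal(n_samples(out), 1250L)
  # 5 Hz survives decimation with amplitude within 5% (and within 1% of the
  # designed anti-aliasing gain)
  mid <- out$data[1, 200:1000]
  expect_equal(max(abs(mid)), antialias_gain(fs, 125, 5), tolerance = 0.01)
  expect_lt(abs(max(abs(mid)) - 1), 0.05)
})

test_that("downsampling refuses upsampling and non-integer ratios; ratio 1 is a no-op", {
  rec <- make_rec(5, fs = 250, dur = 4)
  expect_error(downsample(rec, 500), "exceeds")
  expect_error(downsample(rec, 96), "non-integer")
  expect_identical(downsample(rec, 250), rec)
})

test_that("average referencing zeroes the channel mean, is idempotent, and preserves GFP", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(8 * 100), 8) + 5, 100)
  ref <- average_reference(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-10)
  expect_equal(average_reference(ref)$data, ref$data, tolerance = 1e-14)
  expect_equal(compute_gfp(ref)$values, compute_gfp(rec)$values, tolerance = 1e-12)
})

test_that("preprocessing operations are linear and preserve channel labels", {
  set.seed(9)
  fs <- 200
  X <- matrix(rnorm(3 * fs * 5), 3)
  Y <- matrix(rnorm(3 * fs * 5), 3)
  labs <- c("Fz", "Cz", "Pz")
  rec <- function(M) eeg_recording(M, fs, channel_labels = labs)
  for (op in list(function(r) bandpass_filter(r, 1, 40),
                  function(r) downsample(r, 100),
                  average_reference)) {
    fx <- op(rec(X))$data
    fy <- op(rec(Y))$data
    fxy <- op(rec(2 * X - 3 * Y))$data
    expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
    expect_identical(rownames(op(rec(X))$data), labs)
  }
})
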