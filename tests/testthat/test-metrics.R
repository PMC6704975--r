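seg_from_labels <- function(labels, fs = 125, K = max(labels)) {
  microstater:::make_segmentation(as.integer(labels), fs, K,
                                  matrix(0, length(labels), K))
}

# Sample-by-sample brute-force GEV: squared Pearson correlation with the
# assigned map, weighted by squared GFP.
brute_gev_rec <- function(rec, model, labels) {
  gfp <- apply(rec$data, 2, function(x) sqrt(mean((x - mean(x))^2)))
  num <- vapply(seq_len(ncol(rec$data)), function(t)
    stats::cor(rec$data[, t], model$maps[, labels[t]])^2 * gfp[t]^2,
    numeric(1))
  per <- vapply(seq_len(model$K), function(k) sum(num[labels == k]),
                numeric(1)) / sum(gfp^2)
  list(gev_per_class = per, gev_total = sum(per))
}

test_that("metrics match hand-enumerated label sequences", {
  # one class covering a 10 s recording entirely
  s1 <- seg_from_labels(rep(1L, 1250), fs = 125, K = 2)
  m1 <- compute_metrics(s1)
  expect_equal(m1$coverage, c(1, 0))
  expect_equal(m1$occurrence_per_s, c(0.1, 0))
  expect_equal(m1$duration_ms, c(10000, NA))
  # two classes alternating every 5 samples for 1000 samples at 125 Hz
  s2 <- seg_from_labels(rep(rep(1:2, each = 5), 100), fs = 125)
  m2 <- compute_metrics(s2)
  expect_equal(m2$coverage, c(0.5, 0.5))
  expect_equal(m2$duration_ms, c(40, 40))
  expect_equal(m2$occurrence_per_s, c(12.5, 12.5))
})

test_that("an absent class reports NA duration, zero occurrence and coverage", {
  s <- seg_from_labels(c(rep(1L, 50), rep(2L, 50)), fs = 100, K = 3)
  m <- compute_metrics(s)
  expect_true(is.na(m$duration_ms[3]))
  expect_equal(m$occurrence_per_s[3], 0)
  expect_equal(m$coverage[3], 0)
})

test_that("coverage sums to one and equals occurrence x duration within edge tolerance", {
  set.seed(7)
  for (rep_i in 1:5) {
    lab <- rep.int(sample(1:4, 60, replace = TRUE),
                   pmax(1, rpois(60, 10)))
    s <- seg_from_labels(lab, fs = 125, K = 4)
    m <- compute_metrics(s)
    expect_equal(sum(m$coverage), 1, tolerance = 1e-12)
    pred <- m$occurrence_per_s * m$duration_ms / 1000
    ok <- !is.na(pred)
    expect_equal(m$coverage[ok], pred[ok], tolerance = 0.15)
  }
})

test_that("GEV equals the brute-force weighted-correlation evaluation", {
  sim <- small_sim(n_channels = 10, duration_s = 3, K = 3, snr = 1, seed = 43)
  rec <- average_reference(sim$recording)
  model <- model_from_maps(sim$truth$templates)
  seg <- backfit(rec, model)
  gev <- compute_gev(rec, model, seg)
  bf <- brute_gev_rec(rec, model, seg$labels)
  expect_equal(unname(gev$gev_per_class), bf$gev_per_class, tolerance = 1e-12)
  expect_equal(gev$gev_total, bf$gev_total, tolerance = 1e-12)
  expect_true(all(gev$gev_per_class >= 0))
  expect_equal(sum(gev$gev_per_class), gev$gev_total, tolerance = 1e-12)
})

test_that("a recording of scaled model maps with correct labels has GEV 1", {
  set.seed(12)
  maps <- generate_templates(3, 10, seed = 4)
  lab <- rep(1:3, each = 20)
  rec <- recording_from_labels(maps, lab, amp = runif(60, 0.5, 2))
  model <- model_from_maps(maps)
  seg <- backfit(rec, model)
  expect_identical(seg$labels, lab)
  expect_equal(compute_gev(rec, model, seg)$gev_total, 1, tolerance = 1e-9)
})
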