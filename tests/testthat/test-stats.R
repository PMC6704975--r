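# Brute-force Benjamini-Hochberg step-up: adjusted p_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m))
    adj[ord[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  adj
}

fake_metrics <- function(n_per_group = 8, K = 4, seed = 1, shift = 0) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(2 * n_per_group)),
                      class = LETTERS[seq_len(K)], stringsAsFactors = FALSE)
  grid$group <- rep(rep(c("patient", "control"), each = n_per_group), K)
  grid$duration_ms <- rnorm(nrow(grid), 90, 10) +
    shift * (grid$group == "patient")
  grid$occurrence_per_s <- rnorm(nrow(grid), 2, 0.3)
  grid$coverage <- runif(nrow(grid), 0.1, 0.4)
  grid
}

test_that("identical groups give t = 0 and p = 1 in every cell", {
  met <- fake_metrics(seed = 2)
  # make patient and control values identical per (class, rank)
  for (col in c("duration_ms", "occurrence_per_s", "coverage")) {
    v <- met[[col]]
    v[met$group == "control"] <- v[met$group == "patient"]
    met[[col]] <- v
  }
  res <- group_ttests(met)
  expect_true(all(abs(res$t) < 1e-12))
  expect_true(all(abs(res$p - 1) < 1e-12))
})

test_that("BH adjustment matches the brute-force step-up, including the worked p-vector", {
  p6 <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  expect_equal(stats::p.adjust(p6, "BH"), brute_bh(p6), tolerance = 1e-15)
  set.seed(5)
  for (m in c(3, 6, 12, 20)) {
    p <- runif(m)
    expect_equal(stats::p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-15)
  }
})

test_that("FDR adjustment is applied within each parameter family and is order-equivariant", {
  met <- fake_metrics(seed = 3, shift = 8)
  res <- group_ttests(met)
  for (par in unique(res$parameter)) {
    idx <- res$parameter == par
    expect_equal(res$p_fdr[idx], brute_bh(res$p[idx]), tolerance = 1e-12)
  }
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  expect_true(all(res$p_fdr <= 1))
  # permuting subject rows changes nothing
  met2 <- met[sample(nrow(met)), ]
  res2 <- group_ttests(met2)
  expect_equal(res$p_fdr, res2$p_fdr, tolerance = 1e-12)
})

test_that("Spearman correlation matches the midrank oracle and cor.test", {
  expect_equal(spearman_corr(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_corr(1:10, rev(1:10))$rho, -1)
  set.seed(8)
  for (i in 1:5) {
    x <- sample(1:5, 10, replace = TRUE)       # ties guaranteed
    y <- rnorm(10)
    sc <- spearman_corr(x, y)
    # oracle: Pearson correlation of explicitly computed mid-ranks
    mid <- function(v) {
      sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
    }
    expect_equal(sc$rho, stats::cor(mid(x), mid(y)), tolerance = 1e-12)
    # independent check against the standard implementation
    expect_equal(sc$rho,
                 unname(stats::cor.test(x, y, method = "spearman",
                                        exact = FALSE)$estimate),
                 tolerance = 1e-12)
    tstat <- sc$rho * sqrt(8 / (1 - sc$rho^2))
    expect_equal(sc$p, 2 * stats::pt(-abs(tstat), 8), tolerance = 1e-15)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:3, 1:4), "lengths")
})

test_that("clinical correlations cover the full Cartesian grid and flag planted monotone cells", {
  met <- fake_metrics(n_per_group = 10, K = 4, seed = 13)
  pats <- unique(met$subject[met$group == "patient"])
  clin <- data.frame(subject = pats,
                     madrs = seq(10, 40, length.out = length(pats)),
                     cgi = sample(3:6, length(pats), replace = TRUE))
  # plant a perfect monotone relation for (duration, class B)
  idx <- met$group == "patient" & met$class == "B"
  met$duration_ms[idx] <- 50 + 2 * clin$madrs[match(met$subject[idx], clin$subject)]
  res <- correlate_with_clinical(met, clin, alpha = 0.01)
  expect_equal(nrow(res), 3 * 4 * 2)
  cell <- res[res$parameter == "duration_ms" & res$class == "B" &
                res$variable == "madrs", ]
  expect_equal(cell$rho, 1)
  expect_true(cell$significant)
  expect_error(correlate_with_clinical(met, clin[-1, ], alpha = 0.01),
               "without clinical")
})

test_that("null Spearman flags at alpha = 0.01 occur at about the nominal rate", {
  set.seed(99)
  n <- 19
  flags <- vapply(seq_len(1000), function(i) {
    sc <- spearman_corr(rnorm(n), rnorm(n))
    sc$p < 0.01
  }, logical(1))
  # 3-sigma Monte-Carlo band around 0.01 for 1000 replicates
  expect_lt(abs(mean(flags) - 0.01), 3 * sqrt(0.01 * 0.99 / 1000) + 0.002)
})
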