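#' Polarity-invariant modified k-means for scalp topographies
#'
#' Clusters topographic maps ignoring polarity. The assignment step labels
#' each map with the prototype of highest absolute spatial correlation (for
#' average-referenced maps this is argmax of `|x . m|`, independent of the
#' map's amplitude); the update step replaces each prototype with the
#' dominant spatial mode (first principal direction) of its assigned maps'
#' channel-space scatter, computed by warm-started power iteration, which is
#' polarity-blind and guarantees the global explained variance never
#' decreases within a restart. The best of `n_restarts` random
#' initializations by total GEV is returned.
#'
#' An empty cluster arising during iteration is re-seeded from the map the
#' current model explains worst.
#'
#' @param peak_maps `channels x n` matrix of average-referenced maps (columns),
#'   typically the topographies at GFP peaks; amplitudes are retained and act
#'   as the GEV weights.
#' @param K Number of clusters; must not exceed the number of maps.
#' @param n_restarts Random restarts.
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence threshold on the relative GEV change.
#' @param seed Integer RNG seed; the fit is deterministic given
#'   `(peak_maps, K, n_restarts, seed)`.
#' @return An object of class `microstate_model`: `K`, `maps` (`channels x K`,
#'   unit-norm, average-referenced, columns named A, B, ...), `gev_total`,
#'   `gev_per_class`, `labels` (cluster index of every input map),
#'   `gev_trace` (per-iteration GEV of the winning restart) and `settings`.
#' @export
modified_kmeans <- function(peak_maps, K, n_restarts = 100, max_iter = 1000,
                            tol = 1e-6, seed = 1) {
  X <- as.matrix(peak_maps)
  storage.mode(X) <- "double"
  C <- nrow(X); n <- ncol(X)
  K <- as.integer(K)
  if (K < 1) stop("`K` must be >= 1")
  if (n < K) stop("need at least K = ", K, " peak maps, got ", n)
  stopifnot_avg_ref(X, tol = 1e-6 * max(1, max(abs(X))), what = "peak maps")
  total_ss <- sum(X^2)
  if (total_ss <= 0) stop("peak maps are identically zero")

  fit_once <- function() {
    init <- sample.int(n, K)
    M <- X[, init, drop = FALSE]
    nrm <- sqrt(colSums(M^2))
    if (any(nrm == 0)) {            # a zero map cannot seed a prototype
      alt <- sample.int(n, K)
      M <- X[, alt, drop = FALSE]; nrm <- sqrt(colSums(M^2))
      nrm[nrm == 0] <- 1
    }
    M <- sweep(M, 2, nrm, "/")
    gev <- -Inf; trace <- numeric(0); L <- integer(n)
    for (it in seq_len(max_iter)) {
      A <- crossprod(X, M)                       # n x K projections
      L <- max.col(abs(A), ties.method = "first")
      expl <- A[cbind(seq_len(n), L)]^2
      # empty clusters: steal the worst-explained map as a fresh seed
      empty <- setdiff(seq_len(K), unique(L))
      for (k in empty) {
        w <- which.min(expl / colSums(X^2))
        M[, k] <- X[, w] / sqrt(sum(X[, w]^2))
        L[w] <- k
        expl[w] <- sum(X[, w]^2)
      }
      for (k in seq_len(K)) {
        idx <- which(L == k)
        if (!length(idx)) next
        Xk <- X[, idx, drop = FALSE]
        v <- M[, k]
        for (p in 1:4) {                          # Rayleigh-ascent power steps
          v <- Xk %*% crossprod(Xk, v)
          nv <- sqrt(sum(v^2))
          if (nv == 0) { v <- M[, k]; break }
          v <- v / nv
        }
        M[, k] <- as.numeric(v)
      }
      A <- crossprod(X, M)
      L <- max.col(abs(A), ties.method = "first")
      gev_new <- sum(A[cbind(seq_len(n), L)]^2) / total_ss
      trace <- c(trace, gev_new)
      if (is.finite(gev) && abs(gev_new - gev) <= tol * max(gev, .Machine$double.eps)) {
        gev <- gev_new; break
      }
      gev <- gev_new
    }
    list(M = M, L = L, gev = gev, trace = trace)
  }

  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      f <- fit_once()
      if (is.null(b) || f$gev > b$gev) { b <- f; b$restart <- r }
    }
    b
  })

  M <- best$M
  # deterministic sign and class-order convention
  for (k in seq_len(K)) {
    i <- which.max(abs(M[, k]))
    if (M[i, k] < 0) M[, k] <- -M[, k]
  }
  A <- crossprod(X, M)
  L <- max.col(abs(A), ties.method = "first")
  per_class <- vapply(seq_len(K), function(k) {
    idx <- which(L == k)
    if (!length(idx)) 0 else sum(A[cbind(idx, rep(k, length(idx)))]^2) / total_ss
  }, numeric(1))
  rownames(M) <- rownames(X)
  colnames(M) <- LETTERS[seq_len(K)]
  structure(
    list(K = K, maps = M, gev_total = sum(per_class), gev_per_class = per_class,
         labels = L, gev_trace = best$trace,
         settings = list(n_restarts = n_restarts, max_iter = max_iter,
                         tol = tol, seed = seed, best_restart = best$restart)),
    class = "microstate_model"
  )
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d, GEV = %.3f (%s)\n", x$K, x$gev_total,
              paste(sprintf("%s %.3f", colnames(x$maps), x$gev_per_class),
                    collapse = ", ")))
  invisible(x)
}

#' Match two map sets by absolute spatial correlation
#'
#' Greedy one-to-one matching of the columns of `maps` to the columns of
#' `reference`, taking the highest remaining `|correlation|` first. Used to
#' compare a recovered model against planted templates or against another fit
#' (models are defined only up to map order and sign).
#'
#' @param maps,reference `channels x K` matrices of average-referenced maps.
#' @return A data.frame with `map` (column of `maps`), `reference` (matched
#'   column) and `abs_correlation`.
#' @export
match_maps <- function(maps, reference) {
  maps <- as.matrix(maps); reference <- as.matrix(reference)
  R <- abs(stats::cor(maps, reference))
  k1 <- ncol(maps); k2 <- ncol(reference)
  out <- data.frame(map = integer(0), reference = integer(0),
                    abs_correlation = numeric(0))
  Rw <- R
  for (i in seq_len(min(k1, k2))) {
    w <- which(Rw == max(Rw), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(map = w[["row"]], reference = w[["col"]],
                                 abs_correlation = R[w[["row"]], w[["col"]]]))
    Rw[w[["row"]], ] <- -Inf
    Rw[, w[["col"]]] <- -Inf
  }
  out[order(out$map), , drop = FALSE]
}
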