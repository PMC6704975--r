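# Polarity-invariant dissimilarity between unit-norm average-referenced maps:
# d = sqrt(2 * (1 - |r|)), the chord distance after optimal sign alignment.
map_dissimilarity <- function(maps) {
  Xn <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  r <- abs(crossprod(Xn))
  r[r > 1] <- 1
  d <- sqrt(2 * (1 - r))
  diag(d) <- 0
  d
}

# --- individual cluster-validity criteria ----------------------------------
# Each takes the dissimilarity matrix D, integer labels L, the fitted model
# and the raw maps, and returns a scalar oriented so that LARGER = better
# (criteria whose native orientation is "smaller is better" are negated).

crit_gamma <- function(D, L, ...) {
  # Baker-Hubert Gamma: concordance of within vs between pair distances
  within <- outer(L, L, "==")
  ut <- upper.tri(D)
  dw <- D[ut & within]
  db <- D[ut & !within]
  if (!length(dw) || !length(db)) return(NA_real_)
  sb <- sort(db)
  conc <- sum(length(db) - findInterval(dw, sb))              # b > w strictly
  disc <- sum(findInterval(dw, sb, left.open = TRUE))         # b < w strictly
  if (conc + disc == 0) return(NA_real_)
  (conc - disc) / (conc + disc)
}

crit_silhouette <- function(D, L, ...) {
  n <- length(L)
  ks <- sort(unique(L))
  if (length(ks) < 2L) return(NA_real_)
  sums <- vapply(ks, function(k) rowSums(D[, L == k, drop = FALSE]), numeric(n))
  sizes <- vapply(ks, function(k) sum(L == k), integer(1))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ki <- match(L[i], ks)
    if (sizes[ki] <= 1L) { s[i] <- 0; next }
    a <- sums[i, ki] / (sizes[ki] - 1L)
    b <- min(sums[i, -ki] / sizes[-ki])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

crit_davies_bouldin <- function(D, L, model, maps, ...) {
  # centroid = fitted prototype; scatter = mean map-to-prototype dissimilarity
  proto_d <- map_dissimilarity(cbind(maps, model$maps))
  n <- ncol(maps); K <- model$K
  if (K < 2L) return(NA_real_)
  S <- vapply(seq_len(K), function(k) {
    idx <- which(L == k)
    if (!length(idx)) return(0)
    mean(proto_d[idx, n + k])
  }, numeric(1))
  Mj <- proto_d[n + seq_len(K), n + seq_len(K), drop = FALSE]
  db <- vapply(seq_len(K), function(k) {
    max(vapply(setdiff(seq_len(K), k), function(j) {
      if (Mj[k, j] == 0) return(Inf)
      (S[k] + S[j]) / Mj[k, j]
    }, numeric(1)))
  }, numeric(1))
  -mean(db)                                   # smaller DB is better
}

crit_point_biserial <- function(D, L, ...) {
  ut <- upper.tri(D)
  d <- D[ut]
  between <- as.numeric(outer(L, L, "!=")[ut])
  if (stats::sd(d) == 0 || stats::sd(between) == 0) return(NA_real_)
  stats::cor(d, between)                      # larger separation is better
}

crit_dunn <- function(D, L, ...) {
  ks <- sort(unique(L))
  if (length(ks) < 2L) return(NA_real_)
  diam <- max(vapply(ks, function(k) {
    idx <- which(L == k)
    if (length(idx) < 2L) return(0)
    max(D[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j) {
      min(D[L == ks[i], L == ks[j], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  if (diam == 0) return(Inf)
  sep / diam
}

# within-cluster dispersion: sum of squared dissimilarities to the prototype
within_dispersion <- function(D_to_proto, L, K, n) {
  sum(vapply(seq_len(K), function(k) {
    idx <- which(L == k)
    if (!length(idx)) return(0)
    sum(D_to_proto[idx, k]^2)
  }, numeric(1)))
}

crit_cross_validation <- function(D, L, model, maps, ...) {
  # Pascual-Marqui predictive-residual criterion; smaller is better
  C <- nrow(maps)
  K <- model$K
  if (C - 1L - K <= 0L) return(NA_real_)
  A <- crossprod(maps, model$maps)
  n <- ncol(maps)
  resid <- sum(colSums(maps^2) - A[cbind(seq_len(n), L)]^2)
  sigma2 <- resid / (n * (C - 1L))
  -(sigma2 * ((C - 1L) / (C - 1L - K))^2)
}

#' Select the number of microstate classes by a seven-criterion meta-criterion
#'
#' Fits a polarity-invariant [modified_kmeans()] model for every candidate K,
#' scores each fit with seven independent cluster-validity criteria
#' (Baker-Hubert Gamma, mean Silhouette width, Davies-Bouldin,
#' Point-Biserial, Dunn, Krzanowski-Lai, and the predictive cross-validation
#' criterion), min-max-normalizes each criterion across the candidate range,
#' and selects the K with the best median rank (ties broken toward the
#' smaller K). All distances are polarity-invariant map dissimilarities
#' `sqrt(2 (1 - |r|))`.
#'
#' @param peak_maps `channels x n` matrix of average-referenced maps.
#' @param k_range Integer vector of candidate class counts (within
#'   `[2, ncol(peak_maps)]`; a single candidate is allowed and simply
#'   reported).
#' @param n_restarts,max_iter,tol,seed Passed to [modified_kmeans()].
#' @return An object of class `metacriterion_report`: `k_range`, `scores`
#'   (raw criterion values, oriented larger-is-better), `normalized`,
#'   `median_rank`, `k_selected`, and `models` (the fit per candidate K).
#' @export
select_optimal_k <- function(peak_maps, k_range, n_restarts = 20,
                             max_iter = 1000, tol = 1e-6, seed = 1) {
  X <- as.matrix(peak_maps)
  n <- ncol(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("`k_range` must contain at least one candidate K")
  if (min(k_range) < 2L || max(k_range) > n)
    stop("`k_range` must lie within [2, ", n, "]")
  # fit one extra K on each side so Krzanowski-Lai differences exist at the edges
  fit_ks <- sort(unique(c(k_range, min(k_range) - 1L,
                          pmin(max(k_range) + 1L, n))))
  fit_ks <- fit_ks[fit_ks >= 1L]
  models <- lapply(fit_ks, function(k)
    modified_kmeans(X, k, n_restarts = n_restarts, max_iter = max_iter,
                    tol = tol, seed = derive_seed(seed, k)))
  names(models) <- as.character(fit_ks)
  D <- map_dissimilarity(X)
  C <- nrow(X)

  # within-dispersion per fitted K (for Krzanowski-Lai)
  W <- vapply(models, function(m) {
    pd <- map_dissimilarity(cbind(X, m$maps))
    within_dispersion(pd[seq_len(n), n + seq_len(m$K), drop = FALSE],
                      m$labels, m$K, n)
  }, numeric(1))
  p <- C - 1                                   # effective dimensionality
  diff_k <- function(k) {
    i0 <- match(as.character(k - 1L), names(W))
    i1 <- match(as.character(k), names(W))
    if (is.na(i0) || is.na(i1)) return(NA_real_)
    (k - 1)^(2 / p) * W[i0] - k^(2 / p) * W[i1]
  }
  crit_kl <- function(k) {
    d1 <- diff_k(k); d2 <- diff_k(k + 1L)
    if (is.na(d1) || is.na(d2) || d2 == 0) return(NA_real_)
    abs(d1) / abs(d2)
  }

  crit_funs <- list(gamma = crit_gamma, silhouette = crit_silhouette,
                    davies_bouldin = crit_davies_bouldin,
                    point_biserial = crit_point_biserial, dunn = crit_dunn,
                    cross_validation = crit_cross_validation)
  scores <- matrix(NA_real_, nrow = length(k_range), ncol = 7,
                   dimnames = list(as.character(k_range),
                                   c(names(crit_funs), "krzanowski_lai")))
  for (i in seq_along(k_range)) {
    m <- models[[as.character(k_range[i])]]
    for (cn in names(crit_funs))
      scores[i, cn] <- crit_funs[[cn]](D, m$labels, model = m, maps = X)
    scores[i, "krzanowski_lai"] <- crit_kl(k_range[i])
  }

  normalized <- apply(scores, 2, function(v) {
    # an infinite score (e.g. Dunn with zero diameter) outranks every finite one
    if (any(is.infinite(v))) {
      fin <- v[is.finite(v)]
      v[v == Inf] <- if (length(fin)) max(fin) + 1 else 1
      v[v == -Inf] <- if (length(fin)) min(fin) - 1 else -1
    }
    if (all(is.na(v))) return(rep(0.5, length(v)))
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    out <- (v - rng[1]) / diff(rng)
    out[is.na(out)] <- 0                       # an incomputable criterion never votes for a K
    out
  })
  if (is.null(dim(normalized)))
    normalized <- matrix(normalized, nrow = 1, dimnames = dimnames(scores))

  ranks <- apply(normalized, 2, function(v) rank(v, ties.method = "average"))
  if (is.null(dim(ranks)))
    ranks <- matrix(ranks, nrow = 1, dimnames = dimnames(scores))
  med <- apply(ranks, 1, stats::median, na.rm = TRUE)
  k_selected <- k_range[which.max(med)]        # which.max takes the first (smaller K) on ties

  structure(
    list(k_range = k_range, scores = scores, normalized = normalized,
         median_rank = med, k_selected = k_selected,
         models = models[as.character(k_range)]),
    class = "metacriterion_report"
  )
}

#' @export
print.metacriterion_report <- function(x, ...) {
  cat(sprintf("<metacriterion_report> K candidates %s; selected K* = %d\n",
              paste(range(x$k_range), collapse = "-"), x$k_selected))
  print(round(cbind(x$normalized, median_rank = x$median_rank), 3))
  invisible(x)
}

#' Tidy a meta-criterion report for writing
#'
#' @param report A `metacriterion_report`.
#' @return A data.frame, one row per candidate K: raw and normalized
#'   criterion scores, the median rank, and a `selected` flag.
#' @export
metacriterion_table <- function(report) {
  stopifnot(inherits(report, "metacriterion_report"))
  data.frame(K = report$k_range, report$scores,
             setNames(as.data.frame(report$normalized),
                      paste0(colnames(report$normalized), "_norm")),
             median_rank = report$median_rank,
             selected = report$k_range == report$k_selected,
             row.names = NULL, check.names = FALSE)
}
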