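#' Group comparisons of microstate temporal parameters
#'
#' Two-sided independent two-sample t-tests (pooled variance by default,
#' Welch by flag) of each temporal parameter of each microstate class between
#' patients and controls, with Benjamini-Hochberg FDR correction applied
#' within each parameter family across the K classes (K comparisons per
#' family). Cells where both groups have zero variance are reported with
#' `NA` statistics and a note; the remaining cells proceed.
#'
#' @param metrics A per-subject metrics table as produced by
#'   [segment_subject()] rows bound together: columns `subject`, `group`,
#'   `class`, and the parameter columns.
#' @param parameters Which parameter columns to test.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A data.frame with one row per (parameter, class): `t`, `df`,
#'   `p`, `p_fdr`, group means and sizes, and `note`.
#' @export
group_ttests <- function(metrics,
                         parameters = c("duration_ms", "occurrence_per_s", "coverage"),
                         welch = FALSE) {
  stopifnot(all(c("subject", "group", "class") %in% names(metrics)))
  groups <- unique(metrics$group)
  if (length(groups) != 2L)
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "))
  classes <- sort(unique(metrics$class))
  out <- expand.grid(parameter = parameters, class = classes,
                     stringsAsFactors = FALSE)
  out$t <- out$df <- out$p <- NA_real_
  out$mean_patient <- out$mean_control <- NA_real_
  out$n_patient <- out$n_control <- NA_integer_
  out$note <- ""
  g1 <- if ("patient" %in% groups) "patient" else groups[1]
  g2 <- setdiff(groups, g1)[1]
  for (i in seq_len(nrow(out))) {
    sub <- metrics[metrics$class == out$class[i], ]
    x <- sub[[out$parameter[i]]][sub$group == g1]
    y <- sub[[out$parameter[i]]][sub$group == g2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]         # pairwise deletion of absent-class cells
    out$n_patient[i] <- length(x); out$n_control[i] <- length(y)
    if (length(x) < 2L || length(y) < 2L) {
      out$note[i] <- "fewer than 2 observations in a group"
      next
    }
    out$mean_patient[i] <- mean(x); out$mean_control[i] <- mean(y)
    tt <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                   error = function(e) NULL)
    if (is.null(tt)) {
      out$note[i] <- "zero variance in both groups"
      next
    }
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  out$p_fdr <- NA_real_
  for (par in parameters) {
    idx <- which(out$parameter == par)
    out$p_fdr[idx] <- stats::p.adjust(out$p[idx], method = "BH")
  }
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-sided p
#' from the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return A list with `rho`, `p` and `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` have different lengths")
  if (anyNA(x) || anyNA(y)) stop("missing values: apply pairwise deletion first")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations, got ", n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate microstate parameters with clinical variables
#'
#' Spearman correlations of every (temporal parameter, microstate class)
#' cell with every clinical variable, over patients only, flagged at
#' `alpha` (default 0.01). The full Cartesian table is returned, not only
#' significant rows; cells with missing metric values use pairwise deletion,
#' and cells with fewer than 3 complete pairs get `NA` statistics.
#'
#' @param metrics Per-subject metrics table (as in [group_ttests()]).
#' @param clinical Data.frame with a `subject` column and one column per
#'   clinical variable (e.g. MADRS, CGI, number of episodes, illness
#'   duration, benzodiazepine-equivalent dose, medication scale).
#' @param variables Clinical columns to correlate; default all but `subject`
#'   (and `group` if present).
#' @param parameters Metric columns to correlate.
#' @param alpha Significance level for the flag.
#' @return A data.frame with one row per (parameter, class, variable):
#'   `rho`, `p`, `n`, `significant`.
#' @export
correlate_with_clinical <- function(metrics, clinical,
                                    variables = NULL,
                                    parameters = c("duration_ms",
                                                   "occurrence_per_s",
                                                   "coverage"),
                                    alpha = 0.01) {
  stopifnot(all(c("subject", "class") %in% names(metrics)),
            "subject" %in% names(clinical))
  if ("group" %in% names(metrics))
    metrics <- metrics[metrics$group == "patient", , drop = FALSE]
  unmatched <- setdiff(unique(metrics$subject), clinical$subject)
  if (length(unmatched))
    stop("subjects without clinical records: ", paste(unmatched, collapse = ", "))
  if (is.null(variables))
    variables <- setdiff(names(clinical), c("subject", "group"))
  classes <- sort(unique(metrics$class))
  out <- expand.grid(parameter = parameters, class = classes,
                     variable = variables, stringsAsFactors = FALSE)
  out$rho <- out$p <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sub <- metrics[metrics$class == out$class[i], c("subject", out$parameter[i])]
    merged <- merge(sub, clinical[, c("subject", out$variable[i])], by = "subject")
    v <- merged[[out$parameter[i]]]
    cv <- merged[[out$variable[i]]]
    ok <- !is.na(v) & !is.na(cv)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3L) next
    sc <- tryCatch(spearman_corr(v[ok], cv[ok]), error = function(e) NULL)
    if (is.null(sc)) next
    out$rho[i] <- sc$rho
    out$p[i] <- sc$p
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}
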