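#' Pooled-variance two-sample t test
#'
#' Student's two-sided t test with pooled variance (Welch available via
#' `var_equal = FALSE` but not used by the default pipeline).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param var_equal pool the variances (default TRUE).
#' @param label optional comparison label.
#' @return a `dfc_test` list: `statistic`, `p_value`, `df`, `label`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE, label = "t") {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter), label = label),
            class = "dfc_test")
}

#' Mann-Whitney U test
#'
#' U for the first sample computed from midranks (ties count one half), with a
#' two-sided normal-approximation p value using the tie-corrected variance.
#' Under complete separation with the first sample larger, U equals
#' `n_a * n_b`.
#'
#' @param a,b numeric samples.
#' @param label optional comparison label.
#' @return a `dfc_test` list with `statistic` (U), `p_value`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, label = "U") {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sigma2 == 0) 1 else {
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = U, p_value = min(1, p), n1 = n1, n2 = n2,
                 label = label),
            class = "dfc_test")
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; all expected counts must be positive.
#'
#' @param tab contingency matrix of counts.
#' @param label optional label.
#' @return a `dfc_test` list with `statistic`, `p_value`, `df`.
#' @export
chi_square_test <- function(tab, label = "chisq") {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected count in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter), label = label),
            class = "dfc_test")
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors (n >= 3 complete pairs, nonzero variance).
#' @param pair optional c(metric, clinical) name pair.
#' @return a `dfc_correlation` list: `r`, `p_value`, `n`, `pair`.
#' @export
pearson_correlation <- function(x, y, pair = c("x", "y")) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in '", pair[if (stats::sd(x) == 0) 1 else 2], "'")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x),
                 pair = pair),
            class = "dfc_correlation")
}

#' @export
print.dfc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$label, x$statistic, x$p_value))
  invisible(x)
}

#' @export
print.dfc_correlation <- function(x, ...) {
  cat(sprintf("r(%s, %s) = %.3f, p = %.4g, n = %d\n",
              x$pair[1], x$pair[2], x$r, x$p_value, x$n))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`; e.g. 0.05 over a family of 20 correlations gives 0.0025.
#'
#' @param alpha family-wise level.
#' @param m number of comparisons.
#' @return the adjusted per-test threshold.
#' @export
bonferroni_adjust <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Group comparisons of the DFC state metrics
#'
#' Pooled-variance t tests of each reoccurrence and transition metric between
#' patients and controls, with Bonferroni thresholds applied within the
#' reoccurrence family (k tests) and the transition family (k(k-1)/2 tests)
#' separately.
#'
#' @param metrics a [state_metrics()] data frame.
#' @param manifest cohort manifest.
#' @param alpha family-wise level (default 0.05).
#' @return data frame: metric, family, mean_patient, mean_control, statistic,
#'   p_value, alpha_bonferroni, significant_uncorrected, significant_corrected.
#' @export
group_metric_tests <- function(metrics, manifest, alpha = 0.05) {
  k <- attr(metrics, "k")
  grp <- manifest$group[match(metrics$subject_id, manifest$subject_id)]
  cols <- c(paste0("reocc_s", seq_len(k)),
            paste0("trans_", transition_pair_names(k)))
  family <- rep(c("reoccurrence", "transition"), c(k, k * (k - 1) / 2))
  fam_m <- c(reoccurrence = k, transition = k * (k - 1) / 2)
  rows <- Map(function(col, fam) {
    a <- metrics[[col]][grp == "patient"]
    b <- metrics[[col]][grp == "control"]
    tt <- tryCatch(two_sample_t(a, b, label = col),
                   error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    thr <- bonferroni_adjust(alpha, fam_m[[fam]])
    data.frame(metric = col, family = fam,
               mean_patient = mean(a), mean_control = mean(b),
               statistic = tt$statistic, p_value = tt$p_value,
               alpha_bonferroni = thr,
               significant_uncorrected = isTRUE(tt$p_value < alpha),
               significant_corrected = isTRUE(tt$p_value < thr))
  }, cols, family)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations between state metrics and clinical variables
#'
#' Pearson correlations of each reoccurrence and transition metric against the
#' clinical variables (CIPE total and IELT by default), over subjects with a
#' non-missing value of that variable. Significance is flagged at the
#' uncorrected 0.05 level and at the Bonferroni-adjusted threshold for the
#' full family (number of metrics x number of clinical variables; 20 at k = 4).
#'
#' @param metrics a [state_metrics()] data frame.
#' @param manifest cohort manifest.
#' @param clinical names of manifest columns to correlate against
#'   (default `c("cipe_total", "ielt_minutes")`).
#' @param alpha family-wise level (default 0.05).
#' @return data frame: metric, clinical, r, p_value, n, alpha_bonferroni,
#'   significant_uncorrected, significant_corrected.
#' @export
metric_clinical_correlations <- function(metrics, manifest,
                                         clinical = c("cipe_total", "ielt_minutes"),
                                         alpha = 0.05) {
  k <- attr(metrics, "k")
  cols <- c(paste0("reocc_s", seq_len(k)),
            paste0("trans_", transition_pair_names(k)))
  m_total <- length(cols) * length(clinical)
  thr <- bonferroni_adjust(alpha, m_total)
  idx <- match(metrics$subject_id, manifest$subject_id)
  rows <- list()
  for (cv in clinical) {
    y <- manifest[[cv]][idx]
    if (all(is.na(y))) stop("clinical variable '", cv, "' is entirely missing")
    for (col in cols) {
      # a metric constant across subjects (e.g. a never-used transition pair)
      # has no defined correlation; keep the row with NA rather than abort
      ct <- if (stats::sd(metrics[[col]][!is.na(y)]) == 0)
        list(r = NA_real_, p_value = NA_real_, n = sum(!is.na(y)))
      else pearson_correlation(metrics[[col]], y, pair = c(col, cv))
      rows[[length(rows) + 1L]] <-
        data.frame(metric = col, clinical = cv, r = ct$r, p_value = ct$p_value,
                   n = ct$n, alpha_bonferroni = thr,
                   significant_uncorrected = isTRUE(ct$p_value < alpha),
                   significant_corrected = isTRUE(ct$p_value < thr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
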