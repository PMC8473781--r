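#' Sliding-window parameters
#'
#' Defaults follow the common tapered-window DFC setup: a 22-TR rectangle
#' convolved with a Gaussian of sigma = 3 TRs, slid in steps of 1 TR, with an
#' L1 penalty on the precision matrix and Fisher-z transformed connectivity.
#'
#' @param length_tr window length in TRs (default 22).
#' @param sigma_tr Gaussian taper width in TRs (default 3).
#' @param step_tr slide step in TRs (default 1).
#' @param l1_lambda L1 penalty on the precision matrix; 0 gives plain
#'   taper-weighted Pearson correlations (default 0.1).
#' @param use_fisher_z Fisher-z transform connectivity values (default TRUE).
#' @return a `window_params` list.
#' @export
window_params <- function(length_tr = 22L, sigma_tr = 3, step_tr = 1L,
                          l1_lambda = 0.1, use_fisher_z = TRUE) {
  stopifnot(length_tr >= 1, sigma_tr > 0, step_tr >= 1, l1_lambda >= 0)
  structure(list(length_tr = as.integer(length_tr), sigma_tr = sigma_tr,
                 step_tr = as.integer(step_tr), l1_lambda = l1_lambda,
                 use_fisher_z = isTRUE(use_fisher_z)),
            class = "window_params")
}

#' Build the tapered window
#'
#' Convolves a unit rectangle of `length_tr` samples with a zero-mean discrete
#' Gaussian kernel of width `sigma_tr`, keeps the central `length_tr` samples
#' (zero-padded edges), and normalises to sum 1. The result is strictly
#' positive, symmetric, and peaked at the window centre; as `sigma_tr -> 0` it
#' approaches the flat rectangle.
#'
#' @param length_tr window length in samples.
#' @param sigma_tr Gaussian sigma in samples.
#' @return numeric vector of `length_tr` weights summing to 1.
#' @export
build_taper <- function(length_tr, sigma_tr) {
  if (length_tr < 1) stop("length_tr must be >= 1")
  if (sigma_tr <= 0) stop("sigma_tr must be > 0")
  L <- as.integer(length_tr)
  # central conv samples: w[i] = sum_m g(i - m), m over rectangle positions
  i <- seq_len(L)
  w <- vapply(i, function(ii) sum(exp(-((ii - seq_len(L))^2) / (2 * sigma_tr^2))), 0)
  w / sum(w)
}

#' Number of sliding windows
#'
#' `floor((T - length_tr) / step_tr) + 1`; e.g. 230 TRs with a 22-TR window in
#' steps of 1 give 209 windows.
#'
#' @param n_timepoints series length T.
#' @param length_tr window length.
#' @param step_tr slide step.
#' @return integer window count.
#' @export
count_windows <- function(n_timepoints, length_tr, step_tr = 1L) {
  if (n_timepoints < length_tr)
    stop("series shorter than the window: T = ", n_timepoints,
         " < length_tr = ", length_tr)
  if (step_tr < 1) stop("step_tr must be >= 1")
  as.integer((n_timepoints - length_tr) %/% step_tr + 1L)
}

#' Number of region pairs
#'
#' `R * (R - 1) / 2` unordered ROI pairs; 264 regions give 34,716 features.
#'
#' @param n_regions number of regions R.
#' @return integer pair count.
#' @export
pair_count <- function(n_regions) {
  if (n_regions < 2) stop("need at least 2 regions")
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' Names of the upper-triangle pairs in row-major order
#'
#' Fixed pair ordering (1,2),(1,3),...,(1,R),(2,3),... so that connectivity
#' vectors and centroids are comparable across runs.
#' @param n_regions number of regions.
#' @return character vector of length `pair_count(n_regions)`.
#' @export
pair_names <- function(n_regions) {
  idx <- which(lower.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  # column-major lower triangle of the transpose = row-major upper triangle
  paste0("r", idx[, 2], "_r", idx[, 1])
}

# Extract the row-major upper triangle of a symmetric matrix.
# For symmetric M, M[lower.tri(M)] in column-major order visits exactly
# the pairs (i,j), i<j grouped by i — the documented row-major pair order.
#' @noRd
upper_pairs <- function(m) m[lower.tri(m)]

#' @noRd
fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

#' Connectivity of one window segment
#'
#' Computes the taper-weighted covariance of the segment (weighted mean
#' removed), then either converts it to the weighted Pearson correlation matrix
#' (`l1_lambda = 0`) or estimates the L1-penalised precision matrix from the
#' weighted correlation (graphical lasso) and converts it to partial
#' correlations `-P_ij / sqrt(P_ii P_jj)`. Off-diagonals are optionally
#' Fisher-z transformed (clipped to |r| <= 1 - 1e-7) and returned as the
#' row-major upper-triangle vector.
#'
#' @param segment numeric matrix, `length_tr` x R.
#' @param taper positive weights of length `nrow(segment)` (normalised
#'   internally).
#' @param l1_lambda nonnegative L1 penalty; 0 disables the sparse estimator.
#' @param use_fisher_z logical.
#' @return numeric vector of `pair_count(R)` connectivity values.
#' @export
window_connectivity <- function(segment, taper, l1_lambda = 0,
                                use_fisher_z = TRUE) {
  segment <- as.matrix(segment)
  stopifnot(length(taper) == nrow(segment), all(taper > 0))
  w <- taper / sum(taper)
  mu <- colSums(segment * w)
  xc <- sweep(segment, 2, mu)
  cov_w <- crossprod(xc * sqrt(w), xc * sqrt(w))
  d <- diag(cov_w)
  if (any(d <= 0))
    stop("zero weighted variance in column(s): ",
         paste(which(d <= 0), collapse = ", "))
  corr <- cov_w / sqrt(outer(d, d))
  if (l1_lambda == 0) {
    r <- upper_pairs(corr)
  } else {
    prec <- glasso_precision(corr, l1_lambda)
    pd <- diag(prec)
    pc <- -prec / sqrt(outer(pd, pd))
    r <- upper_pairs(pc)
  }
  if (use_fisher_z) fisher_z(r) else r
}

#' Windowed dynamic connectivity for one subject
#'
#' Slides the tapered window over the subject's time series and estimates one
#' connectivity vector per window, giving a W x F matrix (W windows, F region
#' pairs) of class `subject_dfc`.
#'
#' @param ts a [roi_timeseries()].
#' @param params a [window_params()].
#' @return `subject_dfc`: list with `subject_id`, `dfc` (W x F matrix),
#'   `window_starts` (0-based start indices), `params`.
#' @export
subject_dfc <- function(ts, params = window_params()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  T_ <- nrow(x); R_ <- ncol(x)
  L <- params$length_tr
  W <- count_windows(T_, L, params$step_tr)
  taper <- build_taper(L, params$sigma_tr)
  starts <- seq(0L, by = params$step_tr, length.out = W)
  out <- matrix(NA_real_, W, pair_count(R_))
  for (wi in seq_len(W)) {
    seg <- x[(starts[wi] + 1L):(starts[wi] + L), , drop = FALSE]
    out[wi, ] <- tryCatch(
      window_connectivity(seg, taper, params$l1_lambda, params$use_fisher_z),
      error = function(e) stop("window ", wi, " (subject ", ts$subject_id,
                               "): ", conditionMessage(e), call. = FALSE))
  }
  colnames(out) <- pair_names(R_)
  dfc_log("dfc", sprintf("subject %s: %d windows x %d pairs (L=%d, sigma=%g, lambda=%g)",
                         ts$subject_id, W, ncol(out), L, params$sigma_tr,
                         params$l1_lambda))
  structure(list(subject_id = ts$subject_id, dfc = out,
                 window_starts = starts, params = params),
            class = "subject_dfc")
}

#' @export
print.subject_dfc <- function(x, ...) {
  cat(sprintf("DFC for '%s': %d windows x %d pairs\n",
              x$subject_id, nrow(x$dfc), ncol(x$dfc)))
  invisible(x)
}

#' L1-penalised precision matrix (graphical lasso)
#'
#' Block coordinate-descent estimate of the sparse inverse of a covariance or
#' correlation matrix, with the diagonal penalised (`W_ii = S_ii + lambda`).
#'
#' @param s symmetric positive semi-definite matrix.
#' @param lambda nonnegative penalty.
#' @param max_iter maximum outer sweeps.
#' @param tol convergence tolerance on the average absolute off-diagonal
#'   change of the working covariance.
#' @return the estimated precision matrix.
#' @export
glasso_precision <- function(s, lambda, max_iter = 100L, tol = 1e-4) {
  s <- as.matrix(s)
  stopifnot(nrow(s) == ncol(s), lambda >= 0)
  res <- glasso_cpp(s, lambda, as.integer(max_iter), tol)
  if (!res$converged)
    warning("graphical lasso did not reach tolerance in ", max_iter,
            " sweeps (residual ", signif(res$residual, 3), ")")
  res$precision
}
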