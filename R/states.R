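#' Across-pair connectivity variance per window
#'
#' For each window, the variance of its F pair-connectivity values (population
#' convention, dividing by F). High-variance windows carry pronounced
#' connectivity structure and serve as clustering exemplars.
#'
#' @param dfc a [subject_dfc()] or a W x F matrix.
#' @return numeric vector of length W.
#' @export
fc_variance_series <- function(dfc) {
  m <- if (inherits(dfc, "subject_dfc")) dfc$dfc else as.matrix(dfc)
  rm_ <- rowMeans(m)
  rowMeans(m^2) - rm_^2
}

#' Exemplar window selection at variance local maxima
#'
#' Returns the (1-based) indices of strict interior local maxima of the
#' variance series: `v[w] > v[w-1]` and `v[w] > v[w+1]`, endpoints excluded.
#' If no strict interior maximum exists (monotone series, plateaus), falls
#' back to the single global argmax (first of ties).
#'
#' @param variance numeric vector (length >= 1).
#' @return integer indices of exemplar windows.
#' @export
select_exemplars <- function(variance) {
  w <- length(variance)
  if (w >= 3) {
    interior <- 2:(w - 1)
    hit <- variance[interior] > variance[interior - 1] &
           variance[interior] > variance[interior + 1]
    if (any(hit)) return(interior[hit])
  }
  which.max(variance)
}

#' Fit recurring DFC states across a cohort
#'
#' Two-stage state identification. Stage 1: each subject contributes its
#' exemplar windows (local maxima of across-pair connectivity variance); the
#' pooled exemplars are clustered by k-means under correlation distance with
#' `n_init` random restarts, and when `k = "auto"` the number of states is
#' chosen by the elbow criterion on the exemplar set. Stage 2: every window of
#' every subject is clustered by a single k-means run initialised at the
#' stage-1 centroids. States are then relabelled in descending order of total
#' occupancy, so state 1 is always the most frequent.
#'
#' @param dfc_list list of [subject_dfc()] objects.
#' @param params a [cluster_params()].
#' @return an object of class `dfc_state_model`: `centroids` (k x F, unit-norm
#'   standardised scale), `assignments` (named list of per-subject label
#'   vectors in 1..k), `k`, `elbow_curve` (when `k = "auto"`), `exemplar_index`
#'   (per subject), `params`.
#' @export
fit_dfc_states <- function(dfc_list, params = cluster_params()) {
  stopifnot(length(dfc_list) >= 1,
            all(vapply(dfc_list, inherits, TRUE, "subject_dfc")))
  ids <- vapply(dfc_list, `[[`, "", "subject_id")
  exemplar_index <- lapply(dfc_list, function(d) select_exemplars(fc_variance_series(d)))
  exemplars <- do.call(rbind, Map(function(d, idx) d$dfc[idx, , drop = FALSE],
                                  dfc_list, exemplar_index))
  dfc_log("cluster", sprintf("%d subjects, %d exemplar windows pooled (seed %d)",
                             length(dfc_list), nrow(exemplars), params$seed))

  elbow <- NULL
  k <- params$k
  if (identical(k, "auto")) {
    sel <- elbow_select_k(exemplars, params$k_range, n_init = params$n_init,
                          max_iter = params$max_iter, seed = params$seed)
    k <- sel$k_star
    elbow <- sel$elbow_curve
    dfc_log("cluster", "elbow criterion selected k = ", k)
  }
  if (nrow(exemplars) < k)
    stop("total exemplars (", nrow(exemplars), ") fewer than k = ", k)

  stage1 <- kmeans_correlation(exemplars, k, n_init = params$n_init,
                               max_iter = params$max_iter, seed = params$seed)
  all_windows <- do.call(rbind, lapply(dfc_list, `[[`, "dfc"))
  stage2 <- kmeans_correlation(all_windows, k, max_iter = params$max_iter,
                               init = stage1$centroids)

  # canonical labels: state 1 = most occupied
  occ <- tabulate(stage2$labels, nbins = k)
  ord <- order(occ, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[stage2$labels]
  centroids <- stage2$centroids[ord, , drop = FALSE]
  rownames(centroids) <- paste0("state", seq_len(k))

  n_win <- vapply(dfc_list, function(d) nrow(d$dfc), 0L)
  assignments <- split(labels, rep(seq_along(dfc_list), n_win))
  names(assignments) <- ids
  low <- tabulate(labels, nbins = k) < max(2L, round(0.001 * length(labels)))
  if (any(low))
    dfc_log("cluster", "near-empty state(s) after fitting: ",
            paste(which(low), collapse = ", "))

  structure(list(centroids = centroids, assignments = assignments, k = k,
                 elbow_curve = elbow, exemplar_index = stats::setNames(exemplar_index, ids),
                 inertia = stage2$inertia, params = params,
                 call = match.call()),
            class = "dfc_state_model")
}

#' @export
print.dfc_state_model <- function(x, ...) {
  occ <- tabulate(unlist(x$assignments), nbins = x$k)
  cat(sprintf("DFC state model: k = %d states, %d subjects, %d windows\n",
              x$k, length(x$assignments), sum(occ)))
  cat("  occupancy:",
      paste(sprintf("state %d = %d (%.1f%%)", seq_len(x$k), occ,
                    100 * occ / sum(occ)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dfc_state_model <- function(object, ...) {
  occ <- tabulate(unlist(object$assignments), nbins = object$k)
  out <- list(k = object$k, n_subjects = length(object$assignments),
              n_windows = sum(occ), occupancy = occ,
              occupancy_pct = 100 * occ / sum(occ),
              elbow_curve = object$elbow_curve, inertia = object$inertia)
  class(out) <- "summary.dfc_state_model"
  out
}

#' @export
print.summary.dfc_state_model <- function(x, ...) {
  cat(sprintf("DFC state model (k = %d): %d subjects, %d windows, inertia %.2f\n",
              x$k, x$n_subjects, x$n_windows, x$inertia))
  print(data.frame(state = seq_len(x$k), windows = x$occupancy,
                   percent = round(x$occupancy_pct, 2)), row.names = FALSE)
  if (!is.null(x$elbow_curve)) {
    cat("elbow curve (within/between distance ratio):\n")
    print(x$elbow_curve, row.names = FALSE)
  }
  invisible(x)
}

#' Assign new windows to fitted states
#'
#' Nearest-centroid classification under correlation distance.
#'
#' @param object a fitted `dfc_state_model`.
#' @param newdata a [subject_dfc()] or a W x F matrix of window vectors.
#' @param ... unused.
#' @return integer state labels in 1..k.
#' @export
predict.dfc_state_model <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "subject_dfc")) newdata$dfc else as.matrix(newdata)
  stopifnot(ncol(m) == ncol(object$centroids))
  d <- corr_dist_matrix(standardize_rows(m), object$centroids)
  max.col(-d, ties.method = "first")
}

#' Plot the elbow curve of a DFC state model
#'
#' @param x a `dfc_state_model` fitted with `k = "auto"`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.dfc_state_model <- function(x, ...) {
  if (is.null(x$elbow_curve)) {
    occ <- tabulate(unlist(x$assignments), nbins = x$k)
    graphics::barplot(occ, names.arg = paste0("state ", seq_len(x$k)),
                      ylab = "windows", main = "State occupancy", ...)
  } else {
    plot(x$elbow_curve$k, x$elbow_curve$ratio, type = "b", xlab = "k",
         ylab = "within / between distance ratio", main = "Elbow curve", ...)
    graphics::abline(v = x$k, lty = 2)
  }
  invisible(x)
}
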