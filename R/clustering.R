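#' Clustering parameters
#'
#' @param k number of states, or `"auto"` for elbow-based selection.
#' @param k_range candidate k values when `k = "auto"` (default 2:8).
#' @param n_init random restarts for the exemplar-stage k-means (default 50).
#' @param max_iter Lloyd iteration cap per run (default 500).
#' @param seed integer seed for centroid initialisation.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(k = "auto", k_range = 2:8, n_init = 50L,
                           max_iter = 500L, seed = 1L) {
  if (!identical(k, "auto")) {
    stopifnot(is.numeric(k), k >= 2)
    k <- as.integer(k)
  }
  k_range <- as.integer(k_range)
  stopifnot(all(k_range >= 2), all(k_range <= 12), n_init >= 1, max_iter >= 1)
  structure(list(k = k, k_range = sort(k_range), n_init = as.integer(n_init),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "cluster_params")
}

# Standardise rows to zero mean, unit L2 norm: correlation distance between
# raw rows equals 0.5 * squared Euclidean distance between standardised rows.
#' @noRd
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-variance row(s): ",
                          paste(which(nrm == 0), collapse = ", "))
  x / nrm
}

#' Correlation distance between two vectors
#'
#' `1 - Pearson(x, y)`, in \[0, 2\]; 0 for positively affinely related vectors,
#' 2 for perfect anticorrelation. Sensitive to pattern, not magnitude.
#'
#' @param x,y numeric vectors of equal length with nonzero variance.
#' @return a scalar distance.
#' @export
correlation_distance <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation distance undefined for a zero-variance vector")
  1 - stats::cor(x, y)
}

# cross-correlation of standardised rows against standardised centroids
#' @noRd
corr_dist_matrix <- function(xs, centroids_s) 1 - tcrossprod(xs, centroids_s)

#' k-means clustering under correlation distance
#'
#' Lloyd iterations with the correlation distance, implemented on row-standardised
#' data where the distance is half the squared Euclidean distance. Each restart
#' initialises centroids at k distinct rows; the best of `n_init` runs by total
#' within-cluster distance is returned. An emptied cluster is re-seeded at the
#' row farthest from its centroid. Deterministic given `seed`.
#'
#' @param x numeric matrix, n rows (observations) x F columns.
#' @param k number of clusters (2 <= k <= n).
#' @param n_init number of random restarts.
#' @param max_iter Lloyd iteration cap.
#' @param seed integer seed.
#' @param init optional k x F matrix of starting centroids; when given, a
#'   single run from these centroids is performed (no random restarts).
#' @return list with `centroids` (k x F, on the standardised scale), `labels`
#'   (length n, in 1..k), `inertia` (total within-cluster correlation distance),
#'   `iterations`.
#' @export
kmeans_correlation <- function(x, k, n_init = 50L, max_iter = 500L, seed = 1L,
                               init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) stop("fewer rows (", n, ") than clusters (", k, ")")
  xs <- standardize_rows(x)

  # a centroid can degenerate to zero norm when its members' standardised
  # rows cancel; re-seed such centroids from the data
  fix_centroids <- function(cent) {
    cc <- cent - rowMeans(cent)
    nrm <- sqrt(rowSums(cc^2))
    bad <- !is.finite(nrm) | nrm < 1e-12
    if (any(bad)) cent[bad, ] <- xs[sample.int(n, sum(bad)), , drop = FALSE]
    standardize_rows(cent)
  }

  run_lloyd <- function(cent) {
    cent <- fix_centroids(cent)
    labels <- integer(n)
    for (it in seq_len(max_iter)) {
      d <- corr_dist_matrix(xs, cent)
      new_labels <- max.col(-d, ties.method = "first")
      reseeded <- integer(0)               # re-seed emptied clusters, each
      for (ci in seq_len(k)) {             # from a distinct farthest point
        if (!any(new_labels == ci)) {
          dist_own <- d[cbind(seq_len(n), new_labels)]
          dist_own[reseeded] <- -Inf
          far <- which.max(dist_own)
          new_labels[far] <- ci
          reseeded <- c(reseeded, far)
        }
      }
      if (it > 1L && all(new_labels == labels)) break
      labels <- new_labels
      cent <- t(vapply(seq_len(k),
                       function(ci) colMeans(xs[labels == ci, , drop = FALSE]),
                       numeric(ncol(xs))))
      cent <- fix_centroids(cent)
    }
    d <- corr_dist_matrix(xs, cent)
    inertia <- sum(d[cbind(seq_len(n), labels)])
    list(centroids = cent, labels = labels, inertia = inertia, iterations = it)
  }

  if (!is.null(init)) {
    stopifnot(nrow(init) == k, ncol(init) == ncol(x))
    return(run_lloyd(as.matrix(init)))
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    cent <- xs[sample.int(n, k), , drop = FALSE]
    fit <- run_lloyd(cent)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

#' Elbow-criterion choice of the number of states
#'
#' For each candidate k, fits [kmeans_correlation()] and computes the ratio of
#' the mean within-cluster correlation distance to the mean between-centroid
#' correlation distance. The selected k maximises the discrete second
#' difference `ratio(k-1) - 2 ratio(k) + ratio(k+1)` over interior candidates
#' (the sharpest bend of the curve); ties break toward smaller k. When the
#' curve attains its minimum at the smallest candidate, no bend lies to its
#' right and that candidate is returned directly; a monotonically increasing
#' curve additionally raises a warning (no elbow exists).
#'
#' @param x data matrix (rows clustered).
#' @param k_range integer candidates (>= 3 values for an interior bend).
#' @param n_init,max_iter,seed passed to [kmeans_correlation()].
#' @return list with `k_star` and `elbow_curve` (data frame k, ratio).
#' @export
elbow_select_k <- function(x, k_range = 2:8, n_init = 50L, max_iter = 500L,
                           seed = 1L) {
  k_range <- sort(as.integer(k_range))
  n <- nrow(x)
  k_range <- k_range[k_range <= n - 1L]
  if (!length(k_range)) stop("no feasible k in k_range for n = ", n)
  ratio <- vapply(k_range, function(k) {
    fit <- kmeans_correlation(x, k, n_init = n_init, max_iter = max_iter,
                              seed = seed + k)
    within <- fit$inertia / n
    cent <- fit$centroids
    bet <- corr_dist_matrix(cent, cent)
    between <- mean(bet[lower.tri(bet)])
    within / between
  }, 0)
  curve <- data.frame(k = k_range, ratio = ratio)
  if (all(diff(ratio) >= 0)) {
    warning("elbow curve monotonically increasing; returning smallest k")
    return(list(k_star = k_range[1], elbow_curve = curve))
  }
  if (which.min(ratio) == 1L)
    return(list(k_star = k_range[1], elbow_curve = curve))
  if (length(k_range) < 3) {
    k_star <- k_range[which.min(ratio)]
    return(list(k_star = k_star, elbow_curve = curve))
  }
  interior <- 2:(length(k_range) - 1)
  curvature <- ratio[interior - 1] - 2 * ratio[interior] + ratio[interior + 1]
  k_star <- k_range[interior][which.max(curvature)]
  list(k_star = k_star, elbow_curve = curve)
}
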