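#' State reoccurrence times for one subject
#'
#' The reoccurrence time of a state is the number of windows assigned to it;
#' the counts sum to the subject's window count W.
#'
#' @param assignments integer window labels in 1..k.
#' @param k number of states.
#' @return integer vector of k counts.
#' @export
reoccurrence_times <- function(assignments, k) {
  assignments <- as.integer(assignments)
  if (any(assignments < 1L | assignments > k))
    stop("state label out of range 1..", k)
  tabulate(assignments, nbins = k)
}

#' Undirected state transition frequencies for one subject
#'
#' Scans successive window pairs; each change of state increments the counter
#' of the unordered state pair involved (a move 1 -> 2 and a move 2 -> 1 both
#' count toward pair (1,2)). Self-transitions are not counted. Pairs are in
#' row-major order (1,2),(1,3),...,(k-1,k).
#'
#' @param assignments integer window labels in 1..k.
#' @param k number of states.
#' @param directed if TRUE, returns the k*(k-1) directed counts instead
#'   (row-major (i -> j), i != j); off by default and unused by the standard
#'   pipeline.
#' @return integer vector of `k*(k-1)/2` pair counts (or `k*(k-1)` directed).
#' @export
transition_frequencies <- function(assignments, k, directed = FALSE) {
  assignments <- as.integer(assignments)
  if (any(assignments < 1L | assignments > k))
    stop("state label out of range 1..", k)
  from <- assignments[-length(assignments)]
  to <- assignments[-1L]
  move <- from != to
  from <- from[move]; to <- to[move]
  if (directed) {
    counts <- matrix(0L, k, k)
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    idx <- which(row(counts) != col(counts))
    idx <- idx[order(row(counts)[idx], col(counts)[idx])]
    return(stats::setNames(counts[idx],
                           paste0("s", row(counts)[idx], "_to_s", col(counts)[idx])))
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  counts <- matrix(0L, k, k)
  for (i in seq_along(lo)) counts[lo[i], hi[i]] <- counts[lo[i], hi[i]] + 1L
  out <- t(counts)[lower.tri(counts)]  # row-major upper triangle
  stats::setNames(out, transition_pair_names(k))
}

#' @rdname transition_frequencies
#' @export
transition_pair_names <- function(k) {
  idx <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
  paste0("s", idx[, 2], "_s", idx[, 1])
}

#' Number of distinct states visited
#'
#' @param assignments integer window labels.
#' @return count of unique labels present.
#' @export
distinct_state_count <- function(assignments) {
  stopifnot(length(assignments) > 0)
  length(unique(assignments))
}

#' Per-subject state metrics for a fitted model
#'
#' @param model a [fit_dfc_states()] result.
#' @return data frame of class `subject_state_metrics`: one row per subject
#'   with `subject_id`, `n_states`, `reocc_s1..sk`, and the undirected
#'   transition counts `trans_s*_s*`.
#' @export
state_metrics <- function(model) {
  stopifnot(inherits(model, "dfc_state_model"))
  k <- model$k
  rows <- lapply(names(model$assignments), function(id) {
    a <- model$assignments[[id]]
    re <- reoccurrence_times(a, k)
    tr <- transition_frequencies(a, k)
    out <- data.frame(subject_id = id, n_states = distinct_state_count(a))
    out[paste0("reocc_s", seq_len(k))] <- as.list(re)
    out[paste0("trans_", transition_pair_names(k))] <- as.list(tr)
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "k") <- k
  class(res) <- c("subject_state_metrics", "data.frame")
  res
}

#' Group-by-state occupancy table
#'
#' Pools window counts per state within each group, with percentages of the
#' group total, group totals and the grand total — the standard occupancy
#' summary layout.
#'
#' @param metrics a [state_metrics()] data frame.
#' @param manifest a cohort manifest supplying each subject's group.
#' @return a `group_occupancy` list: `counts` (group x state matrix),
#'   `percent` (rounded to 2 decimals), `group_totals`, `grand_total`.
#' @export
group_occupancy_table <- function(metrics, manifest) {
  k <- attr(metrics, "k")
  grp <- manifest$group[match(metrics$subject_id, manifest$subject_id)]
  if (anyNA(grp)) stop("subject(s) missing from manifest: ",
                       paste(metrics$subject_id[is.na(grp)], collapse = ", "))
  re <- as.matrix(metrics[paste0("reocc_s", seq_len(k))])
  counts <- rowsum(re, grp)
  group_totals <- rowSums(counts)
  structure(list(counts = counts,
                 percent = round(100 * counts / group_totals, 2),
                 group_totals = group_totals,
                 grand_total = sum(counts)),
            class = "group_occupancy")
}

#' @export
print.group_occupancy <- function(x, ...) {
  k <- ncol(x$counts)
  cat("Windows per state by group:\n")
  disp <- matrix(sprintf("%d (%.2f%%)", x$counts, x$percent),
                 nrow = nrow(x$counts),
                 dimnames = list(rownames(x$counts), paste0("state ", seq_len(k))))
  disp <- cbind(disp, total = as.character(x$group_totals))
  print(as.data.frame(disp))
  cat("grand total:", x$grand_total, "\n")
  invisible(x)
}

#' Write the metrics / occupancy tables
#'
#' @param metrics a [state_metrics()] data frame.
#' @param manifest cohort manifest (adds the group column).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, manifest, path) {
  out <- as.data.frame(metrics)
  out$group <- manifest$group[match(out$subject_id, manifest$subject_id)]
  out <- out[c("subject_id", "group", setdiff(names(out), c("subject_id", "group")))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
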