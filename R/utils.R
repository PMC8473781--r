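#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structured stage logging
#'
#' Emits a single-line log message tagged with the pipeline stage. Controlled
#' by `options(dfcstates.verbose = TRUE/FALSE)`; on by default.
#' @param stage character stage tag.
#' @param ... values passed to [sprintf()]-style formatting via [paste0()].
#' @return invisibly, the message string.
#' @keywords internal
dfc_log <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("dfcstates.verbose", TRUE))) message(msg)
  invisible(msg)
}

#' Derive a stage seed from the pipeline seed
#'
#' One global seed governs the run; each stochastic stage draws its own seed
#' deterministically so stages can be re-run in isolation. The derivation is
#' `(seed * 48271 + stage_offset) mod (2^31 - 1)`, a fixed documented map.
#'
#' @param seed integer global seed.
#' @param stage one of `"simulate"`, `"cluster"`, `"classify"`, `"permute"`.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage = c("simulate", "cluster", "classify", "permute")) {
  stage <- match.arg(stage)
  offset <- c(simulate = 101L, cluster = 211L, classify = 307L, permute = 401L)[[stage]]
  as.integer((as.numeric(seed) * 48271 + offset) %% (2^31 - 1))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score recovery of planted state sequences.
#'
#' @param a,b integer/character label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions up to relabeling.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
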