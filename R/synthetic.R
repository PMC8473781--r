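#' Specification of a synthetic Markov-switching cohort
#'
#' Defines the generative model used to validate the pipeline end to end:
#' each subject's regional time series is multivariate Gaussian with a
#' covariance that switches among `k_true` latent states following a per-group
#' Markov chain, and clinical scores are linear in state occupancy plus noise.
#' Defaults emulate the study conditions the pipeline targets: 36 patients and
#' 23 controls, 230 timepoints, 4 latent states with block-structured
#' connectivity, patients spending more time in an "enriched" state (state
#' index 3) and less in the baseline state (index 1), and clinical scores
#' negatively coupled to the enriched-state occupancy.
#'
#' Transition matrices have the sticky form `P = s I + (1 - s) 1 pi'`, whose
#' stationary distribution is exactly `pi` and whose mean dwell time in state
#' i is `1 / ((1 - s)(1 - pi_i))`; the default `stay = 0.98` gives mean dwells
#' of 50+ TRs, i.e. at least twice the 22-TR window, so windowed estimates can
#' resolve the states.
#'
#' @param n_patients,n_controls group sizes (defaults 36, 23).
#' @param n_timepoints series length T (default 230).
#' @param n_regions regions R (default 60; 264 supported).
#' @param k_true number of latent states (default 4).
#' @param occupancy_patient,occupancy_control stationary state distributions
#'   (defaults mirror a baseline-dominant control profile and an
#'   enriched-state shift in patients).
#' @param stay self-transition stickiness s in (0, 1) (default 0.98).
#' @param within_block_r,between_block_r block correlation levels of the state
#'   covariances (defaults 0.6, 0.15).
#' @param noise_sd observation noise standard deviation (default 0.5).
#' @param cipe_coupling,ielt_coupling lists `(intercept, slopes, noise_sd)`;
#'   slopes act on the k occupancy fractions. Defaults plant a positive
#'   coupling to baseline-state occupancy and a negative coupling to
#'   enriched-state occupancy, calibrated for planted |r| around 0.3-0.45.
#' @param tr_seconds repetition time (default 2).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 36L, n_controls = 23L,
                        n_timepoints = 230L, n_regions = 60L, k_true = 4L,
                        occupancy_patient = c(0.38, 0.13, 0.30, 0.19),
                        occupancy_control = c(0.55, 0.12, 0.20, 0.13),
                        stay = 0.98,
                        within_block_r = 0.6, between_block_r = 0.15,
                        noise_sd = 0.5,
                        cipe_coupling = list(intercept = 14, slopes = c(15, 0, -15, 0), noise_sd = 14),
                        ielt_coupling = list(intercept = 10, slopes = c(4, 0, -4, 0), noise_sd = 4.7),
                        tr_seconds = 2, seed = 1L) {
  stopifnot(k_true >= 2, length(occupancy_patient) == k_true,
            length(occupancy_control) == k_true,
            abs(sum(occupancy_patient) - 1) < 1e-8,
            abs(sum(occupancy_control) - 1) < 1e-8,
            stay > 0, stay < 1, noise_sd >= 0)
  markov_patient <- sticky_chain(occupancy_patient, stay)
  markov_control <- sticky_chain(occupancy_control, stay)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_timepoints = as.integer(n_timepoints),
                 n_regions = as.integer(n_regions), k_true = as.integer(k_true),
                 occupancy_patient = occupancy_patient,
                 occupancy_control = occupancy_control,
                 markov_patient = markov_patient,
                 markov_control = markov_control, stay = stay,
                 within_block_r = within_block_r,
                 between_block_r = between_block_r, noise_sd = noise_sd,
                 cipe_coupling = cipe_coupling, ielt_coupling = ielt_coupling,
                 tr_seconds = tr_seconds, seed = as.integer(seed)),
            class = "cohort_spec")
}

# P = s I + (1-s) 1 pi': row-stochastic, stationary distribution exactly pi.
#' @noRd
sticky_chain <- function(pi, stay) {
  k <- length(pi)
  stay * diag(k) + (1 - stay) * matrix(pi, k, k, byrow = TRUE)
}

#' Block-structured state covariance matrices
#'
#' Builds `k` correlation-scale SPD matrices over `R` regions partitioned into
#' `2k` contiguous blocks. Each state activates a distinct disjoint pair of
#' blocks: active blocks get `within_block_r` internal correlation and
#' `between_block_r` correlation to each other; all other entries are 0.
#' Distinct states therefore have nearly orthogonal vectorised connectivity
#' patterns. Matrices are SPD by construction; if numerical flooring is ever
#' needed, eigenvalues are floored at 1e-6.
#'
#' @param n_regions number of regions R.
#' @param k number of states.
#' @param within_block_r within-block correlation (|r| < 1).
#' @param between_block_r correlation between a state's two active blocks.
#' @param seed unused placeholder for interface stability (construction is
#'   deterministic).
#' @return list of k R x R covariance matrices; attribute `"blocks"` holds
#'   the block index of each region.
#' @export
make_state_covariances <- function(n_regions, k, within_block_r = 0.6,
                                   between_block_r = 0.15, seed = 1L) {
  stopifnot(abs(within_block_r) < 1, abs(between_block_r) < 1, k >= 1)
  n_blocks <- 2L * k
  if (n_regions < n_blocks)
    stop("need at least ", n_blocks, " regions for ", k, " states")
  blocks <- sort(rep_len(seq_len(n_blocks), n_regions))
  covs <- vector("list", k)
  for (s in seq_len(k)) {
    active <- c(2L * s - 1L, 2L * s)
    sig <- diag(n_regions)
    for (bl in active) {
      idx <- which(blocks == bl)
      sig[idx, idx] <- within_block_r
    }
    i1 <- which(blocks == active[1]); i2 <- which(blocks == active[2])
    sig[i1, i2] <- between_block_r
    sig[i2, i1] <- between_block_r
    diag(sig) <- 1
    ev <- eigen(sig, symmetric = TRUE)
    if (min(ev$values) < 1e-6) {
      vals <- pmax(ev$values, 1e-6)
      sig <- ev$vectors %*% (vals * t(ev$vectors))
    }
    covs[[s]] <- sig
  }
  attr(covs, "blocks") <- blocks
  covs
}

# draw a latent Markov state sequence from its stationary start
#' @noRd
markov_sequence <- function(P, pi, n) {
  k <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = pi)
  for (t in 2:n) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  s
}

#' Simulate one subject's switching time series
#'
#' Draws a latent state sequence from the group's Markov chain (started at its
#' stationary distribution), then each timepoint from the current state's
#' zero-mean Gaussian, plus isotropic observation noise.
#'
#' @param spec a [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param covariances optional precomputed [make_state_covariances()] output
#'   (rebuilt from the spec when omitted).
#' @return list with `ts` (a [roi_timeseries()]) and `latent` (length-T state
#'   sequence).
#' @export
simulate_subject <- function(spec, group = c("patient", "control"), seed = 1L,
                             subject_id = "sim", covariances = NULL) {
  group <- match.arg(group)
  if (is.null(covariances))
    covariances <- make_state_covariances(spec$n_regions, spec$k_true,
                                          spec$within_block_r,
                                          spec$between_block_r, spec$seed)
  P <- if (group == "patient") spec$markov_patient else spec$markov_control
  pi <- if (group == "patient") spec$occupancy_patient else spec$occupancy_control
  chol_list <- attr(covariances, "chol") %||% lapply(covariances, chol)
  set.seed(seed)
  latent <- markov_sequence(P, pi, spec$n_timepoints)
  x <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions),
              spec$n_timepoints, spec$n_regions)
  for (s in unique(latent)) {
    rows <- latent == s
    x[rows, ] <- x[rows, , drop = FALSE] %*% chol_list[[s]]
  }
  if (spec$noise_sd > 0)
    x <- x + spec$noise_sd * matrix(stats::rnorm(length(x)),
                                    nrow(x), ncol(x))
  list(ts = roi_timeseries(x, subject_id = subject_id,
                           tr_seconds = spec$tr_seconds),
       latent = latent)
}

#' Simulate a full cohort with ground truth
#'
#' Generates all subjects, clinical scores linearly coupled to the realised
#' state-occupancy fractions (plus Gaussian noise), a mean framewise
#' displacement column drawn independently of everything else, and the ground
#' truth needed to score recovery. When `dir` is given, per-subject TSVs, the
#' manifest CSV and a ground-truth JSON are written there.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return list of class `synthetic_cohort`: `manifest`, `timeseries` (named
#'   list of [roi_timeseries()]), `ground_truth` (per-subject latent sequences,
#'   occupancy fractions, group chains, coupling coefficients, covariances).
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  covs <- make_state_covariances(spec$n_regions, spec$k_true,
                                 spec$within_block_r, spec$between_block_r,
                                 spec$seed)
  attr(covs, "chol") <- lapply(covs, chol)
  n_total <- spec$n_patients + spec$n_controls
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  ids <- sprintf("sub%03d", seq_len(n_total))
  base_seed <- stage_seed(spec$seed, "simulate")

  ts_list <- vector("list", n_total)
  latent <- vector("list", n_total)
  occ <- matrix(0, n_total, spec$k_true)
  for (i in seq_len(n_total)) {
    sim <- simulate_subject(spec, groups[i], seed = base_seed + i,
                            subject_id = ids[i], covariances = covs)
    ts_list[[i]] <- sim$ts
    latent[[i]] <- sim$latent
    occ[i, ] <- tabulate(sim$latent, spec$k_true) / spec$n_timepoints
  }
  names(ts_list) <- names(latent) <- ids

  set.seed(base_seed + n_total + 1L)
  cipe <- spec$cipe_coupling$intercept + drop(occ %*% spec$cipe_coupling$slopes) +
    stats::rnorm(n_total, sd = spec$cipe_coupling$noise_sd)
  ielt <- spec$ielt_coupling$intercept + drop(occ %*% spec$ielt_coupling$slopes) +
    stats::rnorm(n_total, sd = spec$ielt_coupling$noise_sd)
  ielt <- pmax(ielt, 0.1)
  mean_fd <- pmax(stats::rnorm(n_total, 0.09, 0.05), 0.01)

  manifest <- as_cohort_manifest(data.frame(
    subject_id = ids, group = groups,
    series_path = if (is.null(dir)) paste0(ids, ".tsv")
                  else file.path(dir, paste0(ids, ".tsv")),
    cipe_total = round(cipe), ielt_minutes = round(ielt, 2),
    mean_fd = round(mean_fd, 4), stringsAsFactors = FALSE))

  truth <- list(latent = latent, occupancy = occ,
                occupancy_patient = spec$occupancy_patient,
                occupancy_control = spec$occupancy_control,
                cipe_coupling = spec$cipe_coupling,
                ielt_coupling = spec$ielt_coupling,
                covariances = covs, k_true = spec$k_true)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_total))
      write_timeseries(ts_list[[i]], manifest$series_path[i])
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(k_true = spec$k_true, latent = latent,
           occupancy = as.data.frame(occ),
           occupancy_patient = spec$occupancy_patient,
           occupancy_control = spec$occupancy_control),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  dfc_log("simulate", sprintf("cohort: %d patients + %d controls, T=%d, R=%d, k=%d (seed %d)",
                              spec$n_patients, spec$n_controls, spec$n_timepoints,
                              spec$n_regions, spec$k_true, spec$seed))
  structure(list(manifest = manifest, timeseries = ts_list,
                 ground_truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Match fitted states to planted states
#'
#' Pairs each fitted centroid with the planted state whose vectorised
#' correlation pattern it resembles most (greedy assignment on the centroid x
#' planted correlation matrix). Used to score sign recovery when the fitted
#' canonical labels (occupancy-ordered) differ from the generator's indices.
#'
#' @param model a [fit_dfc_states()] result.
#' @param covariances planted covariance list from [make_state_covariances()].
#' @return integer vector: element s is the planted state matched to fitted
#'   state s.
#' @export
match_states <- function(model, covariances) {
  planted <- vapply(covariances, function(s) {
    d <- diag(s); cc <- s / sqrt(outer(d, d)); upper_pairs(cc)
  }, numeric(pair_count(nrow(covariances[[1]]))))
  cmat <- stats::cor(t(model$centroids), planted)
  k <- nrow(cmat)
  mapping <- integer(k)
  for (i in seq_len(k)) {
    best <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
    mapping[best[1]] <- best[2]
    cmat[best[1], ] <- -Inf
    cmat[, best[2]] <- -Inf
  }
  mapping
}

#' Majority latent state within each sliding window
#'
#' Reference labels for scoring window-level state recovery: each window is
#' tagged with the most frequent latent state among its timepoints (ties to
#' the lower state index).
#'
#' @param latent length-T latent state sequence.
#' @param n_windows number of windows W.
#' @param length_tr window length.
#' @param step_tr slide step.
#' @return integer vector of W reference labels.
#' @export
window_majority_state <- function(latent, n_windows, length_tr, step_tr = 1L) {
  vapply(seq_len(n_windows), function(w) {
    seg <- latent[((w - 1L) * step_tr + 1L):((w - 1L) * step_tr + length_tr)]
    which.max(tabulate(seg, nbins = max(latent)))
  }, 0L)
}
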