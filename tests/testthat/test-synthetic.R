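test_that("state covariances are SPD with near-orthogonal vectorised patterns", {
  covs <- make_state_covariances(60, 4, 0.6, 0.15)
  expect_length(covs, 4)
  for (s in covs) {
    expect_equal(s, t(s))
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  vecs <- sapply(covs, function(s) s[lower.tri(s)])
  cc <- cor(vecs)
  expect_lte(max(abs(cc[lower.tri(cc)])), 0.5)
})

test_that("zero block correlations give identity covariances", {
  covs <- make_state_covariances(20, 2, 0, 0)
  for (s in covs) expect_equal(s, diag(20))
})

test_that("subject simulation is seed-deterministic with stationary-start chains", {
  spec <- small_spec(seed = 5)
  a <- simulate_subject(spec, "patient", seed = 11, subject_id = "a")
  b <- simulate_subject(spec, "patient", seed = 11, subject_id = "a")
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$latent, b$latent)
  c_ <- simulate_subject(spec, "patient", seed = 12)
  expect_false(identical(a$latent, c_$latent) && identical(a$ts$data, c_$ts$data))
  expect_true(all(a$latent %in% 1:4))
  expect_identical(length(a$latent), 120L)
})

test_that("a frozen chain yields one latent state and one fitted state", {
  spec <- small_spec(seed = 6, stay = 1 - 1e-12)
  sim <- simulate_subject(spec, "control", seed = 3)
  expect_identical(length(unique(sim$latent)), 1L)
  d <- subject_dfc(sim$ts, window_params(l1_lambda = 0))
  ref <- window_majority_state(sim$latent, nrow(d$dfc), 22)
  expect_identical(length(unique(ref)), 1L)
})

test_that("mean dwell time follows the geometric law of the sticky chain", {
  # uniform occupancy, self-transition probability 0.95 -> mean dwell 20 TRs
  k <- 4
  stay <- 1 - (1 - 0.95) / (1 - 1 / k)   # sticky form: P_ii = stay + (1-stay)/k
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_timepoints = 2000,
                      n_regions = 16, stay = stay,
                      occupancy_patient = rep(0.25, 4),
                      occupancy_control = rep(0.25, 4), seed = 1)
  expect_equal(diag(spec$markov_patient), rep(0.95, 4), tolerance = 1e-12)
  dwells <- c()
  for (s in 1:20) {
    sim <- simulate_subject(spec, "patient", seed = 500 + s)
    runs <- rle(sim$latent)$lengths
    dwells <- c(dwells, runs[-c(1, length(runs))])  # drop censored end runs
  }
  expect_lt(abs(mean(dwells) - 20) / 20, 0.1)
})

test_that("cohort simulation produces the full manifest with ground truth", {
  spec <- small_spec(seed = 7)
  co <- simulate_cohort(spec)
  expect_identical(nrow(co$manifest), 14L)
  expect_equal(unname(table(co$manifest$group)[c("patient", "control")]),
               c(8L, 6L), ignore_attr = TRUE)
  expect_length(co$timeseries, 14)
  expect_identical(dim(co$ground_truth$occupancy), c(14L, 4L))
  expect_equal(rowSums(co$ground_truth$occupancy), rep(1, 14))
  # same spec, same cohort; different seed, different cohort
  co2 <- simulate_cohort(spec)
  expect_identical(co$timeseries[[1]]$data, co2$timeseries[[1]]$data)
  co3 <- simulate_cohort(small_spec(seed = 8))
  expect_false(identical(co$timeseries[[1]]$data, co3$timeseries[[1]]$data))
})

test_that("cohort files round-trip through a directory", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_spec(n_patients = 2, n_controls = 2,
                                    n_timepoints = 60, n_regions = 10,
                                    seed = 9), dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 4L)
  ts <- read_timeseries(man$series_path[1], subject_id = man$subject_id[1])
  expect_equal(ts$data, co$timeseries[[man$subject_id[1]]]$data,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("zero coupling slopes leave clinical scores uncorrelated with occupancy", {
  null_coupling <- list(intercept = 10, slopes = c(0, 0, 0, 0), noise_sd = 3)
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_spec(n_regions = 12, seed = 600 + s,
                                      cipe_coupling = null_coupling,
                                      ielt_coupling = null_coupling))
    max(abs(cor(co$manifest$cipe_total, co$ground_truth$occupancy)))
  }, 0)
  expect_gte(mean(hits <= 0.5), 19 / 20)
})

test_that("equal group chains give non-significant occupancy differences", {
  pi0 <- c(0.4, 0.2, 0.25, 0.15)
  ps <- unlist(lapply(1:20, function(s) {
    co <- simulate_cohort(cohort_spec(n_regions = 12, seed = 700 + s,
                                      occupancy_patient = pi0,
                                      occupancy_control = pi0))
    occ <- co$ground_truth$occupancy
    grp <- co$manifest$group
    vapply(1:4, function(k)
      two_sample_t(occ[grp == "patient", k], occ[grp == "control", k])$p_value, 0)
  }))
  expect_gte(mean(ps >= 0.05), 0.9)
})

test_that("matched planted states are identified from fitted centroids", {
  co <- simulate_cohort(small_spec(seed = 10))
  dfc <- lapply(co$timeseries, subject_dfc,
                params = window_params(l1_lambda = 0))
  model <- fit_dfc_states(dfc, cluster_params(k = 4, n_init = 5, seed = 2))
  mapping <- match_states(model, co$ground_truth$covariances)
  expect_setequal(mapping, 1:4)
  # mapped assignments agree with latent majority states
  ref <- unlist(lapply(co$ground_truth$latent, window_majority_state,
                       n_windows = 99, length_tr = 22))
  mapped <- mapping[unlist(model$assignments)]
  # short series and few regions blur window labels; full-scale recovery is
  # asserted separately at the default cohort geometry
  expect_gt(mean(mapped == ref), 0.6)
})
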