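test_that("feature matrix has the documented columns and label coding", {
  set.seed(1)
  assigns <- lapply(1:12, function(i) sample(1:4, 60, replace = TRUE))
  assigns[[1]] <- rep(1L, 60)          # subject locked in state 1
  names(assigns) <- sprintf("s%02d", 12:1)  # deliberately unsorted
  metrics <- state_metrics(fake_model(assigns, 4))
  man <- fake_manifest(names(assigns), rep_len(c("patient", "control"), 12))
  fm <- build_feature_matrix(metrics, man)
  expect_identical(ncol(fm$x), 11L)  # 1 + 4 + 6
  expect_identical(fm$feature_names[1:2], c("n_states", "reocc_s1"))
  expect_identical(fm$subject_id, sort(names(assigns)))
  expect_true(all(fm$y %in% c(-1, 1)))
  locked <- fm$x[fm$subject_id == "s12", ]
  expect_equal(unname(locked), c(1, 60, 0, 0, 0, rep(0, 6)))
  # row order invariance up to the documented sort
  fm2 <- build_feature_matrix(metrics[sample(12), ], man)
  expect_identical(fm$x, fm2$x)
})

test_that("LSVM separates a symmetric two-point problem at zero", {
  x <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  fit <- lsvm(x, y, standardize = FALSE)
  expect_identical(predict(fit, x, type = "class"), y)
  expect_equal(fit$bias, 0, tolerance = 1e-8)
})

test_that("LSVM agrees with an independent squared-hinge QP oracle", {
  set.seed(2)
  x <- rbind(matrix(rnorm(20, 1.5), 10, 2), matrix(rnorm(20, -1.5), 10, 2))
  y <- rep(c(1, -1), each = 10)
  fit <- lsvm(x, y, nu = 1, tol = 1e-10)
  expect_equal(mean(predict(fit, x, type = "class") == y), 1)
  oracle <- qp_svm_oracle(x, y, nu = 1)
  expect_lt(max(abs(predict(fit, x) - oracle$scores)), 1e-3)
})

test_that("LSVM is invariant to dataset duplication with rebalanced nu", {
  # each row twice doubles the loss weight, so nu/2 restores the objective:
  # the solutions must coincide exactly
  set.seed(3)
  x <- rbind(matrix(rnorm(24, 2), 12, 2), matrix(rnorm(24, -2), 12, 2))
  y <- rep(c(1, -1), each = 12)
  f1 <- lsvm(x, y, nu = 1, tol = 1e-10, standardize = FALSE)
  f2 <- lsvm(rbind(x, x), c(y, y), nu = 0.5, tol = 1e-10, standardize = FALSE)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$bias, f2$bias, tolerance = 1e-6)
})

test_that("LSVM iterate residuals are nonincreasing after the first step", {
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rnorm(60), 20, 3)
    y <- sign(x[, 1] + 0.5 * rnorm(20)); y[y == 0] <- 1
    fit <- lsvm(x, y, tol = 1e-12, max_iter = 5000)
    r <- fit$residuals
    if (length(r) > 2) expect_true(all(diff(r[-1]) <= 1e-10))
  }
})

test_that("feature ranking is driven by training rows only", {
  set.seed(5)
  y <- rep(c(1, -1), each = 15)
  x <- matrix(rnorm(30 * 6), 30, 6)
  x[, 4] <- y                         # label copy
  expect_identical(rank_features(x, y)[1], 4L)
  # planted 2-sd effect ranked first in >= 95% of replicates
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    xx <- matrix(rnorm(30 * 8), 30, 8)
    xx[, 3] <- xx[, 3] + y * 1        # group separation of 2 sd
    rank_features(xx, y)[1] == 3L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # leakage guard: held-out rows never change the ranking
  tr <- 1:20
  r1 <- rank_features(x[tr, ], y[tr])
  x[21:30, ] <- 1e6
  expect_identical(rank_features(x[tr, ], y[tr]), r1)
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(roc_auc(rep(2, 10), rep_len(c(1, -1), 10)), 0.5)
  set.seed(6)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    s <- sample(1:5, n, replace = TRUE)  # many ties
    expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # independent reference implementation
  set.seed(7)
  y <- rep(c(1, -1), c(12, 9)); s <- rnorm(21) + (y > 0)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<", levels = c(-1, 1)))),
               tolerance = 1e-12)
})

test_that("nested CV reaches high accuracy on a strongly separated cohort", {
  set.seed(7)
  n1 <- 20; n0 <- 16
  y <- rep(c(1, -1), c(n1, n0))
  x <- matrix(rnorm((n1 + n0) * 11), n1 + n0, 11)
  x[, 2] <- x[, 2] + y * 1.8          # >= 3 pooled-sd occupancy-style effect
  x[, 5] <- x[, 5] - y * 1.6
  fm <- list(x = x, y = y, subject_id = sprintf("s%02d", 1:(n1 + n0)),
             feature_names = paste0("f", 1:11))
  rep_ <- nested_cv(fm, classify_params(outer_folds = 6, inner_folds = 5,
                                        seed = 2))
  expect_gte(rep_$accuracy, 90)
  expect_gte(rep_$auc, 0.9)
  # self-consistency: pooled accuracy recomputed from stored predictions
  expect_equal(rep_$accuracy, 100 * mean(rep_$predictions == fm$y))
  expect_equal(rep_$sensitivity,
               100 * mean(rep_$predictions[fm$y > 0] == 1))
  expect_equal(rep_$specificity,
               100 * mean(rep_$predictions[fm$y < 0] == -1))
  expect_length(rep_$decision_scores, n1 + n0)
})

test_that("nested CV is at chance on permuted labels", {
  accs <- vapply(1:6, function(s) {
    set.seed(20 + s)
    n <- 40
    y <- sample(rep(c(1, -1), each = 20))
    x <- matrix(rnorm(n * 8), n, 8)   # features independent of labels
    fm <- list(x = x, y = y, subject_id = sprintf("s%02d", 1:n),
               feature_names = paste0("f", 1:8))
    nested_cv(fm, classify_params(outer_folds = 5, inner_folds = 4,
                                  seed = s))$accuracy
  }, 0)
  # pooled over 240 chance-level predictions: binomial 95% band around 50%
  expect_lt(abs(mean(accs) - 50), 100 * 1.96 * sqrt(0.25 / 240))
})

test_that("permutation p values respect their formula bounds", {
  set.seed(9)
  n <- 24
  y <- rep(c(1, -1), each = 12)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + y * 3            # near-perfect separation
  fm <- list(x = x, y = y, subject_id = sprintf("s%02d", 1:n),
             feature_names = paste0("f", 1:4))
  params <- classify_params(outer_folds = 4, inner_folds = 3,
                            n_permutations = 9, seed = 3)
  pt <- permutation_test(fm, params)
  expect_gte(pt$p_accuracy, 1 / 10)
  expect_lte(pt$p_accuracy, 1)
  expect_identical(length(pt$null_accuracy), 9L)
  # observed beats every null here, so p hits the formula floor
  expect_equal(pt$p_accuracy, 1 / 10)
})

test_that("stratified folds keep both classes in every fold", {
  y <- rep(c(1, -1), c(30, 12))
  set.seed(10)
  fm <- list(x = matrix(rnorm(42 * 3), 42, 3), y = y,
             subject_id = sprintf("s%02d", 1:42), feature_names = paste0("f", 1:3))
  rep_ <- nested_cv(fm, classify_params(outer_folds = 6, inner_folds = 3, seed = 4))
  for (f in 1:6) expect_setequal(unique(y[rep_$fold_assignments == f]), c(-1, 1))
  expect_error(nested_cv(fm, classify_params(outer_folds = 13, inner_folds = 3)),
               "fewer members")
})
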