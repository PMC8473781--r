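test_that("taper equals the explicit rectangle-Gaussian convolution", {
  L <- 22; sigma <- 3
  w <- build_taper(L, sigma)
  # direct double-loop convolution oracle, central L samples of rect * gauss
  J <- 50
  g <- exp(-((-J:J)^2) / (2 * sigma^2))
  oracle <- numeric(L)
  for (i in seq_len(L)) {
    for (m in seq_len(L)) oracle[i] <- oracle[i] + g[(i - m) + J + 1]
  }
  oracle <- oracle / sum(oracle)
  expect_equal(w, oracle, tolerance = 1e-12)
  expect_length(w, L)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_lt(w[1], w[11])
  expect_equal(which.max(w), 11)
})

test_that("taper approaches the flat rectangle as sigma vanishes", {
  w <- build_taper(22, 1e-6)
  expect_equal(w, rep(1 / 22, 22), tolerance = 1e-6)
})

test_that("taper rejects non-positive arguments", {
  expect_error(build_taper(0, 3))
  expect_error(build_taper(22, 0))
})

test_that("window and pair counts match closed forms and brute enumeration", {
  expect_identical(count_windows(230, 22, 1), 209L)
  expect_identical(count_windows(22, 22, 1), 1L)
  # brute-force start-offset enumeration for step 5
  expect_identical(count_windows(230, 22, 5),
                   length(seq(0, 230 - 22, by = 5)))
  expect_identical(count_windows(230, 22, 5), 42L)
  expect_error(count_windows(21, 22, 1), "shorter")
  expect_identical(pair_count(264), 34716L)
  expect_identical(pair_count(2), 1L)
  expect_identical(pair_count(5), nrow(t(combn(5, 2))))
  expect_error(pair_count(1))
})

test_that("windowed correlation with a flat taper equals direct Pearson summation", {
  set.seed(7)
  seg <- matrix(rnorm(22 * 6), 22, 6)
  got <- window_connectivity(seg, rep(1, 22), l1_lambda = 0,
                             use_fisher_z = FALSE)
  # direct summation oracle in documented row-major pair order
  oracle <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    xi <- seg[, i] - mean(seg[, i]); xj <- seg[, j] - mean(seg[, j])
    oracle <- c(oracle, sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)))
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("perfectly correlated columns give pair value 1, clipped before Fisher z", {
  seg <- cbind(a = sin(1:22), b = 2 * sin(1:22) + 3, c = cos(1:22))
  raw <- window_connectivity(seg, build_taper(22, 3), 0, use_fisher_z = FALSE)
  expect_equal(raw[1], 1, tolerance = 1e-12)
  z <- window_connectivity(seg, build_taper(22, 3), 0, use_fisher_z = TRUE)
  expect_true(all(is.finite(z)))
  expect_equal(z[1], atanh(1 - 1e-7))
})

test_that("Fisher z preserves the ordering of pair values", {
  set.seed(3)
  seg <- matrix(rnorm(22 * 8), 22, 8)
  taper <- build_taper(22, 3)
  raw <- window_connectivity(seg, taper, 0, use_fisher_z = FALSE)
  z <- window_connectivity(seg, taper, 0, use_fisher_z = TRUE)
  expect_identical(order(raw), order(z))
})

test_that("connectivity is invariant to columnwise affine rescaling", {
  set.seed(11)
  seg <- matrix(rnorm(22 * 5), 22, 5)
  taper <- build_taper(22, 3)
  seg2 <- sweep(sweep(seg, 2, c(2, 0.1, 5, 1, 30), "*"), 2, c(-3, 0, 7, 2, 100))
  for (lam in c(0, 0.05)) {
    expect_equal(window_connectivity(seg, taper, lam),
                 window_connectivity(seg2, taper, lam), tolerance = 1e-8)
  }
})

test_that("penalised precision separates planted blocks into weak partial correlations", {
  # 6 ROIs, two 3-blocks with within-block r = 0.8
  sigma <- diag(6)
  for (b in list(1:3, 4:6)) sigma[b, b] <- 0.8
  diag(sigma) <- 1
  set.seed(5)
  x <- matrix(rnorm(4000 * 6), 4000, 6) %*% chol(sigma)
  v <- window_connectivity(x, rep(1, 4000), l1_lambda = 0.05,
                           use_fisher_z = FALSE)
  within <- c(1, 2, 6, 13, 14, 15)   # pairs (1,2),(1,3),(2,3),(4,5),(4,6),(5,6)
  expect_true(max(abs(v[-within])) < min(abs(v[within])))
  # dense precision of the true covariance shows the same split
  prec <- solve(sigma)
  pc <- -prec / sqrt(outer(diag(prec), diag(prec)))
  truth <- pc[lower.tri(pc)]
  expect_true(max(abs(truth[-within])) < min(abs(truth[within])))
  expect_gt(cor(v, truth), 0.95)
})

test_that("graphical lasso matches the unpenalised inverse as lambda -> 0", {
  sigma <- diag(4); sigma[1, 2] <- sigma[2, 1] <- 0.5
  prec <- glasso_precision(sigma, 1e-8)
  expect_equal(prec, solve(sigma), tolerance = 1e-4)
})

test_that("subject_dfc geometry follows the window count for random valid triples", {
  set.seed(21)
  for (rep in 1:8) {
    T_ <- sample(40:90, 1)
    L <- sample(10:min(30, T_), 1)
    step <- sample(1:5, 1)
    ts <- roi_timeseries(matrix(rnorm(T_ * 6), T_, 6), "p")
    d <- subject_dfc(ts, window_params(length_tr = L, step_tr = step,
                                       l1_lambda = 0))
    expect_identical(nrow(d$dfc), as.integer(count_windows(T_, L, step)))
    expect_identical(ncol(d$dfc), pair_count(6L))
    expect_equal(d$window_starts, seq(0, by = step, length.out = nrow(d$dfc)))
    expect_true(all(is.finite(d$dfc)))
  }
})

test_that("white-noise series yields near-zero mean connectivity", {
  set.seed(31)
  ts <- roi_timeseries(matrix(rnorm(230 * 10), 230, 10), "null")
  d <- subject_dfc(ts, window_params(l1_lambda = 0))
  cm <- colMeans(d$dfc)
  # windows overlap, so only ~W/L of them are independent, and the taper
  # reduces each window to ~1/sum(w^2) effective samples
  n_eff <- (nrow(d$dfc) / 22) * (1 / sum(build_taper(22, 3)^2))
  expect_true(all(abs(cm) < 3 / sqrt(n_eff)))
  expect_lt(abs(mean(cm)), 0.05)
})

test_that("a covariance change between halves separates early and late windows", {
  set.seed(41)
  sig <- diag(6); sig[1:3, 1:3] <- 0.7; diag(sig) <- 1
  a <- matrix(rnorm(100 * 6), 100, 6) %*% chol(sig)
  sig2 <- diag(6); sig2[4:6, 4:6] <- 0.7; diag(sig2) <- 1
  b <- matrix(rnorm(100 * 6), 100, 6) %*% chol(sig2)
  ts <- roi_timeseries(rbind(a, b), "switch")
  d <- subject_dfc(ts, window_params(l1_lambda = 0))
  early <- colMeans(d$dfc[1:60, ])
  late <- colMeans(d$dfc[119:179, ])
  within_half <- mean(abs(colMeans(d$dfc[1:30, ]) - colMeans(d$dfc[31:60, ])))
  expect_gt(mean(abs(early - late)), within_half)
})
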