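options(dfcstates.verbose = FALSE)

# small cohort used by several suites: quick to simulate and to cluster
small_spec <- function(seed = 1, ...) {
  cohort_spec(n_patients = 8L, n_controls = 6L, n_timepoints = 120L,
              n_regions = 24L, seed = seed, ...)
}

# rows drawn around k planted unit-norm patterns with within-cluster
# correlation ~ high and between ~ low; returns rows + labels
planted_rows <- function(n_per, k, f = 50, noise = 0.2, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * f), k, f)
  labels <- rep(seq_len(k), each = n_per)
  x <- centers[labels, ] + noise * matrix(rnorm(n_per * k * f), n_per * k, f)
  list(x = x, labels = labels, centers = centers)
}

# fabricate a minimal state-model object from per-subject label vectors
fake_model <- function(assignments, k) {
  structure(list(assignments = assignments, k = k,
                 centroids = matrix(rnorm(k * 10), k, 10)),
            class = "dfc_state_model")
}

# manifest for n subjects without reading any files
fake_manifest <- function(ids, groups, cipe = NA, ielt = NA, fd = NA) {
  as_cohort_manifest(data.frame(
    subject_id = ids, group = groups, series_path = paste0(ids, ".tsv"),
    cipe_total = cipe, ielt_minutes = ielt, mean_fd = fd,
    stringsAsFactors = FALSE))
}

# exhaustive pair-counting Mann-Whitney U (ties count one half)
brute_u <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s
}

# all-pairs AUC with ties at one half
brute_auc <- function(scores, y) {
  pos <- scores[y > 0]; neg <- scores[y < 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# squared-hinge primal SVM matching the Lagrangian formulation
# (penalised bias), solved by BFGS: the independent QP-equivalent oracle
qp_svm_oracle <- function(x, y, nu) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  obj <- function(par) {
    w <- par[-length(par)]; g <- par[length(par)]
    m <- pmax(0, 1 - y * (drop(xs %*% w) - g))
    0.5 * (sum(w^2) + g^2) + nu / 2 * sum(m^2)
  }
  grad <- function(par) {
    w <- par[-length(par)]; g <- par[length(par)]
    m <- pmax(0, 1 - y * (drop(xs %*% w) - g))
    gw <- w - nu * drop(crossprod(xs, y * m))
    gg <- g + nu * sum(y * m)
    c(gw, gg)
  }
  fit <- optim(rep(0, ncol(xs) + 1), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  w <- fit$par[-length(fit$par)]; g <- fit$par[length(fit$par)]
  list(weights = w, bias = g,
       scores = drop(scale(x, center = attr(xs, "scaled:center"),
                           scale = attr(xs, "scaled:scale")) %*% w) - g)
}
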