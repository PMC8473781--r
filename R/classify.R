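#' Classification parameters
#'
#' @param outer_folds outer CV folds (default 10).
#' @param inner_folds inner CV folds for feature-count selection (default 10).
#' @param nu LSVM regularisation (default 1).
#' @param tol LSVM convergence tolerance (default 1e-6).
#' @param max_iter LSVM iteration cap (default 10000).
#' @param n_permutations label permutations for the null distribution
#'   (default 1000).
#' @param seed integer seed for fold assignment and permutations.
#' @return a `classify_params` list.
#' @export
classify_params <- function(outer_folds = 10L, inner_folds = 10L, nu = 1,
                            tol = 1e-6, max_iter = 10000L,
                            n_permutations = 1000L, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, nu > 0, tol > 0,
            n_permutations >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds), nu = nu, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "classify_params")
}

#' Build the subject-level feature matrix
#'
#' One row per subject (sorted by `subject_id`), with columns: number of
#' distinct states visited, the k reoccurrence times, and the k(k-1)/2
#' undirected transition counts. Labels are +1 for patients, -1 for controls.
#'
#' @param metrics a [state_metrics()] data frame.
#' @param manifest cohort manifest.
#' @return list with `x` (n x d matrix), `y` (+1/-1), `subject_id`,
#'   `feature_names`.
#' @export
build_feature_matrix <- function(metrics, manifest) {
  k <- attr(metrics, "k")
  ord <- order(metrics$subject_id)
  metrics <- metrics[ord, , drop = FALSE]
  grp <- manifest$group[match(metrics$subject_id, manifest$subject_id)]
  if (anyNA(grp)) stop("subject(s) without a group label: ",
                       paste(metrics$subject_id[is.na(grp)], collapse = ", "))
  cols <- c("n_states", paste0("reocc_s", seq_len(k)),
            paste0("trans_", transition_pair_names(k)))
  x <- as.matrix(metrics[cols])
  rownames(x) <- metrics$subject_id
  list(x = x, y = ifelse(grp == "patient", 1, -1),
       subject_id = metrics$subject_id, feature_names = cols)
}

#' Rank features by discriminability on training rows
#'
#' Features ordered by descending absolute pooled two-sample t statistic
#' between the classes, computed on the supplied (training) rows only.
#' Zero-variance features get |t| = 0 and sort last.
#'
#' @param x training feature matrix.
#' @param y training labels in \{+1, -1\}.
#' @return integer ordering of the feature columns.
#' @export
rank_features <- function(x, y) {
  x <- as.matrix(x)
  a <- x[y > 0, , drop = FALSE]
  b <- x[y < 0, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  stopifnot(n1 >= 1, n2 >= 1)
  # single-member classes contribute no variance dof; with no dof at all the
  # ranking degenerates to the original column order
  va <- if (n1 >= 2) apply(a, 2, stats::var) else 0
  vb <- if (n2 >= 2) apply(b, 2, stats::var) else 0
  dof <- (n1 - 1) + (n2 - 1)
  if (dof == 0) return(seq_len(ncol(x)))
  sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / dof
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- abs(colMeans(a) - colMeans(b)) / se
  # a zero-variance feature with separated means is infinitely discriminative
  # (sorts first); one with equal means is uninformative (sorts last)
  tstat[is.nan(tstat)] <- 0
  order(tstat, decreasing = TRUE)
}

# Stratified fold assignment: classes are split separately so each fold keeps
# the class ratio; errors if a class has fewer members than folds.
#' @noRd
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < n_folds)
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", n_folds, ")")
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Rank-based area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half (midrank formulation).
#'
#' @param scores numeric decision scores.
#' @param y labels in \{+1, -1\}.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  pos <- y > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nested cross-validated LSVM classification
#'
#' Outer stratified folds estimate generalisation; inside each outer training
#' set, inner stratified folds select the number of top-ranked features
#' (candidates m = 1..d, ranked by [rank_features()] on inner-training rows
#' only; ties broken toward smaller m). The model is refit on the full outer
#' training set with its own top-m features and scored on the outer test fold.
#' Pooled outer-fold predictions give accuracy, sensitivity (patients = +1 as
#' positives), specificity, and rank-based AUC. Standardisation, ranking and
#' model fitting never see held-out rows.
#'
#' @param features a [build_feature_matrix()] list.
#' @param params a [classify_params()].
#' @return an object of class `dfc_classification`: `accuracy`, `sensitivity`,
#'   `specificity` (percentages), `auc`, `decision_scores`, `predictions`,
#'   `fold_assignments`, `selected_m` (per outer fold), `subject_id`, `y`.
#' @export
nested_cv <- function(features, params = classify_params()) {
  x <- features$x; y <- features$y
  n <- nrow(x); d <- ncol(x)
  if (n < params$outer_folds) stop("fewer subjects than outer folds")
  folds <- stratified_folds(y, params$outer_folds, params$seed)

  scores <- numeric(n)
  selected_m <- integer(params$outer_folds)
  for (fo in seq_len(params$outer_folds)) {
    tr <- folds != fo; te <- !tr
    x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
    inner <- stratified_folds(y_tr, params$inner_folds,
                              params$seed + 1000L + fo)
    correct <- matrix(0, params$inner_folds, d)   # inner accuracy per m
    total <- integer(params$inner_folds)
    for (fi in seq_len(params$inner_folds)) {
      itr <- inner != fi
      ord <- rank_features(x_tr[itr, , drop = FALSE], y_tr[itr])
      total[fi] <- sum(!itr)
      for (m in seq_len(d)) {
        sel <- ord[seq_len(m)]
        fit <- lsvm(x_tr[itr, sel, drop = FALSE], y_tr[itr], nu = params$nu,
                    tol = params$tol, max_iter = params$max_iter)
        pred <- predict(fit, x_tr[!itr, sel, drop = FALSE], type = "class")
        correct[fi, m] <- sum(pred == y_tr[!itr])
      }
    }
    inner_acc <- colSums(correct) / sum(total)
    m_star <- which.max(inner_acc)               # ties -> smaller m
    selected_m[fo] <- m_star
    ord <- rank_features(x_tr, y_tr)
    sel <- ord[seq_len(m_star)]
    fit <- lsvm(x_tr[, sel, drop = FALSE], y_tr, nu = params$nu,
                tol = params$tol, max_iter = params$max_iter)
    scores[te] <- predict(fit, x[te, sel, drop = FALSE], type = "score")
  }

  pred <- ifelse(scores >= 0, 1, -1)
  acc <- mean(pred == y)
  sens <- mean(pred[y > 0] == 1)
  spec <- mean(pred[y < 0] == -1)
  structure(list(accuracy = 100 * acc, sensitivity = 100 * sens,
                 specificity = 100 * spec, auc = roc_auc(scores, y),
                 decision_scores = scores, predictions = pred,
                 fold_assignments = folds, selected_m = selected_m,
                 subject_id = features$subject_id, y = y, params = params),
            class = "dfc_classification")
}

#' @export
print.dfc_classification <- function(x, ...) {
  cat(sprintf(paste0("Nested-CV LSVM classification (%d subjects, %d outer folds):\n",
                     "  accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n"),
              length(x$y), x$params$outer_folds, x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p (accuracy) = %.4g, (AUC) = %.4g [%d permutations]\n",
                x$permutation_p["accuracy"], x$permutation_p["auc"],
                x$params$n_permutations))
  invisible(x)
}

#' Permutation test of the nested-CV classification
#'
#' Permutes the subject labels `n_permutations` times, reruns the full nested
#' cross-validation on each permuted cohort, and reports
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)` for both accuracy
#' and AUC.
#'
#' @param features a [build_feature_matrix()] list.
#' @param params a [classify_params()]; `n_permutations` and `seed` control
#'   the null.
#' @param observed optionally, a precomputed [nested_cv()] result for the
#'   unpermuted labels (recomputed when omitted).
#' @return list with `p_accuracy`, `p_auc`, `null_accuracy`, `null_auc`,
#'   `observed`.
#' @export
permutation_test <- function(features, params = classify_params(),
                             observed = NULL) {
  if (is.null(observed)) observed <- nested_cv(features, params)
  P <- params$n_permutations
  null_acc <- numeric(P); null_auc <- numeric(P)
  for (p_i in seq_len(P)) {
    set.seed(stage_seed(params$seed + p_i, "permute"))
    perm <- features
    perm$y <- sample(features$y)
    pp <- params
    pp$seed <- params$seed + p_i
    res <- nested_cv(perm, pp)
    null_acc[p_i] <- res$accuracy
    null_auc[p_i] <- res$auc
  }
  list(p_accuracy = (1 + sum(null_acc >= observed$accuracy)) / (P + 1),
       p_auc = (1 + sum(null_auc >= observed$auc)) / (P + 1),
       null_accuracy = null_acc, null_auc = null_auc, observed = observed)
}
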