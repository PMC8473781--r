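#' Lagrangian support vector machine (linear)
#'
#' Fits the L2-regularised linear SVM with penalised bias by the Lagrangian
#' fixed-point iteration on the dual:
#' \deqn{u_{i+1} = Q^{-1}\,(e + ((Q u_i - e) - \alpha u_i)_+),\qquad
#'       Q = I/\nu + H H^\top,\; H = D\,[A, -e],}
#' where `A` holds the (internally standardised) feature rows, `D` the labels
#' on the diagonal, and `alpha = 1.9 / nu` (convergence requires
#' `alpha < 2/nu`). `Q^{-1}` is applied through the Sherman-Morrison-Woodbury
#' identity, so the per-iteration cost is linear in n for few features. The
#' iteration is linearly convergent; it stops when the iterate change drops
#' below `tol`. Primal weights and bias are recovered as `w = A' D u`,
#' `b = -e' D u`, and the decision value of a row x is `w . x - b`.
#'
#' @param x numeric matrix, n observations x d features.
#' @param y labels in \{+1, -1\} (or a 2-level factor; first level = +1).
#' @param nu regularisation parameter (default 1).
#' @param tol convergence tolerance on `||u_{i+1} - u_i||` (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @param standardize centre/scale columns internally (default TRUE);
#'   constant columns are left centred with unit scale.
#' @return an object of class `lsvm`: `weights`, `bias`, `iterations`,
#'   `residuals` (per-iteration iterate change), `center`, `scale`, `nu`.
#' @export
lsvm <- function(x, y, nu = 1, tol = 1e-6, max_iter = 10000L,
                 standardize = TRUE) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], 1, -1)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)), nu > 0)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(x)

  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  H <- y * cbind(xs, -1)                       # D [A, -e]
  alpha <- 1.9 / nu
  # Q^{-1} v = nu (v - H (I/nu + H'H)^{-1} H' v)  (Woodbury)
  M <- diag(ncol(H)) / nu + crossprod(H)
  Minv <- solve(M)
  Qinv <- function(v) nu * (v - H %*% (Minv %*% crossprod(H, v)))
  Qmul <- function(u) u / nu + H %*% crossprod(H, u)

  e <- rep(1, n)
  u <- Qinv(e)
  residuals <- numeric(0)
  for (it in seq_len(max_iter)) {
    z <- pmax((Qmul(u) - e) - alpha * u, 0)
    u_new <- Qinv(e + z)
    res <- sqrt(sum((u_new - u)^2))
    residuals <- c(residuals, res)
    u <- u_new
    if (res <= tol) break
  }
  if (res > tol)
    warning("LSVM did not converge in ", max_iter,
            " iterations (residual ", signif(res, 3), ")")

  du <- as.numeric(y * u)
  w <- drop(crossprod(xs, du))
  b <- -sum(du)
  structure(list(weights = w, bias = b, iterations = it, residuals = residuals,
                 center = center, scale = scl, nu = nu,
                 converged = res <= tol, call = match.call()),
            class = "lsvm")
}

#' @export
print.lsvm <- function(x, ...) {
  cat(sprintf("Lagrangian SVM: %d features, nu = %g, %d iterations%s\n",
              length(x$weights), x$nu, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.lsvm <- function(object, ...) c(bias = object$bias, object$weights)

#' Decision values or class predictions from an LSVM fit
#'
#' @param object an [lsvm()] fit.
#' @param newdata matrix of rows to score (original feature scale).
#' @param type `"score"` for decision values `w.x - b`, `"class"` for signs.
#' @param ... unused.
#' @return numeric scores or labels in \{+1, -1\}.
#' @export
predict.lsvm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  s <- drop(xs %*% object$weights) - object$bias
  if (type == "class") ifelse(s >= 0, 1, -1) else s
}
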