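#' Multi-response partial least squares regression (NIPALS)
#'
#' PLS2 by the NIPALS algorithm: successive orthogonal X-score vectors
#' maximizing covariance with the response block.  Predictors and responses
#' are centered, not scaled, by default (per-column scaling is exposed
#' because the five mixture parameters differ by orders of magnitude).  The
#' algorithm is deterministic for a fixed input order.
#'
#' @param X predictors, n x m numeric matrix.
#' @param Y responses, n x q numeric matrix (a vector is treated as one
#'   column).
#' @param ncomp number of latent components; silently reduced (with a
#'   warning) if it exceeds the effective rank of X.
#' @param scale if `TRUE`, scale columns of X and Y to unit variance.
#' @return object of class `pls_fit` with score/weight/loading matrices
#'   (`scores`, `weights`, `x_loadings`, `y_loadings`), the centering (and
#'   scaling) vectors, and `ncomp` actually fitted.  Use [coef.pls_fit()]
#'   and [predict.pls_fit()] with any `ncomp` up to the fitted one.
#' @export
pls_fit <- function(X, Y, ncomp, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n, ncomp >= 1)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, m)
  y_scale <- if (scale) apply(Y, 2, stats::sd) else rep(1, q)
  x_scale[x_scale == 0] <- 1; y_scale[y_scale == 0] <- 1
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Yc <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")

  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  actual <- 0L
  for (k in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (iter in 1:500) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_vec <- drop(Xc %*% w)
      cc <- crossprod(Yc, t_vec) / sum(t_vec^2)
      if (q == 1L) break                      # PLS1: one pass, no iteration
      u_new <- drop(Yc %*% cc) / sum(cc^2)
      if (sqrt(sum((t_vec - t_old)^2)) < 1e-12 * sqrt(sum(t_vec^2))) {
        u <- u_new; break
      }
      t_old <- t_vec; u <- u_new
    }
    if (nw < 1e-14 || sum(t_vec^2) < 1e-14) {
      warning("rank of X exhausted after ", k - 1L,
              " components; ncomp reduced")
      break
    }
    p_load <- crossprod(Xc, t_vec) / sum(t_vec^2)
    Xc <- Xc - tcrossprod(t_vec, p_load)
    Yc <- Yc - tcrossprod(t_vec, cc)
    W[, k] <- w; P[, k] <- p_load; C[, k] <- cc; Tm[, k] <- t_vec
    actual <- k
  }
  if (actual == 0L) stop("X has no usable variance")
  structure(list(ncomp = actual,
                 weights = W[, seq_len(actual), drop = FALSE],
                 x_loadings = P[, seq_len(actual), drop = FALSE],
                 y_loadings = C[, seq_len(actual), drop = FALSE],
                 scores = Tm[, seq_len(actual), drop = FALSE],
                 x_center = x_center, y_center = y_center,
                 x_scale = x_scale, y_scale = y_scale,
                 response_names = colnames(Y)),
            class = "pls_fit")
}

#' Regression coefficients of a PLS fit
#'
#' @param object a [pls_fit()] result.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return m x q coefficient matrix on the original (unscaled) variable
#'   scales.
#' @export
coef.pls_fit <- function(object, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  idx <- seq_len(ncomp)
  W <- object$weights[, idx, drop = FALSE]
  P <- object$x_loadings[, idx, drop = FALSE]
  C <- object$y_loadings[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  # undo the (optional) unit-variance scaling
  B <- B * outer(1 / object$x_scale, object$y_scale)
  dimnames(B) <- list(names(object$x_center), object$response_names)
  B
}

#' Predict responses from a PLS fit
#'
#' @param object a [pls_fit()] result.
#' @param newdata matrix of predictors (columns as in training).
#' @param ncomp number of components (default: all fitted).
#' @param ... unused.
#' @return matrix of predicted responses.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$x_center))
  B <- coef(object, ncomp = ncomp)
  sweep(sweep(newdata, 2, object$x_center) %*% B, 2, object$y_center, "+")
}

# LOO predictions for every component count 1..max_ncomp in one pass:
# each fold is fit once at max_ncomp and predicts the held-out row at all
# truncations.  Returns an n x q x max_ncomp array.
loo_pls_all <- function(X, Y, max_ncomp, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); q <- ncol(Y)
  max_ncomp <- min(max_ncomp, n - 2L, ncol(X))
  out <- array(NA_real_, c(n, q, max_ncomp))
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                   ncomp = max_ncomp, scale = scale)
    for (k in seq_len(min(max_ncomp, fit$ncomp)))
      out[i, , k] <- predict(fit, X[i, , drop = FALSE], ncomp = k)
  }
  dimnames(out) <- list(rownames(X), colnames(Y), NULL)
  out
}
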