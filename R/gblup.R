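#' GBLUP fit with REML variance components
#'
#' Fits the mixed model `y = 1 mu + g + e`, `g ~ N(0, sigma2_g K)`,
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood.  The likelihood
#' is profiled on the variance ratio `lambda = sigma2_g / sigma2_e` using
#' the spectral decomposition of K (one eigendecomposition, then each ratio
#' costs O(n)); the ratio is located by a grid over `log(lambda)` in
#' \[-20, 20\] followed by golden-section refinement.
#'
#' The reported `sigma2_g` is the genetic variance per cultivar,
#' `lambda * sigma2_e * mean(diag(K))`: scaling by the mean diagonal makes
#' `sigma2_g` (and hence `h2`) invariant to any positive rescaling of K,
#' which matters because the VanRaden matrix of a fully inbred panel has a
#' mean diagonal near 2 rather than 1.
#'
#' @param y numeric phenotype vector (one value per cultivar), no missing
#'   values.
#' @param K relationship matrix aligned with `y` (e.g. from
#'   [genomic_relationship()]).
#' @param lambda optional fixed variance ratio; when given, REML estimation
#'   of the ratio is skipped and the BLUPs are the closed-form kernel-ridge
#'   solution at that ratio.
#' @return object of class `gblup_fit`: list with `mu`, `sigma2_g`,
#'   `sigma2_e`, `h2`, `lambda`, `blup` (genetic values), `fitted`
#'   (`mu + blup`), and `alpha` (weights such that a genotype with
#'   relationship row k to the training set is predicted as
#'   `mu + k %*% alpha`).
#' @export
gblup_fit <- function(y, K, lambda = NULL) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  stopifnot(nrow(K) == n, ncol(K) == n)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, n)))

  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    xtx <- sum(xs^2 / w)
    beta <- sum(xs * ys / w) / xtx
    r <- ys - xs * beta
    s2e <- sum(r^2 / w) / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(w)) + log(xtx))
  }

  if (is.null(lambda)) {
    grid <- seq(-20, 20, length.out = 201)
    ll <- vapply(grid, reml_ll, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(reml_ll, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    log_lambda <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    lam <- exp(log_lambda)
  } else {
    stopifnot(lambda >= 0)
    lam <- lambda
  }

  w <- lam * d + 1
  beta <- sum(xs * ys / w) / sum(xs^2 / w)
  resid <- y - beta
  alpha <- lam * drop(U %*% (crossprod(U, resid) / w))
  blup <- drop(K %*% alpha)
  s2e <- sum((ys - xs * beta)^2 / w) / (n - 1)
  s2g <- lam * s2e * mean(diag(K))
  structure(list(mu = beta, sigma2_g = s2g, sigma2_e = s2e,
                 h2 = s2g / (s2g + s2e), lambda = lam,
                 blup = blup, fitted = beta + blup, alpha = alpha),
            class = "gblup_fit")
}

#' Predict genetic values of new genotypes from a GBLUP fit
#'
#' @param object a [gblup_fit()] result.
#' @param K_new_train matrix of relationships between new genotypes (rows)
#'   and the training genotypes (columns, in training order).
#' @param ... unused.
#' @return predicted phenotypes `mu + K_new_train %*% alpha`.
#' @export
predict.gblup_fit <- function(object, K_new_train, ...) {
  K_new_train <- matrix(K_new_train, ncol = length(object$alpha))
  drop(object$mu + K_new_train %*% object$alpha)
}

#' Narrow-sense heritability from GBLUP variance components
#'
#' @param vc a [gblup_fit()] result, or any list with `sigma2_g` and
#'   `sigma2_e`.
#' @return `sigma2_g / (sigma2_g + sigma2_e)`.
#' @export
heritability <- function(vc) {
  tot <- vc$sigma2_g + vc$sigma2_e
  if (tot <= 0) stop("degenerate variance components: both zero")
  vc$sigma2_g / tot
}

#' Leave-one-out cross-validated GBLUP predictions
#'
#' For every cultivar, the model (including its variance components) is
#' refit on the remaining cultivars and the held-out cultivar predicted;
#' the held-out phenotype never enters the fold's estimation.
#'
#' @inheritParams gblup_fit
#' @return numeric vector of out-of-sample predictions, aligned with `y`.
#' @export
loo_gblup <- function(y, K) {
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(gblup_fit(y[-i], K[-i, -i, drop = FALSE]),
                    error = function(e) e)
    if (inherits(fit, "error")) next
    out[i] <- predict(fit, K[i, -i, drop = FALSE])
  }
  names(out) <- names(y)
  out
}
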