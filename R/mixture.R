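#' Two-component gamma mixture parameters
#'
#' Construct and validate the five genotype-specific parameters describing one
#' cultivar's grain-weight density: the mixing proportion `p` of the left
#' (unfilled-grain) component and the shape/scale pairs of the left and right
#' gamma components.  The density of a single grain weight x (mg) is
#' `p * dgamma(x, a1, scale = b1) + (1 - p) * dgamma(x, a2, scale = b2)`.
#'
#' Components are canonically labeled: the left component has the smaller
#' mean (`a1 * b1 <= a2 * b2`).  Use `canonical = FALSE` to skip the swap
#' (the ordering is then only checked, not enforced).
#'
#' @param p mixing proportion of the left component, in \[0, 1\].
#' @param a1,b1 shape (dimensionless) and scale (mg) of the left component.
#' @param a2,b2 shape and scale of the right component.
#' @param canonical if `TRUE` (default), swap components (and replace `p` by
#'   `1 - p`) when the left mean exceeds the right mean.
#' @return an object of class `mixture_params`: a list with elements
#'   `p`, `a1`, `b1`, `a2`, `b2`.
#' @examples
#' mp <- mixture_params(0.175, 1.5, 4, 100, 0.25)
#' mixture_mean(mp)
#' @export
mixture_params <- function(p, a1, b1, a2, b2, canonical = TRUE) {
  vals <- c(p = p, a1 = a1, b1 = b1, a2 = a2, b2 = b2)
  if (any(!is.finite(vals)))
    stop("mixture parameters must be finite numbers")
  if (p < 0 || p > 1)
    stop("mixing proportion 'p' must lie in [0, 1], got ", format(p))
  if (a1 <= 0 || b1 <= 0 || a2 <= 0 || b2 <= 0)
    stop("gamma shape and scale parameters must be strictly positive")
  if (canonical && a1 * b1 > a2 * b2) {
    tmp <- c(a1, b1); a1 <- a2; b1 <- b2; a2 <- tmp[1]; b2 <- tmp[2]
    p <- 1 - p
  }
  structure(list(p = p, a1 = a1, b1 = b1, a2 = a2, b2 = b2),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "gamma mixture: p = %.4g | left (a1 = %.4g, b1 = %.4g, mean %.4g mg)",
    x$p, x$a1, x$b1, x$a1 * x$b1), "\n")
  cat(sprintf("               | right (a2 = %.4g, b2 = %.4g, mean %.4g mg)\n",
              x$a2, x$b2, x$a2 * x$b2))
  invisible(x)
}

is_mixture_params <- function(x) inherits(x, "mixture_params")

assert_params <- function(params) {
  if (!is_mixture_params(params)) {
    if (is.list(params) && all(c("p", "a1", "b1", "a2", "b2") %in% names(params)))
      return(mixture_params(params$p, params$a1, params$b1, params$a2,
                            params$b2, canonical = FALSE))
    stop("expected a 'mixture_params' object")
  }
  params
}

#' Overall mean of a gamma mixture
#'
#' @param params a [mixture_params()] object.
#' @return `p * a1 * b1 + (1 - p) * a2 * b2` (mg).
#' @export
mixture_mean <- function(params) {
  params <- assert_params(params)
  params$p * params$a1 * params$b1 + (1 - params$p) * params$a2 * params$b2
}

#' Density of the two-component gamma mixture
#'
#' Evaluated in log space per component (via `dgamma(log = TRUE)`) and
#' combined with a stable log-sum-exp, so large shape parameters (filled
#' grains routinely fit with shapes near 100) do not overflow.
#'
#' @param params a [mixture_params()] object.
#' @param x numeric vector of grain weights (mg); the density is 0 for
#'   `x <= 0`.
#' @param log if `TRUE` return the log density.
#' @return numeric vector of densities (per mg).
#' @export
mixture_pdf <- function(params, x, log = FALSE) {
  params <- assert_params(params)
  out <- rep(if (log) -Inf else 0, length(x))
  pos <- is.finite(x) & x > 0
  if (any(pos)) {
    xp <- x[pos]
    l1 <- stats::dgamma(xp, shape = params$a1, scale = params$b1, log = TRUE)
    l2 <- stats::dgamma(xp, shape = params$a2, scale = params$b2, log = TRUE)
    ld <- logsumexp2(log(params$p) + l1, log1p(-params$p) + l2)
    out[pos] <- if (log) ld else exp(ld)
  }
  out
}

# pairwise log(exp(la) + exp(lb)) handling -Inf safely
logsumexp2 <- function(la, lb) {
  m <- pmax(la, lb)
  res <- m + log(exp(la - m) + exp(lb - m))
  res[!is.finite(m)] <- -Inf
  res
}

#' Cumulative distribution function of the gamma mixture
#'
#' @inheritParams mixture_pdf
#' @param q numeric vector of quantiles (mg).
#' @return probabilities; 0 for `q <= 0`, tending to 1 as `q` grows.
#' @export
mixture_cdf <- function(params, q) {
  params <- assert_params(params)
  out <- numeric(length(q))
  pos <- is.finite(q) & q > 0
  if (any(pos)) {
    qp <- q[pos]
    out[pos] <- params$p * stats::pgamma(qp, shape = params$a1, scale = params$b1) +
      (1 - params$p) * stats::pgamma(qp, shape = params$a2, scale = params$b2)
  }
  out[is.finite(q) & q == Inf] <- 1
  out
}

#' Quantile function of the gamma mixture
#'
#' Inverts [mixture_cdf()] by root finding between component quantiles.
#'
#' @inheritParams mixture_pdf
#' @param prob probabilities in (0, 1).
#' @return quantiles (mg).
#' @export
mixture_quantile <- function(params, prob) {
  params <- assert_params(params)
  vapply(prob, function(pr) {
    if (pr <= 0) return(0)
    if (pr >= 1) return(Inf)
    lo <- min(stats::qgamma(pr, params$a1, scale = params$b1),
              stats::qgamma(pr, params$a2, scale = params$b2))
    hi <- max(stats::qgamma(pr, params$a1, scale = params$b1),
              stats::qgamma(pr, params$a2, scale = params$b2))
    if (hi - lo < .Machine$double.eps) return(lo)
    stats::uniroot(function(z) mixture_cdf(params, z) - pr,
                   lower = lo, upper = hi, tol = 1e-10,
                   extendInt = "upX")$root
  }, numeric(1))
}

#' Log-likelihood of a weight sample under a gamma mixture
#'
#' @param params a [mixture_params()] object.
#' @param weights numeric vector of grain weights (mg); all must be > 0.
#' @return the summed log density.
#' @export
mixture_loglik <- function(params, weights) {
  if (length(weights) == 0) stop("empty weight sample")
  if (any(weights <= 0)) stop("all weights must be strictly positive")
  sum(mixture_pdf(params, weights, log = TRUE))
}

#' Posterior probability that a grain is filled
#'
#' The responsibility of the right-side (filled-grain) component,
#' `(1 - p) f2(x) / f(x)`, computed in log space.  A grain is labeled
#' "filled" when this exceeds 0.5.
#'
#' @inheritParams mixture_loglik
#' @param x numeric vector of grain weights (mg), all > 0.
#' @return probabilities in \[0, 1\].
#' @export
posterior_filled <- function(params, x) {
  params <- assert_params(params)
  if (any(x <= 0)) stop("weights must be strictly positive")
  if (params$p == 0) return(rep(1, length(x)))
  if (params$p == 1) return(rep(0, length(x)))
  l2 <- log1p(-params$p) +
    stats::dgamma(x, shape = params$a2, scale = params$b2, log = TRUE)
  exp(l2 - mixture_pdf(params, x, log = TRUE))
}
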