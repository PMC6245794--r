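#' Self-energy of a gamma density
#'
#' `g(alpha, beta) = integral of dgamma(x, alpha, scale = beta)^2 over
#' (0, Inf)`, in closed form:
#' `2^(1 - 2 alpha) / ((2 alpha - 1) * beta * B(alpha, alpha))`, evaluated
#' in log space (shapes near 100 overflow naive powers).  The integral
#' diverges for `alpha <= 1/2`.
#'
#' @param alpha gamma shape, must exceed 0.5.
#' @param beta gamma scale, positive.
#' @return the squared-density integral (per mg).
#' @export
g_term <- function(alpha, beta) {
  if (any(alpha <= 0.5))
    stop("g_term diverges for shape <= 0.5 (got ", format(min(alpha)), ")")
  if (any(beta <= 0)) stop("scale must be positive")
  exp((1 - 2 * alpha) * log(2) - log(2 * alpha - 1) - log(beta) -
        lbeta(alpha, alpha))
}

#' Twice the cross-energy of two gamma densities
#'
#' `h(a1, a2, b1, b2) = 2 * integral of
#' dgamma(x, a1, scale = b1) * dgamma(x, a2, scale = b2)`, in closed form:
#' `2 * b1^(a2-1) * b2^(a1-1) / ((a1+a2-1) * (b1+b2)^(a1+a2-1) *
#' B(a1, a2))`, evaluated in log space.  Diverges for `a1 + a2 <= 1`.
#' Symmetric under the joint swap `(a1, b1) <-> (a2, b2)`, and
#' `h(a, a, b, b) = 2 * g(a, b)`.
#'
#' @param alpha1,alpha2 gamma shapes with `alpha1 + alpha2 > 1`.
#' @param beta1,beta2 positive gamma scales.
#' @return twice the product-density integral.
#' @export
h_term <- function(alpha1, alpha2, beta1, beta2) {
  if (any(alpha1 + alpha2 <= 1))
    stop("h_term diverges for shape sum <= 1")
  if (any(beta1 <= 0) || any(beta2 <= 0)) stop("scales must be positive")
  exp(log(2) + (alpha2 - 1) * log(beta1) + (alpha1 - 1) * log(beta2) -
        log(alpha1 + alpha2 - 1) -
        (alpha1 + alpha2 - 1) * log(beta1 + beta2) -
        lbeta(alpha1, alpha2))
}

#' Squared L2 distance between two gamma mixtures
#'
#' `integral over (0, Inf) of (f(x) - f_hat(x))^2 dx` where both densities
#' are two-component gamma mixtures, expanded termwise into [g_term()]
#' self-energies and [h_term()] cross-energies.  Writing `q = 1 - p`:
#'
#' \deqn{d^2 = p^2 g_1 + q^2 g_2 + \hat p^2 \hat g_1 + \hat q^2 \hat g_2
#'   + p q\, h(f_1, f_2) + \hat p \hat q\, h(\hat f_1, \hat f_2)
#'   - p\hat p\, h(f_1, \hat f_1) - p \hat q\, h(f_1, \hat f_2)
#'   - q \hat p\, h(f_2, \hat f_1) - q \hat q\, h(f_2, \hat f_2)}
#'
#' The expansion is the algebraic square of the four-term difference; each
#' within-density cross term (including the predicted-density term
#' `+ p_hat * (1 - p_hat) * h(a1_hat, a2_hat, b1_hat, b2_hat)`) enters with
#' a positive sign.  Tiny negative results from cancellation are clamped to
#' zero.
#'
#' All four shapes must exceed 0.5 (the self-energies must exist); a fitted
#' shape at or below 0.5 signals a degenerate fit upstream and is an error.
#'
#' @param f,f_hat [mixture_params()] objects (observed and predicted).
#' @return non-negative squared distance.
#' @export
squared_l2_distance <- function(f, f_hat) {
  f <- assert_params(f); f_hat <- assert_params(f_hat)
  shapes <- c(f$a1, f$a2, f_hat$a1, f_hat$a2)
  if (any(shapes <= 0.5))
    stop("squared_l2_distance requires every shape > 0.5; got ",
         paste(format(shapes), collapse = ", "),
         " (a shape <= 0.5 indicates a degenerate fit)")
  p <- f$p; q <- 1 - p
  ph <- f_hat$p; qh <- 1 - ph
  d <- p^2 * g_term(f$a1, f$b1) + q^2 * g_term(f$a2, f$b2) +
    ph^2 * g_term(f_hat$a1, f_hat$b1) + qh^2 * g_term(f_hat$a2, f_hat$b2) +
    p * q * h_term(f$a1, f$a2, f$b1, f$b2) +
    ph * qh * h_term(f_hat$a1, f_hat$a2, f_hat$b1, f_hat$b2) -
    p * ph * h_term(f$a1, f_hat$a1, f$b1, f_hat$b1) -
    p * qh * h_term(f$a1, f_hat$a2, f$b1, f_hat$b2) -
    q * ph * h_term(f$a2, f_hat$a1, f$b2, f_hat$b1) -
    q * qh * h_term(f$a2, f_hat$a2, f$b2, f_hat$b2)
  max(d, 0)
}

#' Pair observed and predicted mixtures over a cultivar population
#'
#' Aligns observed and predicted parameter sets by cultivar id and builds
#' the mean-parameter reference mixture (the per-parameter means of the
#' observed set), the baseline predictor that defines Q2 = 0.
#'
#' @param observed,predicted named lists of [mixture_params()] (names are
#'   cultivar ids), or data frames with columns
#'   `cultivar_id, p, a1, b1, a2, b2`.
#' @return a `prediction_set`: list with `observed`, `predicted` (aligned
#'   named lists) and `reference_means` (a `mixture_params`).
#' @export
prediction_set <- function(observed, predicted) {
  observed <- as_params_list(observed)
  predicted <- as_params_list(predicted)
  ids <- names(observed)
  if (is.null(ids) || is.null(names(predicted)))
    stop("observed and predicted must be named by cultivar id")
  if (!setequal(ids, names(predicted)))
    stop("cultivar ids of observed and predicted sets differ: ",
         paste(c(setdiff(ids, names(predicted)),
                 setdiff(names(predicted), ids)), collapse = ", "))
  predicted <- predicted[ids]
  mean_of <- function(field) mean(vapply(observed, `[[`, numeric(1), field))
  ref <- mixture_params(mean_of("p"), mean_of("a1"), mean_of("b1"),
                        mean_of("a2"), mean_of("b2"), canonical = FALSE)
  structure(list(observed = observed, predicted = predicted,
                 reference_means = ref),
            class = "prediction_set")
}

as_params_list <- function(x) {
  if (is.data.frame(x)) {
    out <- lapply(seq_len(nrow(x)), function(i)
      mixture_params(x$p[i], x$a1[i], x$b1[i], x$a2[i], x$b2[i],
                     canonical = FALSE))
    names(out) <- as.character(x$cultivar_id)
    return(out)
  }
  lapply(x, assert_params)
}

#' Predicted residual error sum of squares over a cultivar population
#'
#' Sum over cultivars of the squared L2 distance between each observed and
#' predicted grain-weight density.
#'
#' @param pset a [prediction_set()].
#' @return non-negative total.
#' @export
press <- function(pset) {
  stopifnot(inherits(pset, "prediction_set"))
  sum(vapply(names(pset$observed), function(id)
    squared_l2_distance(pset$observed[[id]], pset$predicted[[id]]),
    numeric(1)))
}

#' Shape-level prediction skill Q2
#'
#' `1 - PRESS / PRESS_0`, where `PRESS_0` replaces every prediction by the
#' mean-parameter mixture of the observed population.  Q2 is 1 for perfect
#' prediction, 0 for the mean-parameter predictor, and can be negative for
#' predictors worse than the mean (no clamping).
#'
#' @param pset a [prediction_set()].
#' @return a real number `<= 1`.
#' @export
q2_shape <- function(pset) {
  stopifnot(inherits(pset, "prediction_set"))
  denom <- sum(vapply(pset$observed, function(obs)
    squared_l2_distance(obs, pset$reference_means), numeric(1)))
  if (denom <= 0)
    stop("degenerate population: every observed mixture equals the ",
         "mean-parameter mixture")
  1 - press(pset) / denom
}
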