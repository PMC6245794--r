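# Quadrature oracles and random-parameter generators shared across tests.
# All oracles integrate piecewise between component quantiles so that very
# concentrated gamma components (shape ~ 200) are not missed.

# Adaptive quadrature of `fun` over (0, Inf) after the substitution
# x = exp(t), integrating piecewise between the log-quantiles of the gamma
# components involved.  The substitution removes the power singularity at
# the origin and keeps very concentrated components (shape ~ 200) resolved.
quad_integral <- function(fun, comps) {
  qs <- unlist(lapply(comps, function(cp) {
    stats::qgamma(c(1e-14, 0.05, 0.5, 0.95, 1 - 1e-14), cp[1],
                  scale = cp[2])
  }))
  ts <- sort(unique(log(pmax(qs, 1e-300))))
  ts <- c(min(ts) - 30, ts, max(ts) + 5)
  tot <- 0
  for (i in seq_len(length(ts) - 1L)) {
    piece <- tryCatch(
      stats::integrate(function(t) fun(exp(t)) * exp(t), ts[i], ts[i + 1L],
                       rel.tol = 1e-12, abs.tol = 0,
                       subdivisions = 1000L)$value,
      error = function(e)
        stats::integrate(function(t) fun(exp(t)) * exp(t), ts[i],
                         ts[i + 1L], rel.tol = 1e-9, abs.tol = 1e-14,
                         subdivisions = 1000L)$value)
    tot <- tot + piece
  }
  tot
}

quad_g <- function(alpha, beta) {
  quad_integral(function(x) stats::dgamma(x, alpha, scale = beta)^2,
                list(c(alpha, beta)))
}

quad_h <- function(a1, a2, b1, b2) {
  2 * quad_integral(function(x)
    stats::dgamma(x, a1, scale = b1) * stats::dgamma(x, a2, scale = b2),
    list(c(a1, b1), c(a2, b2)))
}

quad_l2 <- function(f, f_hat) {
  quad_integral(function(x)
    (mixture_pdf(f, x) - mixture_pdf(f_hat, x))^2,
    list(c(f$a1, f$b1), c(f$a2, f$b2),
         c(f_hat$a1, f_hat$b1), c(f_hat$a2, f_hat$b2)))
}

# random mixture with shapes in (0.6, 200), scales in (0.01, 10)
rand_mixture <- function() {
  mixture_params(p = stats::runif(1, 0.02, 0.98),
                 a1 = exp(stats::runif(1, log(0.6), log(200))),
                 b1 = exp(stats::runif(1, log(0.01), log(10))),
                 a2 = exp(stats::runif(1, log(0.6), log(200))),
                 b2 = exp(stats::runif(1, log(0.01), log(10))))
}

# random mixture in the grain-weight regime: unfilled grains light and
# right-skewed, filled grains near 25 mg with small spread
rand_grain_mixture <- function() {
  mixture_params(p = stats::runif(1, 0.1, 0.35),
                 a1 = stats::runif(1, 1.2, 2.5),
                 b1 = stats::runif(1, 2.5, 5),
                 a2 = stats::runif(1, 60, 140),
                 b2 = stats::runif(1, 25 / 140, 25 / 60))
}

# squared-L2 distance using the sign of the final cross term as printed in
# the typeset source formula (minus instead of plus)
l2_printed_sign <- function(f, f_hat) {
  squared_l2_distance(f, f_hat) -
    2 * f_hat$p * (1 - f_hat$p) *
      h_term(f_hat$a1, f_hat$a2, f_hat$b1, f_hat$b2)
}

# small marker panel + heritable trait for genomic-layer tests
sim_small_panel <- function(n, m, seed) {
  set.seed(seed)
  codes <- matrix(2 * stats::rbinom(n * m, 1,
                                    rep(stats::runif(m, 0.05, 0.5),
                                        each = n)) - 1,
                  n, m,
                  dimnames = list(sprintf("c%03d", 1:n),
                                  sprintf("m%04d", 1:m)))
  codes
}
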