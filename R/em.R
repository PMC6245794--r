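#' Prepare a single-cultivar grain-weight sample for fitting
#'
#' Grain weights at or below a measurement floor are removed before fitting
#' (the gamma support excludes zero, and balances recorded as 0 mg would make
#' the likelihood infinite); the count removed is retained.
#'
#' @param weights numeric vector of single-grain dry weights (mg).
#' @param cultivar_id optional identifier carried through to results.
#' @param floor_mg weights `<= floor_mg` are excluded (default 0.1 mg).
#' @param min_grains minimum retained sample size (default 50).
#' @return a `grain_sample` object: list with `cultivar_id`, `weights`,
#'   `n_excluded_zero`.
#' @export
grain_sample <- function(weights, cultivar_id = NA_character_,
                         floor_mg = 0.1, min_grains = 50L) {
  if (any(!is.finite(weights))) stop("weights must be finite")
  keep <- weights > floor_mg
  w <- weights[keep]
  if (length(w) < min_grains)
    stop("cultivar ", cultivar_id, ": only ", length(w),
         " grains above the ", floor_mg, " mg floor (minimum ", min_grains, ")")
  structure(list(cultivar_id = cultivar_id, weights = w,
                 n_excluded_zero = sum(!keep)),
            class = "grain_sample")
}

as_grain_sample <- function(x, ...) {
  if (inherits(x, "grain_sample")) x else grain_sample(x, ...)
}

#' Random initial parameters for the mixture EM
#'
#' The initial mixing proportion is 0.5.  Two distinct grain weights x' are
#' drawn without replacement; for each, the moment-matched start
#' `a0 = x'^2 / Var(x)`, `b0 = Var(x) / x'` (so `a0 * b0 = x'`) seeds one
#' component — the lighter draw the left component, the heavier the right.
#' Tied draws are rejected and redrawn.
#'
#' @param sample a `grain_sample` (or bare weight vector).
#' @return a [mixture_params()] object (not canonicalized; the draws are
#'   ordered so left mean < right mean by construction).
#' @export
init_parameters <- function(sample) {
  sample <- as_grain_sample(sample)
  x <- sample$weights
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0)
    stop("degenerate sample: zero variance")
  for (attempt in 1:100) {
    d <- sample(x, 2L, replace = FALSE)
    if (d[1] != d[2]) break
  }
  if (d[1] == d[2]) stop("could not draw two distinct weights")
  d <- sort(d)
  mixture_params(p = 0.5,
                 a1 = d[1]^2 / v, b1 = v / d[1],
                 a2 = d[2]^2 / v, b2 = v / d[2],
                 canonical = FALSE)
}

#' EM fit of the two-component gamma mixture from one initialization
#'
#' Alternates the E-step (posterior responsibilities of the left component)
#' with the M-step (`p` set to the mean responsibility; each component refit
#' by [weighted_gamma_mle()] with the responsibilities as weights).  The
#' log-likelihood is non-decreasing across iterations; iteration stops when
#' the increase falls below `tol` or `max_iter` is reached.  The result is
#' canonically labeled so the left component has the smaller mean.
#'
#' @param sample a `grain_sample` (or bare weight vector).
#' @param init a [mixture_params()] starting point.
#' @param tol stopping threshold on the log-likelihood increase.
#' @param max_iter iteration cap.
#' @return list of class `em_fit` with `params`, `loglik`, `loglik_trace`,
#'   `n_iterations`, `converged`.
#' @export
em_fit <- function(sample, init, tol = 1e-8, max_iter = 1000L) {
  sample <- as_grain_sample(sample)
  x <- sample$weights
  n <- length(x)
  par <- assert_params(init)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: responsibility of the left component, in log space
    l1 <- log(par$p) + stats::dgamma(x, par$a1, scale = par$b1, log = TRUE)
    l2 <- log1p(-par$p) + stats::dgamma(x, par$a2, scale = par$b2, log = TRUE)
    ld <- logsumexp2(l1, l2)
    r <- exp(l1 - ld)
    ll <- sum(ld)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    s1 <- sum(r); s2 <- n - s1
    if (s1 < 1e-10 || s2 < 1e-10)
      stop("component collapse: a responsibility sum vanished")
    c1 <- weighted_gamma_mle(x, r)
    c2 <- weighted_gamma_mle(x, 1 - r)
    par <- mixture_params(p = s1 / n,
                          a1 = c1$shape, b1 = c1$scale,
                          a2 = c2$shape, b2 = c2$scale,
                          canonical = FALSE)
  }
  params <- mixture_params(par$p, par$a1, par$b1, par$a2, par$b2,
                           canonical = TRUE)
  structure(list(params = params,
                 loglik = trace[length(trace)],
                 loglik_trace = trace,
                 n_iterations = length(trace),
                 converged = converged),
            class = "em_fit")
}

#' Multi-restart EM fit
#'
#' Runs [em_fit()] from `n_restarts` independent random initializations
#' ([init_parameters()]) and returns the converged run with the highest
#' log-likelihood.  Restarts that fail (component collapse, degenerate
#' M-step) are recorded and discarded.
#'
#' @inheritParams em_fit
#' @param n_restarts number of random initializations (default 100, the
#'   recommended production setting; tests and quick runs use fewer).
#' @param seed optional integer seed for reproducible initializations.
#' @return an `em_fit` list with additional fields `restart_index`
#'   (1-based index of the winning restart), `n_failed`, and
#'   `restart_logliks` (NA for failed restarts).
#' @export
fit_with_restarts <- function(sample, n_restarts = 100L, seed = NULL,
                              tol = 1e-8, max_iter = 1000L) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  sample <- as_grain_sample(sample)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  logliks <- rep(NA_real_, n_restarts)
  failures <- character(0)
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(em_fit(sample, init_parameters(sample),
                           tol = tol, max_iter = max_iter),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    logliks[i] <- fit$loglik
    if (fit$converged &&
        (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
      best$restart_index <- i
    }
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts failed or did not converge; ",
         "first failure: ",
         if (length(failures)) failures[1] else "non-convergence")
  best$n_failed <- length(failures)
  best$restart_logliks <- logliks
  best
}

#' Fit gamma mixtures for every cultivar in a grain-weight table
#'
#' Pools all panicles of a cultivar (replicate pooling), drops weights at or
#' below the measurement floor, and runs the multi-restart EM.  Cultivars
#' whose fit fails or does not meet the minimum sample size are flagged in
#' the output, not silently dropped.
#'
#' @param data data frame with columns `cultivar_id` and `grain_weight_mg`
#'   (a `panicle_id` column, if present, is ignored for fitting — replicates
#'   are pooled).
#' @param n_restarts,seed,tol,max_iter passed to [fit_with_restarts()];
#'   each cultivar gets a seed derived deterministically from `seed`.
#' @param floor_mg,min_grains passed to [grain_sample()].
#' @return list with `table` (one row per cultivar: the five parameters, the
#'   four feature values, boundary statistics, log-likelihood, counts,
#'   convergence flag) and `fits` (named list of `mixture_params`, NULL
#'   where fitting failed).
#' @export
fit_cultivars <- function(data, n_restarts = 100L, seed = 1L,
                          floor_mg = 0.1, min_grains = 50L,
                          tol = 1e-8, max_iter = 1000L) {
  stopifnot(all(c("cultivar_id", "grain_weight_mg") %in% names(data)))
  ids <- unique(as.character(data$cultivar_id))
  fits <- stats::setNames(vector("list", length(ids)), ids)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    w <- data$grain_weight_mg[data$cultivar_id == id]
    res <- tryCatch({
      smp <- grain_sample(w, id, floor_mg = floor_mg, min_grains = min_grains)
      fit <- fit_with_restarts(smp, n_restarts = n_restarts,
                               seed = seed + 7L * k,
                               tol = tol, max_iter = max_iter)
      list(smp = smp, fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("cultivar ", id, ": ", conditionMessage(res), call. = FALSE)
      rows[[k]] <- data.frame(cultivar_id = id, p = NA_real_, a1 = NA_real_,
                              b1 = NA_real_, a2 = NA_real_, b2 = NA_real_,
                              mode1 = NA_real_, skewness1 = NA_real_,
                              mu2 = NA_real_, var2 = NA_real_,
                              boundary_point = NA_real_,
                              boundary_probability = NA_real_,
                              boundary_ratio = NA_real_, bimodal = NA,
                              loglik = NA_real_,
                              n_grains = sum(w > floor_mg),
                              n_excluded = sum(w <= floor_mg),
                              converged = FALSE)
      next
    }
    par <- res$fit$params
    fv <- feature_values(par)
    ba <- boundary_analysis(par)
    fits[[id]] <- par
    rows[[k]] <- data.frame(cultivar_id = id, p = par$p, a1 = par$a1,
                            b1 = par$b1, a2 = par$a2, b2 = par$b2,
                            mode1 = fv$mode1, skewness1 = fv$skewness1,
                            mu2 = fv$mu2, var2 = fv$var2,
                            boundary_point = ba$boundary_point,
                            boundary_probability = ba$boundary_probability,
                            boundary_ratio = ba$ratio, bimodal = ba$bimodal,
                            loglik = res$fit$loglik,
                            n_grains = length(res$smp$weights),
                            n_excluded = res$smp$n_excluded_zero,
                            converged = res$fit$converged)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fits = fits)
}
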