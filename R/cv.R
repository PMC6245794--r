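PARAM_COLS <- c("p", "a1", "b1", "a2", "b2")

#' Clamp predicted mixture parameters into the valid domain
#'
#' Linear predictors (GBLUP, PLS) are unconstrained, so predicted parameter
#' vectors can fall outside the mixture domain.  Before a predicted table
#' is turned into densities (shape Q2, plug-in trait formulas), `p` is
#' clamped to \[0, 1\], shapes to at least `shape_floor` (the squared-L2
#' geometry requires every shape > 0.5), and scales to at least
#' `scale_floor`.
#'
#' @param df data frame with columns `p, a1, b1, a2, b2`.
#' @param shape_floor minimum shape (default 0.55).
#' @param scale_floor minimum scale in mg (default 1e-4).
#' @return the clamped data frame.
#' @export
clamp_mixture_table <- function(df, shape_floor = 0.55, scale_floor = 1e-4) {
  df$p <- pmin(pmax(df$p, 0), 1)
  for (cc in c("a1", "a2")) df[[cc]] <- pmax(df[[cc]], shape_floor)
  for (cc in c("b1", "b2")) df[[cc]] <- pmax(df[[cc]], scale_floor)
  df
}

# Derived grain-filling traits from a table of mixture parameters.
# boundary columns are NA for rows whose mixture is not bimodal.
derived_traits_from_params <- function(df, boundary_grid = 4000L) {
  out <- data.frame(cultivar_id = df$cultivar_id)
  n <- nrow(df)
  cols <- c("mode1", "skewness1", "mu2", "var2", "boundary_point",
            "boundary_probability", "p23mg", "p90pct", "sink_filling_rate")
  for (cc in cols) out[[cc]] <- NA_real_
  for (i in seq_len(n)) {
    par <- mixture_params(df$p[i], df$a1[i], df$b1[i], df$a2[i], df$b2[i],
                          canonical = FALSE)
    fv <- feature_values(par)
    ba <- boundary_analysis(par, n_grid = boundary_grid)
    q95 <- mixture_quantile(par, 0.95)
    out$mode1[i] <- fv$mode1
    out$skewness1[i] <- fv$skewness1
    out$mu2[i] <- fv$mu2
    out$var2[i] <- fv$var2
    out$boundary_point[i] <- ba$boundary_point
    out$boundary_probability[i] <- ba$boundary_probability
    out$p23mg[i] <- mixture_cdf(par, 23)
    out$p90pct[i] <- mixture_cdf(par, 0.9 * q95)
    out$sink_filling_rate[i] <- mixture_mean(par) / q95
  }
  out
}

#' Choose the number of PLS components by leave-one-out shape Q2
#'
#' For each candidate component count, the responses are predicted by
#' leave-one-out cross-validation and the shape-level Q2 ([q2_shape()]) of
#' the resulting mixture population is computed; parameters not covered by
#' this model keep their observed values, so differences in Q2 are
#' attributable to the model under selection.  Ties break toward fewer
#' components.
#'
#' @param X marker matrix (rows = cultivars).
#' @param Y response matrix whose column names are a subset of
#'   `p, a1, b1, a2, b2`.
#' @param observed data frame of the full observed parameter table
#'   (`cultivar_id` + the five parameters), rows aligned with `X`.
#' @param max_ncomp maximum components considered (default 30).
#' @param scale passed to [pls_fit()].
#' @return list with `ncomp` (the argmax), `q2` (the Q2 profile), and
#'   `loo` (the LOO prediction array).
#' @export
select_ncomp <- function(X, Y, observed, max_ncomp = 30L, scale = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(all(colnames(Y) %in% PARAM_COLS), nrow(X) >= 3)
  loo <- loo_pls_all(X, Y, max_ncomp, scale = scale)
  kmax <- dim(loo)[3]
  obs_list <- as_params_list(observed)
  q2 <- vapply(seq_len(kmax), function(k) {
    pred <- observed
    pred[, colnames(Y)] <- loo[, , k]
    pred <- clamp_mixture_table(pred)
    q2_shape(prediction_set(observed, pred))
  }, numeric(1))
  list(ncomp = which.max(q2), q2 = q2, loo = loo)
}

pls_groups <- function(scheme) {
  switch(scheme,
         pls1 = list(all = PARAM_COLS),
         pls3 = list(p = "p", left = c("a1", "b1"), right = c("a2", "b2")),
         plsE = stats::setNames(as.list(PARAM_COLS), PARAM_COLS),
         stop("unknown PLS scheme: ", scheme))
}

# Fitted (training) and LOO-predicted parameter tables for one PLS scheme.
pls_scheme_predict <- function(X, observed, scheme, max_ncomp = 30L,
                               select = c("global", "per-fold"),
                               scale = FALSE) {
  select <- match.arg(select)
  groups <- pls_groups(scheme)
  n <- nrow(X)
  fitted <- predicted <- observed
  ncomp_used <- stats::setNames(integer(length(groups)), names(groups))
  for (gname in names(groups)) {
    cols <- groups[[gname]]
    Y <- as.matrix(observed[, cols, drop = FALSE])
    colnames(Y) <- cols
    if (select == "global") {
      sel <- select_ncomp(X, Y, observed, max_ncomp = max_ncomp,
                          scale = scale)
      ncomp_used[gname] <- sel$ncomp
      predicted[, cols] <- sel$loo[, , sel$ncomp]
    } else {
      ks <- integer(n)
      for (i in seq_len(n)) {
        sel_i <- select_ncomp(X[-i, , drop = FALSE],
                              Y[-i, , drop = FALSE],
                              observed[-i, , drop = FALSE],
                              max_ncomp = max_ncomp, scale = scale)
        ks[i] <- sel_i$ncomp
        fit_i <- pls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                         ncomp = sel_i$ncomp, scale = scale)
        predicted[i, cols] <- predict(fit_i, X[i, , drop = FALSE])
      }
      ncomp_used[gname] <- as.integer(stats::median(ks))
    }
    full <- pls_fit(X, Y, ncomp = max(ncomp_used[gname], 1L), scale = scale)
    fitted[, cols] <- predict(full, X,
                              ncomp = min(ncomp_used[gname], full$ncomp))
  }
  list(fitted = fitted, predicted = predicted, ncomp = ncomp_used)
}

# Fitted and LOO tables for per-parameter GBLUP, plus variance components.
gblup_scheme_predict <- function(K, observed) {
  fitted <- predicted <- observed
  vc <- data.frame(trait = PARAM_COLS, sigma2_g = NA_real_,
                   sigma2_e = NA_real_, h2 = NA_real_)
  for (j in seq_along(PARAM_COLS)) {
    pc <- PARAM_COLS[j]
    y <- observed[[pc]]
    fit <- gblup_fit(y, K)
    fitted[[pc]] <- fit$fitted
    predicted[[pc]] <- loo_gblup(y, K)
    vc$sigma2_g[j] <- fit$sigma2_g
    vc$sigma2_e[j] <- fit$sigma2_e
    vc$h2[j] <- fit$h2
  }
  list(fitted = fitted, predicted = predicted, variance_components = vc)
}

acc_cor <- function(obs, est) {
  ok <- is.finite(obs) & is.finite(est)
  if (sum(ok) < 3 || stats::sd(obs[ok]) == 0 || stats::sd(est[ok]) == 0)
    return(NA_real_)
  stats::cor(obs[ok], est[ok])
}

#' Run the full genomic-prediction experiment
#'
#' Predicts the five grain-weight distribution parameters from genome-wide
#' markers under four schemes — per-parameter GBLUP, one-group PLS (all
#' five parameters in one model), three-group PLS (`{p}`, `{a1, b1}`,
#' `{a2, b2}`), and each-parameter PLS — each evaluated by leave-one-out
#' cross-validation.  Reports, per scheme: Pearson accuracy
#' (observed vs fitted and observed vs LOO-predicted) for the parameters,
#' the derived feature values (`mode1`, `skewness1`, `mu2`, `var2`),
#' boundary statistics, and conventional traits; PRESS and shape Q2 of the
#' fitted and predicted mixture populations; and (GBLUP) REML variance
#' components with narrow-sense heritabilities.  Derived traits are
#' evaluated by plugging predicted parameters into their formulas, and —
#' for GBLUP — also by direct prediction of each trait itself (the
#' parenthesized route of the accuracy tables).
#'
#' @param codes cultivars x markers matrix in \{-1, 0, 1\} (filtered here
#'   unless `filter = FALSE`).
#' @param fits observed parameters: the `table` from [fit_cultivars()], a
#'   data frame with `cultivar_id` and the five parameter columns, or a
#'   named list of [mixture_params()].
#' @param traits optional data frame of measured conventional traits
#'   (`cultivar_id`, `p23mg`, `p90pct`, `sink_filling_rate`); when absent,
#'   plug-in values from the observed parameters serve as the observed
#'   trait values.
#' @param schemes subset of `c("gblup", "pls1", "pls3", "plsE")`.
#' @param max_ncomp maximum PLS components (default 30).
#' @param select PLS component selection: `"per-fold"` (selection repeated
#'   inside every LOO fold; no leakage — the default) or `"global"`
#'   (selected once on the full set, the protocol used in the original
#'   study design).
#' @param filter if `TRUE`, apply [filter_markers()] first.
#' @param maf_min,max_het passed to [filter_markers()].
#' @param scale_pls scale PLS columns to unit variance (default `FALSE`).
#' @return list of class `prediction_experiment` with elements `schemes`
#'   (per-scheme result lists), `observed`, `observed_traits`,
#'   `cultivar_ids`, `n_markers`.
#' @export
run_prediction_experiment <- function(codes, fits, traits = NULL,
                                      schemes = c("gblup", "pls1", "pls3",
                                                  "plsE"),
                                      max_ncomp = 30L,
                                      select = c("per-fold", "global"),
                                      filter = TRUE, maf_min = 0.025,
                                      max_het = 0.05, scale_pls = FALSE) {
  select <- match.arg(select)
  schemes <- match.arg(schemes, several.ok = TRUE)
  observed <- fits_as_table(fits)
  observed <- observed[stats::complete.cases(observed[, PARAM_COLS]), ]
  common <- intersect(rownames(codes), observed$cultivar_id)
  if (length(common) < 10)
    stop("need >= 10 cultivars with both genotype and fitted parameters; ",
         "got ", length(common))
  missing_geno <- setdiff(observed$cultivar_id, common)
  if (length(missing_geno))
    warning("no genotype for cultivar(s): ",
            paste(missing_geno, collapse = ", "))
  observed <- observed[match(common, observed$cultivar_id), ]
  rownames(observed) <- NULL
  codes <- codes[common, , drop = FALSE]
  if (filter) codes <- filter_markers(codes, maf_min = maf_min,
                                      max_het = max_het)
  K <- genomic_relationship(codes)
  X <- codes

  obs_derived <- derived_traits_from_params(observed)
  if (!is.null(traits)) {
    m <- match(common, as.character(traits$cultivar_id))
    for (cc in c("p23mg", "p90pct", "sink_filling_rate"))
      if (cc %in% names(traits)) obs_derived[[cc]] <- traits[[cc]][m]
  }
  derived_cols <- setdiff(names(obs_derived), "cultivar_id")

  results <- list()
  for (scheme in schemes) {
    if (scheme == "gblup") {
      sp <- gblup_scheme_predict(K, observed)
      ncomp <- NULL
    } else {
      sp <- pls_scheme_predict(X, observed, scheme, max_ncomp = max_ncomp,
                               select = select, scale = scale_pls)
      ncomp <- sp$ncomp
    }
    fitted_cl <- clamp_mixture_table(sp$fitted)
    predicted_cl <- clamp_mixture_table(sp$predicted)
    fit_derived <- derived_traits_from_params(fitted_cl)
    pred_derived <- derived_traits_from_params(predicted_cl)

    acc <- data.frame(trait = c(PARAM_COLS, derived_cols),
                      fitting = NA_real_, prediction = NA_real_)
    for (pc in PARAM_COLS) {
      i <- acc$trait == pc
      acc$fitting[i] <- acc_cor(observed[[pc]], sp$fitted[[pc]])
      acc$prediction[i] <- acc_cor(observed[[pc]], sp$predicted[[pc]])
    }
    for (dc in derived_cols) {
      i <- acc$trait == dc
      acc$fitting[i] <- acc_cor(obs_derived[[dc]], fit_derived[[dc]])
      acc$prediction[i] <- acc_cor(obs_derived[[dc]], pred_derived[[dc]])
    }

    res <- list(method = scheme, ncomp = ncomp,
                fitted = sp$fitted, predicted = sp$predicted,
                accuracies = acc,
                press_fitting = press(prediction_set(observed, fitted_cl)),
                q2_fitting = q2_shape(prediction_set(observed, fitted_cl)),
                press_prediction = press(prediction_set(observed,
                                                        predicted_cl)),
                q2_prediction = q2_shape(prediction_set(observed,
                                                        predicted_cl)))
    if (scheme == "gblup") {
      res$variance_components <- sp$variance_components
      # direct route: a GBLUP model per derived trait
      acc$fitting_direct <- NA_real_
      acc$prediction_direct <- NA_real_
      vc_extra <- list()
      for (dc in derived_cols) {
        y <- obs_derived[[dc]]
        ok <- is.finite(y)
        if (sum(ok) < 10 || stats::sd(y[ok]) == 0) next
        fit <- gblup_fit(y[ok], K[ok, ok, drop = FALSE])
        pred <- loo_gblup(y[ok], K[ok, ok, drop = FALSE])
        i <- acc$trait == dc
        acc$fitting_direct[i] <- acc_cor(y[ok], fit$fitted)
        acc$prediction_direct[i] <- acc_cor(y[ok], pred)
        vc_extra[[dc]] <- data.frame(trait = dc, sigma2_g = fit$sigma2_g,
                                     sigma2_e = fit$sigma2_e, h2 = fit$h2)
      }
      res$accuracies <- acc
      res$variance_components <- rbind(sp$variance_components,
                                       do.call(rbind, vc_extra))
      rownames(res$variance_components) <- NULL
    }
    results[[scheme]] <- res
  }
  structure(list(schemes = results, observed = observed,
                 observed_traits = obs_derived,
                 cultivar_ids = common, n_markers = ncol(codes)),
            class = "prediction_experiment")
}

fits_as_table <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("cultivar_id", PARAM_COLS) %in% names(fits)))
    out <- fits[, c("cultivar_id", PARAM_COLS)]
    out$cultivar_id <- as.character(out$cultivar_id)
    return(out)
  }
  if (is.list(fits)) {
    fits <- Filter(Negate(is.null), fits)
    out <- do.call(rbind, lapply(names(fits), function(id) {
      par <- assert_params(fits[[id]])
      data.frame(cultivar_id = id, p = par$p, a1 = par$a1, b1 = par$b1,
                 a2 = par$a2, b2 = par$b2)
    }))
    rownames(out) <- NULL
    return(out)
  }
  stop("unsupported 'fits' input")
}
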