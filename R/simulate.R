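#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the field-study regime the package targets: an inbred
#' rice panel with a uniform minor-allele-frequency spectrum, five
#' additively heritable mixture parameters centered on a population in
#' which filled grains average about 25 mg with small variance, unfilled
#' grains average about 6 mg with strong right skew, and the unfilled
#' proportion centers near 0.175.
#'
#' @param n_cultivars number of (inbred) cultivars.
#' @param n_markers number of biallelic markers.
#' @param n_qtl number of causal markers per parameter.
#' @param target_h2 named vector of heritabilities in (0, 1) for
#'   `p, a1, b1, a2, b2` (a single value is recycled).
#' @param n_grains_per_cultivar grains sampled per cultivar.
#' @param baseline population-center [mixture_params()].
#' @param latent_sd named vector of total latent-scale standard deviations
#'   (p on the logit scale, the others on the log scale).
#' @param het_rate fraction of heterozygous calls (0 for a fully inbred
#'   panel; small values exercise the heterozygosity filter).
#' @param n_duplicate_markers markers duplicated verbatim (to exercise the
#'   complete-linkage filter).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cultivars = 150L, n_markers = 2000L, n_qtl = 50L,
                       target_h2 = 0.5, n_grains_per_cultivar = 1500L,
                       baseline = mixture_params(0.175, 1.5, 4, 100, 0.25),
                       latent_sd = c(p = 0.45, a1 = 0.25, b1 = 0.25,
                                     a2 = 0.2, b2 = 0.12),
                       het_rate = 0, n_duplicate_markers = 0L,
                       seed = 1L) {
  if (length(target_h2) == 1L)
    target_h2 <- stats::setNames(rep(target_h2, 5), PARAM_COLS)
  stopifnot(all(PARAM_COLS %in% names(target_h2)),
            all(target_h2 > 0 & target_h2 < 1),
            n_qtl <= n_markers)
  baseline <- assert_params(baseline)
  if (baseline$a1 * baseline$b1 >= baseline$a2 * baseline$b2)
    stop("baseline must have left-component mean below right-component mean")
  structure(list(n_cultivars = as.integer(n_cultivars),
                 n_markers = as.integer(n_markers),
                 n_qtl = as.integer(n_qtl),
                 target_h2 = target_h2[PARAM_COLS],
                 n_grains_per_cultivar = as.integer(n_grains_per_cultivar),
                 baseline = baseline, latent_sd = latent_sd[PARAM_COLS],
                 het_rate = het_rate,
                 n_duplicate_markers = as.integer(n_duplicate_markers),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an inbred biallelic marker panel
#'
#' Marker allele frequencies are drawn from U(0.05, 0.5); each cultivar
#' carries the alternate homozygote (+1) with that probability,
#' independently across markers (no linkage).  With `het_rate > 0` a
#' fraction of calls is set heterozygous (0) to exercise the panel filter;
#' `n_duplicate_markers` columns are appended as verbatim copies to
#' exercise the complete-linkage filter.
#'
#' @param config a [sim_config()].
#' @return cultivars x markers matrix in \{-1, 0, 1\} with dimnames.
#' @export
simulate_markers <- function(config) {
  set.seed(config$seed)
  n <- config$n_cultivars; m <- config$n_markers
  freq <- stats::runif(m, 0.05, 0.5)
  codes <- matrix(2L * stats::rbinom(n * m, 1L, rep(freq, each = n)) - 1L,
                  nrow = n, ncol = m)
  if (config$het_rate > 0) {
    hets <- stats::runif(n * m) < config$het_rate
    codes[hets] <- 0L
  }
  if (config$n_duplicate_markers > 0) {
    src <- sample(m, config$n_duplicate_markers, replace = TRUE)
    codes <- cbind(codes, codes[, src, drop = FALSE])
  }
  dimnames(codes) <- list(sprintf("cv%03d", seq_len(n)),
                          sprintf("mk%05d", seq_len(ncol(codes))))
  storage.mode(codes) <- "double"
  codes
}

#' Simulate heritable genotype-specific mixture parameters
#'
#' Each parameter gets an additive genetic value `u = Z[, qtl] %*% beta`
#' (the same causal markers for all five parameters, independent effect
#' sizes — mimicking shared genetic control of grain filling), rescaled so
#' that `var(u) / (var(u) + var(e))` equals the target heritability, plus
#' independent normal noise `e`.  The latent value perturbs the baseline on
#' a logit scale for `p` and log scales for the shapes and scales, so every
#' emitted parameter set is a valid mixture.
#'
#' @param codes marker matrix from [simulate_markers()].
#' @param config a [sim_config()].
#' @return list with `params` (data frame: `cultivar_id` plus the five
#'   parameters), `genetic_values` (matrix of the true breeding values on
#'   the latent scale), and `params_list` (named list of
#'   [mixture_params()]).
#' @export
simulate_distribution_params <- function(codes, config) {
  set.seed(config$seed + 1L)
  n <- nrow(codes)
  qtl <- sample(ncol(codes), config$n_qtl)
  Z <- scale(codes[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  base <- config$baseline
  latent0 <- c(p = stats::qlogis(base$p), a1 = log(base$a1),
               b1 = log(base$b1), a2 = log(base$a2), b2 = log(base$b2))
  G <- matrix(NA_real_, n, 5, dimnames = list(rownames(codes), PARAM_COLS))
  latent <- G
  for (j in seq_along(PARAM_COLS)) {
    pc <- PARAM_COLS[j]
    h2 <- config$target_h2[[pc]]
    sd_tot <- config$latent_sd[[pc]]
    beta <- stats::rnorm(config$n_qtl)
    u <- drop(Z %*% beta)
    vu <- stats::var(u)
    if (vu > 0) u <- u * sqrt(h2 * sd_tot^2 / vu) else u <- rep(0, n)
    e <- stats::rnorm(n, sd = sqrt((1 - h2) * sd_tot^2))
    G[, j] <- u
    latent[, j] <- latent0[[pc]] + u + e
  }
  params <- data.frame(cultivar_id = rownames(codes),
                       p = stats::plogis(latent[, "p"]),
                       a1 = exp(latent[, "a1"]), b1 = exp(latent[, "b1"]),
                       a2 = exp(latent[, "a2"]), b2 = exp(latent[, "b2"]))
  rownames(params) <- NULL
  plist <- as_params_list(params)
  list(params = params, genetic_values = G, params_list = plist)
}

#' Sample single-grain weights from a gamma mixture
#'
#' Component membership is Bernoulli(`p`) per grain; each grain's weight is
#' then drawn from its component's gamma distribution.  Membership labels
#' are retained for oracle tests.
#'
#' @param params a [mixture_params()].
#' @param n number of grains.
#' @param seed optional integer seed.
#' @return list with `weights` (mg) and `component` (1 = left/unfilled,
#'   2 = right/filled).
#' @export
simulate_grain_weights <- function(params, n, seed = NULL) {
  params <- assert_params(params)
  if (!is.null(seed)) set.seed(seed)
  comp <- 2L - stats::rbinom(n, 1L, params$p)
  w <- numeric(n)
  left <- comp == 1L
  w[left] <- stats::rgamma(sum(left), params$a1, scale = params$b1)
  w[!left] <- stats::rgamma(sum(!left), params$a2, scale = params$b2)
  list(weights = w, component = comp)
}

#' Generate a complete synthetic dataset
#'
#' Composes the marker, parameter, and grain-weight generators into the
#' full study design: an inbred marker panel, heritable genotype-specific
#' mixture parameters, and a grain-weight sample per cultivar.  Truth
#' tables carry everything needed by recovery tests: the true parameters,
#' latent genetic values, and per-grain component labels.
#'
#' @param config a [sim_config()].
#' @return list with `codes` (marker matrix), `params` (true parameter
#'   table), `genetic_values`, `params_list`, `samples` (named list of
#'   weight vectors), `components` (named list of membership labels), and
#'   `grain_data` (long data frame `cultivar_id, panicle_id,
#'   grain_weight_mg` ready for [fit_cultivars()]).
#' @export
make_dataset <- function(config) {
  codes <- simulate_markers(config)
  truth <- simulate_distribution_params(codes, config)
  ids <- truth$params$cultivar_id
  samples <- components <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(ids)) {
    gw <- simulate_grain_weights(truth$params_list[[ids[k]]],
                                 config$n_grains_per_cultivar,
                                 seed = config$seed + 100L + k)
    samples[[k]] <- gw$weights
    components[[k]] <- gw$component
  }
  grain_data <- data.frame(
    cultivar_id = rep(ids, each = config$n_grains_per_cultivar),
    panicle_id = "pooled",
    grain_weight_mg = unlist(samples, use.names = FALSE))
  list(codes = codes, params = truth$params,
       genetic_values = truth$genetic_values,
       params_list = truth$params_list,
       samples = samples, components = components,
       grain_data = grain_data)
}
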