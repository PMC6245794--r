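#' Rescale counted single-grain weights to dry-matter totals
#'
#' Automatic counting-and-weighing systems report relative single-grain
#' weights; these are adjusted so their sum matches the panicle's total dry
#' weight measured separately.
#'
#' @param measured_weights positive weights as measured.
#' @param total_dry_weight target total (mg).
#' @return rescaled weights summing to `total_dry_weight`.
#' @export
rescale_weights <- function(measured_weights, total_dry_weight) {
  s <- sum(measured_weights)
  if (!is.finite(s) || s <= 0) stop("measured weights must sum to a positive value")
  if (total_dry_weight <= 0) stop("total_dry_weight must be positive")
  measured_weights * (total_dry_weight / s)
}

#' Proportion of grains lighter than a fixed threshold
#'
#' The conventional unfilled-grain proportion: the fraction of grains
#' strictly lighter than `threshold_mg` (default 23 mg).  A single threshold
#' is convenient across cultivars but confounds grain size with filling, so
#' the threshold is configurable.
#'
#' @param weights numeric vector of grain weights (mg).
#' @param threshold_mg weight threshold (default 23).
#' @return fraction in \[0, 1\].
#' @export
p_23mg <- function(weights, threshold_mg = 23) {
  if (length(weights) == 0) stop("empty weight sample")
  mean(weights < threshold_mg)
}

#' Proportion of grains lighter than 90% of the 95th-percentile weight
#'
#' A grain-size-free unfilled proportion: the 95th percentile of the
#' cultivar's own weight distribution stands in for the filled-grain weight,
#' and the trait is the fraction strictly below 90% of it.  Percentiles use
#' linear interpolation of order statistics (the default "type 7" rule of
#' [stats::quantile()]).
#'
#' @param weights numeric vector of grain weights (mg).
#' @param prob percentile defining the reference weight (default 0.95).
#' @param frac fraction of the reference weight used as threshold
#'   (default 0.9).
#' @return fraction in \[0, 1\].
#' @export
p_90pct <- function(weights, prob = 0.95, frac = 0.9) {
  if (length(weights) == 0) stop("empty weight sample")
  q <- stats::quantile(weights, prob, names = FALSE, type = 7)
  mean(weights < frac * q)
}

#' Sink-filling rate
#'
#' Ratio of the total grain weight to the sink capacity, where sink capacity
#' is the 95th-percentile single-grain weight multiplied by the number of
#' grains.  Values near 1 indicate that nearly every grain reached the
#' cultivar's attainable weight.
#'
#' @param weights observed single-grain weights (mg) defining the
#'   percentile.
#' @param n_grains total number of grains.
#' @param total_weight total grain weight (mg); defaults to `sum(weights)`.
#' @param prob percentile defining per-grain sink capacity (default 0.95).
#' @return positive ratio.
#' @export
sink_filling_rate <- function(weights, n_grains = length(weights),
                              total_weight = sum(weights), prob = 0.95) {
  if (n_grains < 1) stop("n_grains must be >= 1")
  if (total_weight <= 0) stop("total_weight must be positive")
  q <- stats::quantile(weights, prob, names = FALSE, type = 7)
  if (q <= 0) stop("degenerate sample: zero sink capacity")
  total_weight / (q * n_grains)
}

#' Conventional grain-filling traits for every cultivar
#'
#' @param data data frame with columns `cultivar_id`, `grain_weight_mg`.
#' @param threshold_mg threshold for [p_23mg()].
#' @return data frame with one row per cultivar: `cultivar_id`, `p23mg`,
#'   `p90pct`, `sink_filling_rate`, `q95`.
#' @export
conventional_traits <- function(data, threshold_mg = 23) {
  stopifnot(all(c("cultivar_id", "grain_weight_mg") %in% names(data)))
  ids <- unique(as.character(data$cultivar_id))
  rows <- lapply(ids, function(id) {
    w <- data$grain_weight_mg[data$cultivar_id == id]
    data.frame(cultivar_id = id,
               p23mg = p_23mg(w, threshold_mg),
               p90pct = p_90pct(w),
               sink_filling_rate = sink_filling_rate(w),
               q95 = stats::quantile(w, 0.95, names = FALSE, type = 7))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classification of positional grains into filled / unfilled components
#'
#' Superior grains (early-flowering, on primary branches) and inferior
#' grains (late-flowering, on secondary branches) are classified by the
#' posterior probability of the filled-grain component under each cultivar's
#' fitted mixture.  Returns the pooled filled fraction per position plus
#' per-cultivar counts (for correlating unfilled counts with the mixing
#' proportion p).
#'
#' @param data data frame with columns `cultivar_id`, `grain_weight_mg`,
#'   `position` (values such as `"superior"` / `"inferior"`; `"unknown"`
#'   rows are ignored).
#' @param fits named list of [mixture_params()] keyed by cultivar id (as
#'   produced by [fit_cultivars()]).
#' @return list with `by_position` (data frame: `position`, `n`, `n_filled`,
#'   `filled_fraction`) and `by_cultivar` (data frame: `cultivar_id`,
#'   `position`, `n`, `n_unfilled`).  Cultivars without a fit are reported
#'   in `skipped` and excluded.
#' @export
positional_classification_summary <- function(data, fits) {
  stopifnot(all(c("cultivar_id", "grain_weight_mg", "position") %in% names(data)))
  data <- data[!is.na(data$position) & data$position != "unknown", ]
  if (nrow(data) == 0) stop("no positional grains present")
  ids <- unique(as.character(data$cultivar_id))
  have <- ids[vapply(ids, function(i) !is.null(fits[[i]]), logical(1))]
  skipped <- setdiff(ids, have)
  data <- data[data$cultivar_id %in% have, ]
  filled <- vapply(seq_len(nrow(data)), function(i) {
    posterior_filled(fits[[as.character(data$cultivar_id[i])]],
                     data$grain_weight_mg[i]) > 0.5
  }, logical(1))
  by_pos <- do.call(rbind, lapply(unique(data$position), function(ps) {
    sel <- data$position == ps
    data.frame(position = ps, n = sum(sel), n_filled = sum(filled[sel]),
               filled_fraction = mean(filled[sel]))
  }))
  combos <- unique(data[, c("cultivar_id", "position")])
  by_cv <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- data$cultivar_id == combos$cultivar_id[i] &
      data$position == combos$position[i]
    data.frame(cultivar_id = combos$cultivar_id[i],
               position = combos$position[i],
               n = sum(sel), n_unfilled = sum(!filled[sel]))
  }))
  rownames(by_pos) <- rownames(by_cv) <- NULL
  list(by_position = by_pos, by_cultivar = by_cv, skipped = skipped)
}
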