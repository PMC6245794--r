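#' Read a grain-weight CSV
#'
#' One row per grain, columns `cultivar_id, panicle_id, grain_weight_mg`,
#' optionally `position` (`superior`/`inferior`/`unknown`).
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_grain_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar_id", "grain_weight_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("grain-weight CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(df$grain_weight_mg)))
    stop("non-numeric grain weights in ", path, " (first bad row: ",
         which(!is.finite(df$grain_weight_mg))[1], ")")
  df$cultivar_id <- as.character(df$cultivar_id)
  df
}

#' Write a fitted-parameters (or traits) table as TSV
#'
#' @param table data frame (e.g. `fit_cultivars()$table`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_params_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fitted-parameters TSV back
#'
#' @param path TSV written by [write_params_tsv()].
#' @return data frame.
#' @export
read_params_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cultivar_id = "character"))
}

#' Serialize a prediction experiment as a JSON report
#'
#' Per scheme: PRESS and Q2 for the fitted and LOO-predicted populations,
#' the per-trait accuracy table, selected PLS component counts, and (GBLUP)
#' variance components with heritabilities.
#'
#' @param experiment a [run_prediction_experiment()] result.
#' @param path output path; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
write_report_json <- function(experiment, path = NULL) {
  stopifnot(inherits(experiment, "prediction_experiment"))
  blocks <- lapply(experiment$schemes, function(s) {
    b <- list(method = s$method,
              press_fitting = s$press_fitting,
              q2_fitting = s$q2_fitting,
              press_prediction = s$press_prediction,
              q2_prediction = s$q2_prediction,
              accuracies = s$accuracies)
    if (!is.null(s$ncomp)) b$ncomp <- as.list(s$ncomp)
    if (!is.null(s$variance_components))
      b$variance_components <- s$variance_components
    b
  })
  report <- list(n_cultivars = length(experiment$cultivar_ids),
                 n_markers = experiment$n_markers,
                 schemes = blocks)
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Flatten a prediction experiment's accuracy tables to one TSV
#'
#' @param experiment a [run_prediction_experiment()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_tsv <- function(experiment, path) {
  stopifnot(inherits(experiment, "prediction_experiment"))
  rows <- do.call(rbind, lapply(experiment$schemes, function(s) {
    acc <- s$accuracies
    acc$method <- s$method
    acc
  }))
  rownames(rows) <- NULL
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
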