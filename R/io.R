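#' Read and write 1D signals as single-column CSV
#'
#' Signals travel as CSV with a single `value` column, one sample per row.
#'
#' @param path file path.
#' @return `read_signal_csv` returns a numeric vector.
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("signal CSV not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) {
    stop("signal CSV must have a 'value' column", call. = FALSE)
  }
  as.numeric(df$value)
}

#' @rdname read_signal_csv
#' @param signal numeric vector to write.
#' @export
write_signal_csv <- function(signal, path) {
  utils::write.csv(data.frame(value = as.numeric(signal)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a structure-function table as tidy CSV
#'
#' Columns `q`, `d`, `K`, one row per (q, d) cell.
#'
#' @param table an `"sf_table"`.
#' @param path file path.
#' @export
write_sf_table_csv <- function(table, path) {
  stopifnot(inherits(table, "sf_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write a Hurst spectrum as CSV or JSON
#'
#' CSV columns: `q`, `H`, `slope`, `r_squared`.
#'
#' @param spectrum a `"hurst_spectrum"`.
#' @param path file path; `write_spectrum_json` writes the same fields as a
#'   JSON object.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "hurst_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_spectrum_json <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "hurst_spectrum"))
  jsonlite::write_json(list(q = spectrum$q_values, H = spectrum$H,
                            slope = spectrum$slope,
                            r_squared = spectrum$r_squared),
                       path, digits = NA)
  invisible(path)
}

#' Read and write feature tables
#'
#' The features CSV has one row per image: `image_id`, `H1..Hk` and,
#' when class membership is known, a `label` column in {+1, -1}.
#'
#' @param path file path.
#' @return `read_features_csv` returns a data frame.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("features CSV not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"image_id" %in% names(df) || !any(grepl("^H[0-9]+$", names(df)))) {
    stop("features CSV must have image_id and H1..Hk columns", call. = FALSE)
  }
  df
}

#' @rdname read_features_csv
#' @param features data frame as produced by [extract_features_batch()] or
#'   [generate_dataset()].
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

feature_matrix <- function(df) {
  cols <- grep("^H[0-9]+$", names(df), value = TRUE)
  cols <- cols[order(as.integer(sub("H", "", cols)))]
  as.matrix(df[, cols, drop = FALSE])
}

#' Write a LOOCV evaluation report as JSON
#'
#' The JSON object carries the aggregate metrics, their per-fold-indicator
#' standard deviations, the classifier configuration and the full per-fold
#' prediction table, so the metrics can be recomputed from the report alone.
#'
#' @param report a `"loocv_report"` from [evaluate_loocv()].
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "loocv_report"))
  jsonlite::write_json(
    list(metrics = list(ccr = report$ccr,
                        sensitivity = report$sensitivity,
                        specificity = report$specificity,
                        ccr_std = report$ccr_std,
                        sens_std = report$sens_std,
                        spec_std = report$spec_std,
                        n = report$n),
         config = unclass(report$config),
         per_fold = report$per_fold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize and restore a trained SVM model as JSON
#'
#' @param model an `"msa_svm"`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "msa_svm"))
  jsonlite::write_json(
    list(support_vectors = model$support_vectors,
         alphas = model$alphas,
         support_labels = model$support_labels,
         coefs = model$coefs,
         bias = model$bias,
         center = model$center,
         scale = model$scale,
         config = unclass(model$config),
         n_features = model$n_features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$support_vectors <- matrix(obj$support_vectors,
                                ncol = obj$n_features)
  obj$config <- svm_config(obj$config$degree, obj$config$C,
                           obj$config$standardize)
  structure(obj, class = "msa_svm")
}
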