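#' Serialize a report to JSON
#'
#' Full-precision values plus a `rounded` block for report rendering
#' (millimetres to 2 decimals, AUC-type quantities to 3).
#'
#' @param x An `agreement_report`, `roc_report`, `grid_search_result` or
#'   `doi_analysis_report`.
#' @param path Optional file path; when given, the JSON is written there.
#' @param ... Unused.
#' @return A JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(x, path = NULL, ...) UseMethod("report_to_json")

render_json <- function(lst, path) {
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE, dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

round_num <- function(lst, digits) {
  lapply(lst, function(v) if (is.numeric(v)) round(v, digits) else v)
}

#' @export
report_to_json.agreement_report <- function(x, path = NULL, ...) {
  core <- unclass(x)
  render_json(c(core, list(rounded = round_num(core, 2))), path)
}

#' @export
report_to_json.roc_report <- function(x, path = NULL, ...) {
  core <- unclass(x)
  rounded <- list(auc = round(x$auc, 3),
                  optimal_cutoff = round(x$optimal_cutoff, 2),
                  sens_at_cutoff = round(x$sens_at_cutoff, 3),
                  spec_at_cutoff = round(x$spec_at_cutoff, 3),
                  youden_j = round(x$youden_j, 3))
  render_json(c(core, list(rounded = rounded)), path)
}

#' @export
report_to_json.grid_search_result <- function(x, path = NULL, ...) {
  core <- unclass(x)
  core$logit_coefficients_at_best <- as.list(x$logit_coefficients_at_best)
  rounded <- list(best_threshold = round(x$best_threshold, 2),
                  best_auc = round(x$best_auc, 3),
                  auc_per_threshold = round(x$auc_per_threshold, 3))
  render_json(c(core, list(rounded = rounded)), path)
}

#' @export
report_to_json.doi_analysis_report <- function(x, path = NULL, ...) {
  strip <- function(obj) {
    if (inherits(obj, "cohort_summary")) return(unclass(obj))
    if (inherits(obj, c("agreement_report", "roc_report",
                        "grid_search_result"))) {
      return(unclass(obj))
    }
    obj
  }
  lst <- lapply(unclass(x), function(section) {
    if (is.list(section) && !is.data.frame(section) &&
        !inherits(section, c("cohort_summary", "agreement_report",
                             "roc_report", "grid_search_result"))) {
      lapply(section, strip)
    } else {
      strip(section)
    }
  })
  render_json(lst, path)
}
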