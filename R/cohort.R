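COHORT_COLUMNS <- c("patient_id", "p_doi_mm", "us_doi_mm", "mr_doi_mm",
                    "clnm", "c_t", "c_n", "c_stage")

#' Summarize a cohort, overall and by CLNM status
#'
#' Produces the usual baseline-characteristics table: for each categorical
#' variable, counts and percentages per level within the total cohort and
#' within each CLNM stratum (percentages of the stratum's non-missing
#' total, rounded to one decimal); for each continuous variable, median and
#' interquartile range.
#'
#' @param cohort A `doi_cohort` data frame (see [generate_cohort()]).
#' @return A list of class `"cohort_summary"` with elements `categorical`
#'   (data frame: `variable`, `level`, `stratum`, `n`, `percent`),
#'   `continuous` (data frame: `variable`, `stratum`, `n`, `median`, `q1`,
#'   `q3`) and `strata` (named stratum sizes).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("summarize_cohort: cohort is empty", call. = FALSE)

  strata <- list(total = rep(TRUE, nrow(cohort)))
  if ("clnm" %in% names(cohort) && any(!is.na(cohort$clnm))) {
    strata$clnm_negative <- !is.na(cohort$clnm) & cohort$clnm == 0
    strata$clnm_positive <- !is.na(cohort$clnm) & cohort$clnm == 1
  }

  cat_vars <- intersect(c("c_t", "c_n", "c_stage"), names(cohort))
  cat_vars <- cat_vars[vapply(cat_vars, function(v) any(!is.na(cohort[[v]])),
                              logical(1))]
  cont_vars <- intersect(c("p_doi_mm", "us_doi_mm", "mr_doi_mm"), names(cohort))

  cat_rows <- list()
  for (v in cat_vars) {
    levels_v <- sort(unique(cohort[[v]][!is.na(cohort[[v]])]))
    for (s in names(strata)) {
      x <- cohort[[v]][strata[[s]]]
      denom <- sum(!is.na(x))
      for (lv in levels_v) {
        n_lv <- sum(x == lv, na.rm = TRUE)
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          variable = v, level = lv, stratum = s, n = n_lv,
          percent = if (denom > 0) round(100 * n_lv / denom, 1) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }

  cont_rows <- list()
  for (v in cont_vars) {
    for (s in names(strata)) {
      x <- cohort[[v]][strata[[s]]]
      x <- x[!is.na(x)]
      q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
           else rep(NA_real_, 3)
      cont_rows[[length(cont_rows) + 1L]] <- data.frame(
        variable = v, stratum = s, n = length(x),
        median = q[2], q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
    }
  }

  structure(list(
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else
      data.frame(variable = character(), level = character(),
                 stratum = character(), n = integer(), percent = numeric()),
    continuous = do.call(rbind, cont_rows),
    strata = vapply(strata, sum, integer(1))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$strata[["total"]], ")\n", sep = "")
  if (length(x$strata) > 1L) {
    cat("  CLNM negative: ", x$strata[["clnm_negative"]],
        ", CLNM positive: ", x$strata[["clnm_positive"]], "\n", sep = "")
  }
  if (nrow(x$continuous)) {
    cat("Continuous (median [IQR]):\n")
    for (i in seq_len(nrow(x$continuous))) {
      r <- x$continuous[i, ]
      cat(sprintf("  %-10s %-14s %5.1f [%.1f-%.1f] (n=%d)\n",
                  r$variable, r$stratum, r$median, r$q1, r$q3, r$n))
    }
  }
  if (nrow(x$categorical)) {
    cat("Categorical (n, % of stratum):\n")
    for (i in seq_len(nrow(x$categorical))) {
      r <- x$categorical[i, ]
      cat(sprintf("  %-8s %-6s %-14s %3d (%.1f%%)\n",
                  r$variable, r$level, r$stratum, r$n, r$percent))
    }
  }
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Schema: `patient_id, p_doi_mm, us_doi_mm, mr_doi_mm, clnm, c_t, c_n,
#' c_stage`; missing values as empty fields, decimal point, UTF-8, LF.
#'
#' @param cohort A `doi_cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    stop("write_cohort_csv: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(cohort[COHORT_COLUMNS], con, row.names = FALSE,
                   na = "", eol = "\n", quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the schema of [write_cohort_csv()]: `p_doi_mm` and `clnm` are
#' required columns, empty cells become `NA`, malformed numeric or
#' non-binary CLNM entries are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A `doi_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_cohort_csv: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("p_doi_mm", "clnm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("read_cohort_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  clnm_chr <- raw$clnm
  bad_clnm <- which(!is.na(clnm_chr) & !clnm_chr %in% c("0", "1"))
  if (length(bad_clnm)) {
    stop("read_cohort_csv: non-binary clnm value(s) at row(s): ",
         paste(bad_clnm, collapse = ", "),
         " (", paste(unique(clnm_chr[bad_clnm]), collapse = ", "), ")",
         call. = FALSE)
  }
  parse_num <- function(col) {
    x <- raw[[col]]
    if (is.null(x)) return(rep(NA_real_, n))
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("read_cohort_csv: malformed numeric in column '", col,
           "' at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  p_doi <- parse_num("p_doi_mm")
  us_doi <- parse_num("us_doi_mm")
  mr_doi <- parse_num("mr_doi_mm")
  bad_pdoi <- which(is.na(p_doi))
  if (length(bad_pdoi)) {
    stop("read_cohort_csv: p_doi_mm missing at row(s): ",
         paste(bad_pdoi, collapse = ", "),
         " (pathology is the reference standard for every record)",
         call. = FALSE)
  }
  chr_col <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, n)
  }
  new_doi_cohort(data.frame(
    patient_id = if ("patient_id" %in% names(raw)) raw$patient_id
                 else sprintf("P%04d", seq_len(n)),
    p_doi_mm = p_doi,
    us_doi_mm = us_doi,
    mr_doi_mm = mr_doi,
    clnm = as.integer(clnm_chr),
    c_t = chr_col("c_t"),
    c_n = chr_col("c_n"),
    c_stage = chr_col("c_stage"),
    stringsAsFactors = FALSE
  ))
}
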