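#' Analysis configuration
#'
#' Bundles the inputs of [run_full_analysis()]: either a cohort CSV path or
#' generator parameters, the candidate percentile levels, the optimal-cutoff
#' criterion, an optional output directory and the seed.
#'
#' @param input Path to a cohort CSV (see [read_cohort_csv()]), or `NULL`
#'   to simulate.
#' @param params A [generator_params()] object used when `input` is `NULL`.
#' @param percentiles Strictly increasing integer levels in \[1, 99\].
#' @param criterion Cutoff criterion, `"youden"` or `"closest_topleft"`.
#' @param output_dir Optional directory; when set, the report JSON and the
#'   per-threshold / ROC-curve CSVs are written there.
#' @param seed Integer seed used when simulating.
#' @param verbose Emit progress messages.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(input = NULL, params = generator_params(),
                            percentiles = seq(10, 90, by = 10),
                            criterion = c("youden", "closest_topleft"),
                            output_dir = NULL, seed = 1L, verbose = FALSE) {
  criterion <- match.arg(criterion)
  if (length(percentiles) == 0L || anyNA(percentiles) ||
      any(percentiles < 1 | percentiles > 99) ||
      any(diff(percentiles) <= 0)) {
    stop("analysis_config: percentiles must be strictly increasing within [1, 99]",
         call. = FALSE)
  }
  if (!is.null(input) && (!is.character(input) || length(input) != 1L)) {
    stop("analysis_config: input must be NULL or a single file path",
         call. = FALSE)
  }
  structure(list(input = input, params = params, percentiles = percentiles,
                 criterion = criterion, output_dir = output_dir,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "analysis_config")
}

say <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

#' Run the full DOI analysis pipeline
#'
#' Orchestrates every stage on the appropriate subset of the cohort:
#' cohort summary (all records); correlation + Bland-Altman agreement for
#' usDOI and mrDOI against pDOI (pairwise-complete subsets); ROC analyses
#' of CLNM for usDOI, mrDOI and pDOI on their available subsets; the
#' switching-threshold grid search on the complete-case subset; and the
#' composite ROC at the selected threshold. Stages whose preconditions the
#' cohort cannot meet (e.g. an entirely missing modality) are skipped with
#' a warning naming the stage and subset size, so a partial cohort still
#' yields a partial report.
#'
#' @param config An [analysis_config()].
#' @return An object of class `"doi_analysis_report"`: `summary`,
#'   `agreement` (per modality), `roc` (usDOI, mrDOI, pDOI, composite),
#'   `grid_search`, `subset_sizes`, `provenance`.
#' @examples
#' rep <- run_full_analysis(analysis_config(seed = 3))
#' rep$subset_sizes
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (is.null(config$input)) {
    say(config, "simulating cohort (n = %d, seed = %s)",
        config$params$n_patients, format(config$seed))
    generate_cohort(config$params, seed = config$seed)
  } else {
    say(config, "reading cohort from %s", config$input)
    read_cohort_csv(config$input)
  }

  n_total <- nrow(cohort)
  has_us <- !is.na(cohort$us_doi_mm)
  has_mr <- !is.na(cohort$mr_doi_mm)
  has_pd <- !is.na(cohort$p_doi_mm)
  has_y <- !is.na(cohort$clnm)
  complete <- has_us & has_mr & has_pd & has_y
  subset_sizes <- c(n_total = n_total, n_us = sum(has_us & has_pd),
                    n_mr = sum(has_mr & has_pd), n_complete = sum(complete))
  say(config, "subsets: total %d, US %d, MRI %d, complete %d",
      subset_sizes[1], subset_sizes[2], subset_sizes[3], subset_sizes[4])

  run_stage <- function(stage, n, min_n, expr) {
    if (n < min_n) {
      warning(sprintf("stage '%s' skipped: subset size %d < %d",
                      stage, n, min_n), call. = FALSE)
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      warning(sprintf("stage '%s' failed on subset of %d: %s",
                      stage, n, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }

  idx_us <- has_us & has_pd
  idx_mr <- has_mr & has_pd
  agreement <- list(
    us = run_stage("agreement_us", sum(idx_us), 2, bland_altman(
      cohort$us_doi_mm[idx_us], cohort$p_doi_mm[idx_us])),
    mr = run_stage("agreement_mr", sum(idx_mr), 2, bland_altman(
      cohort$mr_doi_mm[idx_mr], cohort$p_doi_mm[idx_mr]))
  )

  roc_for <- function(stage, score, keep) {
    run_stage(stage, sum(keep & has_y), 2,
              roc_report(score[keep & has_y], cohort$clnm[keep & has_y],
                         criterion = config$criterion))
  }
  roc <- list(
    us = roc_for("roc_us", cohort$us_doi_mm, has_us),
    mr = roc_for("roc_mr", cohort$mr_doi_mm, has_mr),
    pd = roc_for("roc_pd", cohort$p_doi_mm, has_pd)
  )

  grid <- run_stage("grid_search", sum(complete), 4,
                    grid_search(cohort, config$percentiles))
  roc$composite <- if (!is.null(grid)) {
    sub <- cohort[complete, , drop = FALSE]
    comp <- compose_doi(sub$us_doi_mm, sub$mr_doi_mm, grid$best_threshold)
    run_stage("roc_composite", nrow(sub), 2,
              roc_report(comp, sub$clnm, criterion = config$criterion))
  } else NULL

  report <- structure(list(
    summary = summarize_cohort(cohort),
    agreement = agreement,
    roc = roc,
    grid_search = grid,
    subset_sizes = as.list(subset_sizes),
    provenance = list(
      package = "doifusion",
      version = as.character(utils::packageVersion("doifusion")),
      seed = config$seed,
      input = if (is.null(config$input)) "simulated" else config$input,
      percentiles = config$percentiles,
      criterion = config$criterion,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "doi_analysis_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    report_to_json(report, file.path(config$output_dir, "analysis_report.json"))
    if (!is.null(grid)) {
      write_grid_csv(grid, file.path(config$output_dir, "grid_search.csv"))
    }
    for (nm in names(roc)) {
      if (!is.null(roc[[nm]])) {
        write_roc_csv(roc[[nm]],
                      file.path(config$output_dir, paste0("roc_", nm, ".csv")))
      }
    }
    say(config, "report written to %s", config$output_dir)
  }
  report
}

#' @export
print.doi_analysis_report <- function(x, ...) {
  cat("DOI analysis report\n")
  s <- x$subset_sizes
  cat(sprintf("  Subsets: total %d | US %d | MRI %d | complete %d\n",
              s$n_total, s$n_us, s$n_mr, s$n_complete))
  for (nm in c("us", "mr")) {
    a <- x$agreement[[nm]]
    if (!is.null(a)) {
      cat(sprintf("  %sDOI vs pDOI: r = %.3f, bias %+0.2f mm, LoA [%.2f, %.2f]\n",
                  nm, a$pearson_r, a$bias, a$loa_low, a$loa_high))
    }
  }
  score_labels <- c(us = "usDOI:", mr = "mrDOI:", pd = "pDOI:",
                    composite = "us/mrDOI:")
  for (nm in names(score_labels)) {
    r <- x$roc[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  ROC %-9s AUC = %.3f, cutoff = %.2f mm\n",
                  score_labels[[nm]], r$auc, r$optimal_cutoff))
    }
  }
  if (!is.null(x$grid_search)) {
    cat(sprintf("  Grid search: best threshold %.2f mm (AUC %.3f, n = %d)\n",
                x$grid_search$best_threshold, x$grid_search$best_auc,
                x$grid_search$n_complete))
  }
  invisible(x)
}

#' Write the package's standard test fixtures
#'
#' Writes three CSV cohorts: the default calibrated cohort (n = 46), the
#' regime-shift stress cohort (n = 200, [regime_shift_params()]), and a
#' tiny eight-patient cohort whose ROC/AUC quantities are small enough to
#' verify by hand; alongside the tiny cohort an `tiny_expected.json` file
#' records its pathology-DOI AUC and composite values computed at the time
#' of writing.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the two simulated cohorts.
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20140901) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  default_cohort <- generate_cohort(generator_params(seed = seed))
  p1 <- file.path(dir, "cohort_default.csv")
  write_cohort_csv(default_cohort, p1)

  shift_cohort <- generate_cohort(regime_shift_params(seed = seed))
  p2 <- file.path(dir, "cohort_regime_shift.csv")
  write_cohort_csv(shift_cohort, p2)

  tiny <- tiny_cohort()
  p3 <- file.path(dir, "tiny_cohort.csv")
  write_cohort_csv(tiny, p3)

  expected <- list(
    auc_pdoi = auc(tiny$p_doi_mm, tiny$clnm),
    auc_usdoi = auc(tiny$us_doi_mm, tiny$clnm),
    composite_at_7 = compose_doi(tiny$us_doi_mm, tiny$mr_doi_mm, 7)
  )
  p4 <- file.path(dir, "tiny_expected.json")
  writeLines(jsonlite::toJSON(expected, auto_unbox = TRUE, digits = NA), p4)

  invisible(c(p1, p2, p3, p4))
}

# Eight hand-checkable records: depths chosen so that every pairwise score
# comparison is easy to enumerate, with one tied usDOI pair.
tiny_cohort <- function() {
  new_doi_cohort(data.frame(
    patient_id = sprintf("T%02d", 1:8),
    p_doi_mm = c(2, 3, 5, 6, 8, 9, 12, 15),
    us_doi_mm = c(2.5, 4, 5.5, 7, 9, 9, 10, 11),
    mr_doi_mm = c(4, 6, 7, 8, 11, 12, 15, 18),
    clnm = c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L),
    c_t = c("T1", "T1", "T2", "T2", "T3", "T3", "T4", "T4"),
    c_n = c("N0", "N0", "N0", "N1", "N0", "N1", "N2", "N2"),
    c_stage = c("I", "I", "II", "II", "III", "III", "IV", "IV"),
    stringsAsFactors = FALSE
  ))
}
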