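#' Composite us/mrDOI switching rule
#'
#' The composite biomarker uses the ultrasound reading where ultrasound is
#' trusted and switches to MRI beyond a depth threshold: it returns `us_doi`
#' when `us_doi <= threshold` and `mr_doi` when `us_doi > threshold`
#' (strict inequality, so a reading exactly at the threshold stays with
#' ultrasound).
#'
#' @param us_doi,mr_doi Ultrasound and MRI DOI (mm); vectors of equal
#'   length, no missing values (the composite is defined only on complete
#'   pairs).
#' @param threshold Switching threshold (mm).
#' @return Numeric vector of composite DOI values (mm).
#' @examples
#' compose_doi(c(5, 9, 7), c(8, 12, 10), threshold = 7)  # 5, 12, 7
#' @export
compose_doi <- function(us_doi, mr_doi, threshold) {
  if (length(us_doi) != length(mr_doi)) {
    stop("compose_doi: us_doi and mr_doi have different lengths", call. = FALSE)
  }
  if (anyNA(us_doi) || anyNA(mr_doi) ||
      !all(is.finite(us_doi)) || !all(is.finite(mr_doi))) {
    stop("compose_doi: missing or non-finite DOI value; ",
         "the composite is defined only on complete pairs", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("compose_doi: threshold must be a single number", call. = FALSE)
  }
  ifelse(us_doi <= threshold, us_doi, mr_doi)
}

#' Candidate switching thresholds from usDOI percentiles
#'
#' Sample percentiles of the observed ultrasound DOI distribution at the
#' requested levels (default: deciles 10, 20, ..., 90, giving nine
#' candidates on distinct data), deduplicated and sorted ascending. The
#' percentile definition defaults to linear interpolation between order
#' statistics ([stats::quantile()] type 7) and is configurable, since
#' printed threshold grids cannot adjudicate the convention without the raw
#' sample.
#'
#' @param us_values Non-empty numeric vector of usDOI values (mm).
#' @param percentiles Integer levels in \[1, 99\].
#' @param type Quantile definition passed to [stats::quantile()].
#' @return Sorted numeric vector of thresholds (mm).
#' @examples
#' candidate_thresholds(seq(10, 100, by = 10))  # 19 28 37 46 55 64 73 82 91
#' @export
candidate_thresholds <- function(us_values, percentiles = seq(10, 90, by = 10),
                                 type = 7) {
  if (length(us_values) == 0L) {
    stop("candidate_thresholds: us_values is empty", call. = FALSE)
  }
  if (anyNA(us_values)) {
    stop("candidate_thresholds: us_values contains missing values", call. = FALSE)
  }
  if (length(percentiles) == 0L || anyNA(percentiles) ||
      any(percentiles < 1 | percentiles > 99)) {
    stop("candidate_thresholds: percentiles must lie in [1, 99]", call. = FALSE)
  }
  q <- stats::quantile(us_values, sort(percentiles) / 100,
                       type = type, names = FALSE)
  sort(unique(q))
}

#' Univariable logistic regression of a binary outcome on a score
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' [stats::glm()] with a binomial family, tolerance 1e-10, at most 100
#' iterations). Complete separation — in the univariable case, exactly
#' non-overlapping class score ranges — is detected and flagged: the last
#' iterate is returned with `converged = FALSE` and a warning, since the
#' maximum-likelihood estimate is then at infinity.
#'
#' @param x Numeric predictor.
#' @param labels Binary 0/1 outcome; both classes present, n >= 4.
#' @return A list with `intercept`, `slope`, `converged`, `separated`, `n`.
#' @export
fit_logistic <- function(x, labels) {
  if (length(x) != length(labels)) {
    stop("fit_logistic: x and labels have different lengths", call. = FALSE)
  }
  if (anyNA(x) || anyNA(labels)) {
    stop("fit_logistic: missing values; subset to complete cases", call. = FALSE)
  }
  if (length(x) < 4L) {
    stop("fit_logistic: need at least 4 observations", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    stop("fit_logistic: labels must be binary with both classes present",
         call. = FALSE)
  }
  separated <- max(x[labels == 0]) < min(x[labels == 1]) ||
               max(x[labels == 1]) < min(x[labels == 0])
  fit <- suppressWarnings(
    stats::glm(labels ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  converged <- fit$converged && !separated
  if (separated) {
    warning("fit_logistic: complete separation detected; ",
            "the likelihood is monotone and coefficients diverge",
            call. = FALSE)
  }
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       converged = converged,
       separated = separated,
       n = length(x))
}

#' Grid search for the optimal us/mrDOI switching threshold
#'
#' For each candidate threshold (usDOI percentiles on the complete-case
#' subset), builds the composite score with [compose_doi()], fits a
#' univariable logistic model of CLNM on the composite, and evaluates the
#' AUC. The threshold with the maximum AUC is selected; ties are broken
#' toward the smallest threshold (keeping more patients on the
#' better-validated ultrasound regime).
#'
#' The AUC is computed from the composite score directly: it is invariant
#' to the monotone logit transform, so whenever the fitted slope is
#' positive this equals the AUC of the fitted probabilities (asserted
#' internally on every grid cell); the logistic fit is retained for its
#' coefficients. A non-positive slope at the selected threshold raises a
#' warning.
#'
#' Only complete cases (usDOI, mrDOI, pDOI, CLNM all present) enter the
#' analysis; no imputation is performed.
#'
#' @param cohort A `doi_cohort` data frame.
#' @param percentiles Candidate percentile levels (default deciles).
#' @param type Percentile convention, as in [candidate_thresholds()].
#' @return An object of class `"grid_search_result"`:
#'   `candidate_thresholds`, `auc_per_threshold`, `n_switched`,
#'   `best_threshold`, `best_auc`, `n_complete`,
#'   `logit_coefficients_at_best` (`intercept`, `slope`), `tie` (TRUE if
#'   the maximum AUC was attained at more than one threshold).
#' @export
grid_search <- function(cohort, percentiles = seq(10, 90, by = 10), type = 7) {
  stopifnot(is.data.frame(cohort))
  needed <- c("us_doi_mm", "mr_doi_mm", "p_doi_mm", "clnm")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("grid_search: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(cohort[needed])
  sub <- cohort[cc, , drop = FALSE]
  n_complete <- nrow(sub)
  if (n_complete < 4L) {
    stop("grid_search: insufficient complete cases (n_complete = ",
         n_complete, ", need >= 4)", call. = FALSE)
  }
  if (length(unique(sub$clnm)) < 2L) {
    stop("grid_search: only one CLNM class among the ", n_complete,
         " complete cases", call. = FALSE)
  }
  thresholds <- candidate_thresholds(sub$us_doi_mm, percentiles, type = type)
  k <- length(thresholds)
  auc_t <- numeric(k)
  n_switched <- integer(k)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    comp <- compose_doi(sub$us_doi_mm, sub$mr_doi_mm, thresholds[i])
    auc_t[i] <- auc(comp, sub$clnm)
    n_switched[i] <- sum(sub$us_doi_mm > thresholds[i])
    fits[[i]] <- suppressWarnings(fit_logistic(comp, sub$clnm))
    if (isTRUE(fits[[i]]$slope > 0)) {
      prob <- stats::plogis(fits[[i]]$intercept + fits[[i]]$slope * comp)
      stopifnot(abs(auc(prob, sub$clnm) - auc_t[i]) < 1e-9)
    }
  }
  best_idx <- which(auc_t == max(auc_t))
  tie <- length(best_idx) > 1L
  best_idx <- best_idx[1L]  # smallest threshold wins ties
  best_fit <- fits[[best_idx]]
  if (!isTRUE(best_fit$slope > 0)) {
    warning("grid_search: logistic slope at the selected threshold is not ",
            "positive; composite-score and fitted-probability AUCs may differ",
            call. = FALSE)
  }
  structure(list(
    candidate_thresholds = thresholds,
    auc_per_threshold = auc_t,
    n_switched = n_switched,
    best_threshold = thresholds[best_idx],
    best_auc = auc_t[best_idx],
    n_complete = n_complete,
    logit_coefficients_at_best = c(intercept = best_fit$intercept,
                                   slope = best_fit$slope),
    tie = tie
  ), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("us/mrDOI switching-threshold grid search (complete cases n =",
      x$n_complete, ")\n")
  tab <- data.frame(threshold_mm = round(x$candidate_thresholds, 2),
                    auc = round(x$auc_per_threshold, 3),
                    n_switched_to_mri = x$n_switched)
  print(tab, row.names = FALSE)
  cat(sprintf("  Best threshold: %.2f mm (AUC = %.3f)%s\n",
              x$best_threshold, x$best_auc,
              if (isTRUE(x$tie)) " [tie broken toward smallest]" else ""))
  invisible(x)
}

#' @export
plot.grid_search_result <- function(x, ...) {
  graphics::plot(x$candidate_thresholds, x$auc_per_threshold, type = "b",
                 xlab = "usDOI switching threshold (mm)", ylab = "AUC", ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

#' Write the per-threshold grid table to CSV
#'
#' @param result A [grid_search()] result.
#' @param path Output path; columns `threshold_mm`, `auc`,
#'   `n_switched_to_mri`.
#' @export
write_grid_csv <- function(result, path) {
  stopifnot(inherits(result, "grid_search_result"))
  utils::write.csv(
    data.frame(threshold_mm = result$candidate_thresholds,
               auc = result$auc_per_threshold,
               n_switched_to_mri = result$n_switched),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
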