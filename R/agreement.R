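#' Pearson correlation with significance test
#'
#' Sample product-moment correlation with the two-sided t-test on n - 2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each non-constant.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_with_test <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_with_test: input is constant; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y Numeric vectors, n >= 3, x non-constant.
#' @return A list with `slope`, `intercept`, `residual_sd`, `n`.
#' @export
linear_fit <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  if (stats::sd(x) == 0) {
    stop("linear_fit: x is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary() warns on exact fits; residual_sd = 0 is a legitimate result
  s <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = s$sigma,
       n = length(x))
}

check_paired <- function(x, y, min_n = 2L) {
  if (length(x) != length(y)) {
    stop("paired vectors have different lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("paired vectors contain missing values; subset to complete pairs first",
         call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("need at least ", min_n, " pairs, got ", length(x), call. = FALSE)
  }
  invisible(TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between an imaging DOI and the pathological
#' reference. Differences are oriented as imaging minus pathology, so a
#' positive bias means the imaging modality overestimates depth. The limits
#' of agreement use the conventional 1.96 multiplier on the sample SD of
#' the differences (denominator n - 1). Proportional bias — systematic
#' dependence of the difference on depth — is assessed by OLS of the
#' differences on the pairwise means; a significantly negative slope
#' operationalizes depth-dependent underestimation.
#'
#' Pearson correlation and the regression of measure on reference are
#' included in the report when computable (n >= 3, non-constant inputs) and
#' are `NA` otherwise.
#'
#' @param measure Imaging DOI values (mm).
#' @param reference Pathological DOI values (mm), same length, n >= 2.
#' @return An object of class `"agreement_report"`: `n_pairs`, `pearson_r`,
#'   `r_p_value`, `slope`, `intercept`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `prop_bias_slope`, `prop_bias_p`, `prop_bias_available`.
#' @examples
#' set.seed(7)
#' pd <- rlnorm(50, log(8), 0.5)
#' us <- pd + 0.88 + rnorm(50, 0, 1.59)
#' bland_altman(us, pd)
#' @export
bland_altman <- function(measure, reference) {
  check_paired(measure, reference, min_n = 2L)
  n <- length(measure)
  d <- measure - reference
  m <- (measure + reference) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff

  can_corr <- n >= 3L && stats::sd(measure) > 0 && stats::sd(reference) > 0
  pr <- if (can_corr) pearson_with_test(measure, reference) else
    list(r = NA_real_, p_value = NA_real_)
  lf <- if (n >= 3L && stats::sd(reference) > 0)
    linear_fit(reference, measure) else
    list(slope = NA_real_, intercept = NA_real_)

  prop_available <- n >= 3L && stats::sd(m) > 0
  if (prop_available) {
    pb <- prop_bias_ols(d, m)
  } else {
    pb <- list(slope = NA_real_, p_value = NA_real_)
  }

  structure(list(
    n_pairs = n,
    pearson_r = pr$r, r_p_value = pr$p_value,
    slope = lf$slope, intercept = lf$intercept,
    bias = bias, sd_diff = sd_diff,
    loa_low = loa_low, loa_high = loa_high,
    prop_bias_slope = pb$slope, prop_bias_p = pb$p_value,
    prop_bias_available = prop_available
  ), class = "agreement_report")
}

prop_bias_ols <- function(d, m) {
  fit <- stats::lm(d ~ m)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  # residual variance 0 (e.g. constant differences) => t undefined, not 0/0
  p <- if (nrow(sm$coefficients) == 2 && is.finite(sm$coefficients[2, 4]) &&
           sm$sigma > 0) sm$coefficients[2, 4] else NA_real_
  list(slope = slope, p_value = p)
}

#' Proportional-bias test
#'
#' OLS slope of the paired differences (measure - reference) on the
#' pairwise means, with its two-sided t-test p-value. Standard extension of
#' the Bland-Altman analysis for magnitude-dependent bias.
#'
#' @inheritParams bland_altman
#' @return A list with `slope`, `p_value`, `n`.
#' @export
proportional_bias_test <- function(measure, reference) {
  check_paired(measure, reference, min_n = 3L)
  m <- (measure + reference) / 2
  if (stats::sd(m) == 0) {
    stop("proportional_bias_test: pairwise means are constant", call. = FALSE)
  }
  pb <- prop_bias_ols(measure - reference, m)
  list(slope = pb$slope, p_value = pb$p_value, n = length(measure))
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement analysis (imaging - pathology), n =", x$n_pairs, "pairs\n")
  cat(sprintf("  Pearson r: %s (p = %s)\n",
              format(round(x$pearson_r, digits)),
              format.pval(x$r_p_value, digits = 2)))
  cat(sprintf("  Regression (measure on reference): slope %.3f, intercept %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  Bias: %+.2f mm (SD %.2f), 95%% LoA [%.2f, %.2f] mm\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  if (isTRUE(x$prop_bias_available)) {
    cat(sprintf("  Proportional bias: slope %+.3f per mm (p = %s)\n",
                x$prop_bias_slope, format.pval(x$prop_bias_p, digits = 2)))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pairwise means with the bias and limit-of-agreement
#' lines.
#'
#' @param measure,reference As in [bland_altman()].
#' @param report Optionally a precomputed [bland_altman()] report.
#' @param ... Passed to [graphics::plot()].
#' @return The report, invisibly.
#' @export
plot_bland_altman <- function(measure, reference,
                              report = bland_altman(measure, reference), ...) {
  d <- measure - reference
  m <- (measure + reference) / 2
  graphics::plot(m, d, xlab = "Mean of measure and reference (mm)",
                 ylab = "Difference, measure - reference (mm)", ...)
  graphics::abline(h = report$bias, lty = 1)
  graphics::abline(h = c(report$loa_low, report$loa_high), lty = 2)
  invisible(report)
}
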