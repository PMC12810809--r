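check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels have different lengths", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores/labels contain missing values; subset first", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ")", call. = FALSE)
  }
  c(n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve points
#'
#' One point per distinct score threshold (decision rule: score >= threshold
#' predicts positive) plus the (0, 0) anchor at threshold `Inf`. Tied scores
#' share a single threshold point. The curve therefore starts at (0, 0) and
#' ends at (1, 1), with FPR and TPR non-decreasing.
#'
#' @param scores Numeric vector; higher values indicate the positive class.
#' @param labels Binary 0/1 vector.
#' @return A data frame with columns `threshold`, `fpr`, `tpr`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_curve <- function(scores, labels) {
  counts <- check_scores_labels(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  # counts of class members at each distinct score, accumulated downward
  tp <- cumsum(vapply(thr, function(t) sum(pos == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(neg == t), numeric(1)))
  data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fp / counts["n_neg"]),
    tpr = c(0, tp / counts["n_pos"])
  )
}

#' Area under the ROC curve (Mann-Whitney estimate)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties credited 0.5 — computed from midranks, so it
#' is exactly the Mann-Whitney U statistic scaled to \[0, 1\]. Identical to
#' the trapezoidal area under [roc_curve()] up to floating-point error.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 2, 2, 3), c(0, 1, 0, 1))  # 0.875
#' @export
auc <- function(scores, labels) {
  counts <- check_scores_labels(scores, labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- counts[["n_pos"]]
  n_neg <- counts[["n_neg"]]
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (as.numeric(n_pos) * n_neg)
}

#' Trapezoidal area under a ROC curve
#'
#' Independent geometric route to the AUC, integrating the curve returned
#' by [roc_curve()] with the trapezoidal rule.
#'
#' @param curve A data frame from [roc_curve()] (columns `fpr`, `tpr`).
#' @return Area in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("fpr", "tpr") %in% names(curve)))
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Optimal cutoff on a ROC curve
#'
#' Selects the decision threshold maximizing Youden's J (sensitivity +
#' specificity - 1), the near-universal default in clinical ROC reporting;
#' `criterion = "closest_topleft"` minimizes the squared distance to the
#' (0, 1) corner instead. Ties are broken toward the higher threshold
#' (fewer test-positives). The reported cutoff is placed at the midpoint
#' between the selected observed score and the next lower distinct score
#' when one exists (matching common statistical-package behavior, which is
#' why reported cutoffs need not be observed values), else at the observed
#' score itself.
#'
#' @inheritParams roc_curve
#' @param criterion `"youden"` (default) or `"closest_topleft"`.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `threshold_score` (the observed score defining the decision rule).
#' @export
youden_cutoff <- function(scores, labels, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  curve <- roc_curve(scores, labels)
  cand <- curve[is.finite(curve$threshold), , drop = FALSE]
  obj <- switch(criterion,
    youden = cand$tpr - cand$fpr,
    closest_topleft = -((1 - cand$tpr)^2 + cand$fpr^2)
  )
  # ties toward the higher threshold = earliest row (thresholds descend)
  best <- which(obj == max(obj))[1L]
  thr <- cand$threshold[best]
  distinct <- sort(unique(scores))
  pos_in <- match(thr, distinct)
  cutoff <- if (!is.na(pos_in) && pos_in > 1L) {
    (distinct[pos_in] + distinct[pos_in - 1L]) / 2
  } else {
    thr
  }
  list(cutoff = cutoff,
       sensitivity = cand$tpr[best],
       specificity = 1 - cand$fpr[best],
       youden_j = cand$tpr[best] - cand$fpr[best],
       threshold_score = thr)
}

#' Full ROC report for a continuous score
#'
#' Bundles the ROC curve, the area under it (trapezoidal, with the
#' Mann-Whitney estimate agreeing to numerical precision), and the optimal
#' cutoff with its sensitivity/specificity.
#'
#' @inheritParams youden_cutoff
#' @return An object of class `"roc_report"`: `n_pos`, `n_neg`, `auc`,
#'   `curve`, `optimal_cutoff`, `sens_at_cutoff`, `spec_at_cutoff`,
#'   `youden_j`, `criterion`.
#' @examples
#' set.seed(1)
#' rep <- roc_report(rnorm(40) + rep(0:1, each = 20), rep(0:1, each = 20))
#' rep$auc
#' @export
roc_report <- function(scores, labels, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  counts <- check_scores_labels(scores, labels)
  curve <- roc_curve(scores, labels)
  cut <- youden_cutoff(scores, labels, criterion)
  structure(list(
    n_pos = counts[["n_pos"]],
    n_neg = counts[["n_neg"]],
    auc = auc_trapezoid(curve),
    curve = curve,
    optimal_cutoff = cut$cutoff,
    sens_at_cutoff = cut$sensitivity,
    spec_at_cutoff = cut$specificity,
    youden_j = cut$sensitivity + cut$specificity - 1,
    criterion = criterion
  ), class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC analysis: %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %.3f\n", x$auc))
  cat(sprintf("  Optimal cutoff (%s): %.2f mm (sens %.3f, spec %.3f, J = %.3f)\n",
              x$criterion, x$optimal_cutoff, x$sens_at_cutoff,
              x$spec_at_cutoff, x$youden_j))
  invisible(x)
}

#' @export
plot.roc_report <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write ROC curve points to CSV
#'
#' @param report A [roc_report()] object.
#' @param path Output path; columns `fpr`, `tpr`, `threshold`.
#' @export
write_roc_csv <- function(report, path) {
  stopifnot(inherits(report, "roc_report"))
  utils::write.csv(report$curve[, c("fpr", "tpr", "threshold")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
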