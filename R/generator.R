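#' Parameters of the synthetic TSCC cohort generator
#'
#' Full parameterization of the measurement-error / outcome / missingness
#' model used by [generate_cohort()]. The defaults are calibrated to the
#' structure of a 46-patient tongue-cancer cohort: ultrasound DOI (usDOI)
#' overestimates pathology by about +0.88 mm (SD 1.59 mm) for shallow tumors
#' but drifts toward underestimation beyond a 10 mm regime-change depth,
#' encoded as a piecewise-linear bias with a single knot; MRI DOI (mrDOI)
#' overestimates by about +2.43 mm (SD 2.39 mm) at all depths. Cervical
#' lymph-node metastasis (CLNM) follows a logistic model in pDOI calibrated
#' to ~43% prevalence, and ultrasound availability follows a logistic model
#' with negative depth slope (US is preferentially performed for tumors
#' presumed shallow), calibrated to ~52% marginal availability; MRI is
#' missing completely at random at ~4%.
#'
#' @param n_patients Number of records to generate.
#' @param pdoi_dist A [doi_dist()] with support on (0, Inf) for the true
#'   pathological depth, in mm. Default: lognormal with median 8 mm and
#'   quartiles near 4 and 15 mm.
#' @param us_bias_shallow Mean of usDOI - pDOI (mm) at or below the knot.
#' @param us_bias_deep_slope Additional bias per mm of depth beyond the
#'   knot; negative values encode progressive underestimation.
#' @param us_knot_mm Regime-change depth (mm).
#' @param us_sd SD of the ultrasound residual error (mm), > 0.
#' @param mr_bias Mean of mrDOI - pDOI (mm), depth-independent.
#' @param mr_sd SD of the MRI residual error (mm), > 0.
#' @param clnm_beta0,clnm_beta1 Intercept and per-mm slope of the logistic
#'   model of CLNM on pDOI.
#' @param us_avail_beta0,us_avail_beta1 Logistic model of ultrasound
#'   availability on pDOI; a negative slope encodes preferential US use for
#'   shallow tumors.
#' @param mr_avail_prob Marginal probability that mrDOI is available.
#' @param seed Integer seed; identical parameters and seed give identical
#'   cohorts.
#'
#' @return An object of class `"generator_params"`.
#' @seealso [generate_cohort()], [regime_shift_params()]
#' @export
generator_params <- function(n_patients = 46L,
                             pdoi_dist = doi_dist("lognormal",
                                                  meanlog = log(8), sdlog = 0.95),
                             us_bias_shallow = 0.88,
                             us_bias_deep_slope = -0.5,
                             us_knot_mm = 10,
                             us_sd = 1.59,
                             mr_bias = 2.43,
                             mr_sd = 2.39,
                             clnm_beta0 = -1.39,
                             clnm_beta1 = 0.10,
                             us_avail_beta0 = 2.50,
                             us_avail_beta1 = -0.25,
                             mr_avail_prob = 44 / 46,
                             seed = 1L) {
  p <- list(n_patients = n_patients, pdoi_dist = pdoi_dist,
            us_bias_shallow = us_bias_shallow,
            us_bias_deep_slope = us_bias_deep_slope,
            us_knot_mm = us_knot_mm, us_sd = us_sd,
            mr_bias = mr_bias, mr_sd = mr_sd,
            clnm_beta0 = clnm_beta0, clnm_beta1 = clnm_beta1,
            us_avail_beta0 = us_avail_beta0, us_avail_beta1 = us_avail_beta1,
            mr_avail_prob = mr_avail_prob, seed = seed)
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  bad <- function(field, why) {
    stop("generator_params: invalid field '", field, "': ", why, call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  if (!is.numeric(p$n_patients) || length(p$n_patients) != 1L ||
      is.na(p$n_patients) || p$n_patients < 1 ||
      p$n_patients != round(p$n_patients)) {
    bad("n_patients", "must be a whole number >= 1")
  }
  if (!inherits(p$pdoi_dist, "doi_dist")) bad("pdoi_dist", "must be a doi_dist")
  if (!has_positive_support(p$pdoi_dist)) {
    bad("pdoi_dist", "must have support on (0, Inf) (lognormal or gamma)")
  }
  for (f in c("us_bias_shallow", "us_bias_deep_slope", "us_knot_mm",
              "mr_bias", "clnm_beta0", "clnm_beta1",
              "us_avail_beta0", "us_avail_beta1")) num1(f)
  if (num1("us_sd") <= 0) bad("us_sd", "must be > 0")
  if (num1("mr_sd") <= 0) bad("mr_sd", "must be > 0")
  mp <- num1("mr_avail_prob")
  if (mp < 0 || mp > 1) bad("mr_avail_prob", "must be in [0, 1]")
  if (!is.numeric(p$seed) || length(p$seed) != 1L || is.na(p$seed)) {
    bad("seed", "must be a single integer")
  }
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params> n =", x$n_patients, "\n")
  cat("  pDOI marginal: "); print(x$pdoi_dist)
  cat(sprintf("  US error:  bias %+0.2f mm (<= knot %.1f mm), deep slope %+0.2f/mm, SD %.2f mm\n",
              x$us_bias_shallow, x$us_knot_mm, x$us_bias_deep_slope, x$us_sd))
  cat(sprintf("  MRI error: bias %+0.2f mm, SD %.2f mm\n", x$mr_bias, x$mr_sd))
  cat(sprintf("  CLNM logit: %+0.2f %+0.3f * pDOI\n", x$clnm_beta0, x$clnm_beta1))
  cat(sprintf("  US availability logit: %+0.2f %+0.3f * pDOI; MRI availability %.3f\n",
              x$us_avail_beta0, x$us_avail_beta1, x$mr_avail_prob))
  invisible(x)
}

#' Regime-shift scenario parameters
#'
#' A stress scenario for threshold-recovery studies: ultrasound is very
#' precise for shallow tumors (SD 0.6 mm) but nearly depth-blind beyond the
#' 10 mm knot (deep slope -0.95, i.e. the reading gains only 0.05 mm per mm
#' of true depth), while MRI is uniformly noisy (SD 3.0 mm) but keeps the
#' full depth signal. CLNM depends on depth steeply enough (0.25 per mm)
#' that AUC differences between switching thresholds are detectable at
#' n = 200. Both modalities are fully available so the grid search sees
#' every record.
#'
#' @param n_patients Number of records (default 200).
#' @param seed Integer seed.
#' @return A `"generator_params"` object.
#' @export
regime_shift_params <- function(n_patients = 200L, seed = 1L) {
  generator_params(
    n_patients = n_patients,
    us_bias_deep_slope = -0.95,
    us_sd = 0.6,
    mr_sd = 3.0,
    clnm_beta0 = -2.85,
    clnm_beta1 = 0.25,
    us_avail_beta0 = 50, us_avail_beta1 = 0,
    mr_avail_prob = 1,
    seed = seed
  )
}

# One sub-seed per field stream, derived once from the root seed, so that
# adding a downstream field never perturbs earlier draws.
# Order: pDOI, US noise, MRI noise, CLNM, missingness.
derive_subseeds <- function(seed, k = 5L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, k)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

new_doi_cohort <- function(df) {
  class(df) <- c("doi_cohort", "data.frame")
  df
}

#' Generate a synthetic DOI cohort
#'
#' Draws `n_patients` records from the piecewise measurement-error model:
#' \deqn{usDOI = pDOI + b_{US} + s \cdot \max(0, pDOI - knot) + N(0, \sigma_{US})}
#' \deqn{mrDOI = pDOI + b_{MRI} + N(0, \sigma_{MRI})}
#' with imaging values truncated at 0, CLNM drawn from a logistic model in
#' pDOI, usDOI set missing with probability
#' `1 - plogis(us_avail_beta0 + us_avail_beta1 * pDOI)` and mrDOI missing
#' with probability `1 - mr_avail_prob`.
#'
#' @param params A [generator_params()] object.
#' @param seed Optional override of `params$seed`.
#' @return A `doi_cohort` data frame with columns `patient_id`, `p_doi_mm`,
#'   `us_doi_mm`, `mr_doi_mm`, `clnm`, `c_t`, `c_n`, `c_stage`. Missing
#'   imaging values are `NA`; `c_*` columns are `NA` for generated cohorts.
#' @examples
#' cohort <- generate_cohort(generator_params(seed = 42))
#' summary(cohort$p_doi_mm)
#' @export
generate_cohort <- function(params, seed = params$seed) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, params)
  }
  validate_generator_params(params)
  n <- as.integer(params$n_patients)
  ss <- derive_subseeds(seed)

  p_doi <- with_seed(ss[1], r_doi_dist(params$pdoi_dist, n))
  us_noise <- with_seed(ss[2], stats::rnorm(n, 0, params$us_sd))
  mr_noise <- with_seed(ss[3], stats::rnorm(n, 0, params$mr_sd))
  clnm_u <- with_seed(ss[4], stats::runif(n))
  miss_u <- with_seed(ss[5], list(us = stats::runif(n), mr = stats::runif(n)))

  us_doi <- pmax(0, p_doi + params$us_bias_shallow +
                   params$us_bias_deep_slope * pmax(0, p_doi - params$us_knot_mm) +
                   us_noise)
  mr_doi <- pmax(0, p_doi + params$mr_bias + mr_noise)
  clnm <- as.integer(clnm_u < stats::plogis(params$clnm_beta0 +
                                              params$clnm_beta1 * p_doi))
  us_avail <- miss_u$us < stats::plogis(params$us_avail_beta0 +
                                          params$us_avail_beta1 * p_doi)
  mr_avail <- miss_u$mr < params$mr_avail_prob
  us_doi[!us_avail] <- NA_real_
  mr_doi[!mr_avail] <- NA_real_

  new_doi_cohort(data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    p_doi_mm = p_doi,
    us_doi_mm = us_doi,
    mr_doi_mm = mr_doi,
    clnm = clnm,
    c_t = NA_character_,
    c_n = NA_character_,
    c_stage = NA_character_,
    stringsAsFactors = FALSE
  ))
}

#' Generate a cohort from a Gaussian copula
#'
#' Alternative generator that targets the pairwise correlations between
#' imaging and pathological DOI directly: a trivariate standard normal
#' latent vector with correlations `r_us` (usDOI-pDOI), `r_mr` (mrDOI-pDOI)
#' and `r_us_mr` (usDOI-mrDOI, by default imputed as `r_us * r_mr`) is
#' mapped through the probability integral transform onto the requested
#' depth marginal; the imaging coordinates then receive their additive
#' biases. With a normal marginal the latent correlation is exactly the
#' Pearson correlation of the output.
#'
#' @param n Number of records.
#' @param r_us,r_mr Latent correlations, each strictly inside (-1, 1).
#' @param pdoi_dist A [doi_dist()]; `"normal"` is allowed here (draws are
#'   truncated at 0).
#' @param r_us_mr Latent usDOI-mrDOI correlation. The default `r_us * r_mr`
#'   always yields a positive semidefinite correlation matrix; other values
#'   may not, in which case an error is raised.
#' @param us_bias,mr_bias Additive offsets (mm) applied to the imaging
#'   coordinates; they shift locations without changing correlations.
#' @param seed Integer seed.
#' @return A `doi_cohort` data frame (all modalities fully observed; CLNM
#'   drawn from the default depth logistic so records are complete).
#' @export
generate_copula_cohort <- function(n, r_us, r_mr,
                                   pdoi_dist = doi_dist("lognormal",
                                                        meanlog = log(8),
                                                        sdlog = 0.95),
                                   r_us_mr = r_us * r_mr,
                                   us_bias = 0.88, mr_bias = 2.43,
                                   seed = 1L) {
  for (nm in c("r_us", "r_mr")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) >= 1) {
      stop("generate_copula_cohort: '", nm,
           "' must lie strictly inside (-1, 1)", call. = FALSE)
    }
  }
  if (!inherits(pdoi_dist, "doi_dist")) {
    stop("generate_copula_cohort: 'pdoi_dist' must be a doi_dist", call. = FALSE)
  }
  R <- matrix(c(1, r_us, r_mr,
                r_us, 1, r_us_mr,
                r_mr, r_us_mr, 1), 3, 3)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stop("generate_copula_cohort: correlation matrix with r_us_mr = ",
         signif(r_us_mr, 4), " is not positive semidefinite", call. = FALSE)
  }
  ss <- derive_subseeds(seed, 2L)
  z <- with_seed(ss[1], matrix(stats::rnorm(3 * n), n, 3)) %*% ch
  u <- stats::pnorm(z)
  p_doi <- pmax(0, q_doi_dist(pdoi_dist, u[, 1]))
  us_doi <- pmax(0, q_doi_dist(pdoi_dist, u[, 2]) + us_bias)
  mr_doi <- pmax(0, q_doi_dist(pdoi_dist, u[, 3]) + mr_bias)
  clnm_u <- with_seed(ss[2], stats::runif(n))
  clnm <- as.integer(clnm_u < stats::plogis(-1.39 + 0.10 * p_doi))

  new_doi_cohort(data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    p_doi_mm = p_doi,
    us_doi_mm = us_doi,
    mr_doi_mm = mr_doi,
    clnm = clnm,
    c_t = NA_character_,
    c_n = NA_character_,
    c_stage = NA_character_,
    stringsAsFactors = FALSE
  ))
}
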