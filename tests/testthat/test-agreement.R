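test_that("pearson_with_test matches independent formulas and handles edge cases", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  got <- pearson_with_test(x, y)
  expect_equal(got$r, pearson_definition(x, y), tolerance = 1e-12)
  expect_equal(got$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)

  z <- c(0.3, 1.7, 2, 5, 9)
  expect_equal(pearson_with_test(z, z)$r, 1)
  expect_lt(pearson_with_test(z, z)$p_value, 1e-10)
  expect_equal(pearson_with_test(z, -z)$r, -1)

  expect_error(pearson_with_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_with_test(1:4, 1:5), "length")
})

test_that("linear_fit is exact OLS", {
  x <- c(0.4, 1.1, 2.2, 3.8, 5.0)
  expect_equal(linear_fit(x, 2 * x + 1),
               list(slope = 2, intercept = 1, residual_sd = 0, n = 5L),
               tolerance = 1e-12)

  set.seed(21)
  xf <- rnorm(10)
  yf <- 1.5 + 0.7 * xf + rnorm(10)
  got <- linear_fit(xf, yf)
  oracle <- ols_normal_equations(xf, yf)
  expect_equal(got$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(got$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  # slope * sd(x) / sd(y) == r
  expect_equal(got$slope * sd(xf) / sd(yf), pearson_with_test(xf, yf)$r,
               tolerance = 1e-10)
  # centered data => intercept is the mean of y
  xc <- xf - mean(xf)
  expect_equal(linear_fit(xc, yf)$intercept, mean(yf), tolerance = 1e-10)
  expect_error(linear_fit(rep(2, 5), rnorm(5)), "constant")
})

test_that("bland_altman on constant-offset and identity fixtures", {
  ref <- c(3, 5, 8, 11, 14)
  ba <- bland_altman(ref + 2, ref)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(2, 2))
  expect_equal(ba$prop_bias_slope, 0)

  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  expect_error(bland_altman(1, 1), "at least 2")
  two <- bland_altman(c(3, 5), c(2, 5))
  expect_false(two$prop_bias_available)
  expect_true(is.na(two$prop_bias_slope))
})

test_that("agreement statistics match textbook formulas on a small fixture", {
  set.seed(31)
  ref <- rlnorm(12, log(8), 0.6)
  mea <- ref + 0.9 + rnorm(12, 0, 1.5)
  ba <- bland_altman(mea, ref)
  d <- mea - ref
  m <- (mea + ref) / 2
  expect_equal(ba$n_pairs, 12L)
  expect_equal(ba$bias, sum(d) / 12, tolerance = 1e-10)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 11), tolerance = 1e-10)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba$pearson_r, pearson_definition(mea, ref), tolerance = 1e-10)
  nb <- ols_normal_equations(m, d)
  expect_equal(ba$prop_bias_slope, unname(nb["slope"]), tolerance = 1e-10)
  nr <- ols_normal_equations(ref, mea)
  expect_equal(ba$slope, unname(nr["slope"]), tolerance = 1e-10)
  expect_equal(ba$intercept, unname(nr["intercept"]), tolerance = 1e-10)
})

test_that("translation invariances of the agreement statistics", {
  set.seed(32)
  ref <- rlnorm(30, log(8), 0.7)
  mea <- ref + 0.5 + rnorm(30, 0, 1.2)
  base <- bland_altman(mea, ref)
  for (c0 in c(-3, 4.5)) {
    both <- bland_altman(mea + c0, ref + c0)
    expect_equal(both$pearson_r, base$pearson_r, tolerance = 1e-10)
    expect_equal(both$sd_diff, base$sd_diff, tolerance = 1e-10)
    expect_equal(both$prop_bias_slope, base$prop_bias_slope, tolerance = 1e-10)
    expect_equal(both$bias, base$bias, tolerance = 1e-10)
    expect_equal(both$loa_low, base$loa_low, tolerance = 1e-10)

    shifted <- bland_altman(mea + c0, ref)
    expect_equal(shifted$bias, base$bias + c0, tolerance = 1e-8)
    expect_equal(shifted$loa_high, base$loa_high + c0, tolerance = 1e-8)
  }
})

test_that("bland_altman recovers a simulated bias/SD at large n", {
  p <- generator_params(n_patients = 20000, us_bias_deep_slope = 0,
                        us_avail_beta0 = 50, us_avail_beta1 = 0,
                        mr_avail_prob = 1, seed = 17)
  co <- generate_cohort(p)
  ba <- bland_altman(co$us_doi_mm, co$p_doi_mm)
  expect_lt(abs(ba$bias - 0.88), 3 * 1.59 / sqrt(20000))
  expect_lt(abs(ba$sd_diff - 1.59), 3 * 1.59 / sqrt(2 * 20000))
})

test_that("proportional-bias test detects the deep-regime underestimation", {
  # A deep, wide marginal with small US noise keeps two artifacts far
  # below detection in the zero-slope case: truncation at 0 (inactive) and
  # the regression-to-the-mean term of difference-on-mean regression,
  # whose expectation is sigma^2 / (2 var(mean)) when only the measure
  # carries noise.
  make <- function(slope, seed) {
    p <- generator_params(n_patients = 4000, us_bias_deep_slope = slope,
                          pdoi_dist = doi_dist("lognormal", log(10), 0.95),
                          us_sd = 0.5,
                          us_knot_mm = 10, us_avail_beta0 = 50,
                          us_avail_beta1 = 0, mr_avail_prob = 1, seed = seed)
    generate_cohort(p)
  }
  co <- make(-0.3, 23)
  pb <- proportional_bias_test(co$us_doi_mm, co$p_doi_mm)
  expect_lt(pb$slope, 0)
  expect_lt(pb$p_value, 0.01)

  co0 <- make(0, 24)
  pb0 <- proportional_bias_test(co0$us_doi_mm, co0$p_doi_mm)
  # null case: slope within 3 SEs of zero
  fit <- lm(I(co0$us_doi_mm - co0$p_doi_mm) ~ I((co0$us_doi_mm + co0$p_doi_mm) / 2))
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(pb0$slope), 3 * se)

  expect_error(proportional_bias_test(c(2, 2, 2), c(2, 2, 2)), "constant")
})
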