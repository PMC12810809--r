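test_that("composite switching rule, including the boundary", {
  expect_equal(compose_doi(5, 8, 7), 5)
  expect_equal(compose_doi(9, 12, 7), 12)
  expect_equal(compose_doi(7, 10, 7), 7)  # strict '>': boundary stays with US
  expect_equal(compose_doi(c(5, 9, 7), c(8, 12, 10), 7), c(5, 12, 7))
  expect_error(compose_doi(NA, 8, 7), "complete pairs")
  expect_error(compose_doi(5, Inf, 7), "complete pairs")
  expect_error(compose_doi(1:3, 1:2, 7), "lengths")
})

test_that("candidate thresholds follow the interpolated percentile convention", {
  expect_equal(candidate_thresholds(seq(10, 100, by = 10)),
               c(19, 28, 37, 46, 55, 64, 73, 82, 91))
  # deciles of a continuous sample: exactly nine candidates
  set.seed(51)
  expect_length(candidate_thresholds(rlnorm(22, log(8), 0.9)), 9L)
  expect_equal(candidate_thresholds(rep(4.2, 10)), 4.2)
  expect_error(candidate_thresholds(numeric(0)), "empty")
  expect_error(candidate_thresholds(1:10, percentiles = c(0, 50)), "\\[1, 99\\]")
})

test_that("logistic fit satisfies the score identity and flags separation", {
  set.seed(52)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(-0.4 + 0.8 * x))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  p_hat <- plogis(fit$intercept + fit$slope * x)
  expect_lt(abs(sum(p_hat) - sum(y)), 1e-6)

  # null fixture: slope within 3 SEs of 0, intercept near logit(prevalence)
  y0 <- rep(c(0, 1), 30)
  fit0 <- fit_logistic(x, y0)
  g <- glm(y0 ~ x, family = binomial())
  expect_lt(abs(fit0$slope), 3 * summary(g)$coefficients[2, 2])
  expect_lt(abs(fit0$intercept - qlogis(mean(y0))), 0.5)

  # complete separation
  xs <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ys <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_warning(sep <- fit_logistic(xs, ys), "separation")
  expect_false(sep$converged)
  expect_true(sep$separated)

  expect_error(fit_logistic(1:8, rep(1, 8)), "both classes")
})

test_that("grid endpoints degenerate to the single-modality AUCs", {
  set.seed(53)
  co <- generate_cohort(regime_shift_params(n_patients = 80, seed = 53))
  cc <- complete.cases(co[c("us_doi_mm", "mr_doi_mm", "p_doi_mm", "clnm")])
  sub <- co[cc, ]
  auc_us <- auc(sub$us_doi_mm, sub$clnm)
  auc_mr <- auc(sub$mr_doi_mm, sub$clnm)
  lo <- min(sub$us_doi_mm) - 1
  hi <- max(sub$us_doi_mm) + 1
  expect_equal(auc(compose_doi(sub$us_doi_mm, sub$mr_doi_mm, hi), sub$clnm),
               auc_us, tolerance = 1e-12)
  expect_equal(auc(compose_doi(sub$us_doi_mm, sub$mr_doi_mm, lo), sub$clnm),
               auc_mr, tolerance = 1e-12)
})

test_that("grid search recovers an engineered switching regime", {
  # usDOI equals pDOI exactly up to 8 mm but reads a flat, uninformative
  # 10 mm beyond (so deep readings still clear the switch); mrDOI tracks
  # pDOI for deep tumors but grossly overestimates shallow ones (the
  # peritumoral-inflammation failure mode), so switching a shallow patient
  # to MRI is strictly costly; CLNM marks the deepest tumors. The largest
  # candidate below the trusted regime's edge is then uniquely optimal:
  # shallow cases keep the exact ultrasound value and every degraded deep
  # reading is replaced by MRI.
  set.seed(54)
  n <- 60
  pd <- seq(1, 16, length.out = n)
  us <- ifelse(pd <= 8, pd, 10)
  mr <- ifelse(pd <= 8, pd + 8, pd + 1 + rnorm(n, 0, 0.8))
  co <- data.frame(patient_id = as.character(1:n), p_doi_mm = pd,
                   us_doi_mm = us, mr_doi_mm = mr,
                   clnm = as.integer(pd > 12),
                   c_t = NA_character_, c_n = NA_character_,
                   c_stage = NA_character_)
  res <- suppressWarnings(grid_search(co))
  cand <- res$candidate_thresholds
  expect_equal(res$best_threshold, cand[which.min(abs(cand - 8))])
  expect_equal(res$best_threshold, max(cand[cand <= 8]))
  cc_auc_us <- auc(us, co$clnm)
  cc_auc_mr <- auc(mr, co$clnm)
  expect_gt(res$best_auc, cc_auc_us)
  expect_gt(res$best_auc, cc_auc_mr)
  expect_equal(res$best_auc, max(res$auc_per_threshold))
  expect_true(res$best_threshold %in% res$candidate_thresholds)
  expect_true(all(diff(res$candidate_thresholds) > 0))
})

test_that("decile grid agrees with an exhaustive all-values grid where they meet", {
  set.seed(55)
  n <- 40
  pd <- rlnorm(n, log(8), 0.8)
  us <- round(pd + rnorm(n, 0, 1), 0)  # <= 12 distinct values
  mr <- pd + 2.4 + rnorm(n, 0, 2.4)
  y <- as.integer(runif(n) < plogis(-2 + 0.25 * pd))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  co <- data.frame(patient_id = as.character(1:n), p_doi_mm = pd,
                   us_doi_mm = us, mr_doi_mm = mr, clnm = y,
                   c_t = NA_character_, c_n = NA_character_,
                   c_stage = NA_character_)
  dec <- suppressWarnings(grid_search(co))
  full_auc <- vapply(sort(unique(us)),
                     function(t) auc(compose_doi(us, mr, t), y), numeric(1))
  names(full_auc) <- sort(unique(us))
  for (i in seq_along(dec$candidate_thresholds)) {
    t <- dec$candidate_thresholds[i]
    if (as.character(t) %in% names(full_auc)) {
      expect_equal(dec$auc_per_threshold[i], unname(full_auc[as.character(t)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("grid search errors name the complete-case count", {
  co <- data.frame(patient_id = c("a", "b", "c"),
                   p_doi_mm = c(3, 6, 9), us_doi_mm = c(3, NA, 9),
                   mr_doi_mm = c(5, 7, NA), clnm = c(0L, 1L, 1L),
                   c_t = NA_character_, c_n = NA_character_,
                   c_stage = NA_character_)
  expect_error(grid_search(co), "n_complete = 1")
})
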