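test_that("a zero BLUP reproduces the population fixed curve", {
  sc <- small_cohort()
  zero <- tibble::tibble(iid = "Z", b0 = 0, b1 = 0, b2 = 0, b3 = 0)
  tr <- predict_trajectory(sc$fit, zero)
  pop <- predict_trajectory(sc$fit, NULL)
  expect_equal(tr$log_bmi, pop$log_bmi)
})

test_that("the prediction grid steps exactly 0.01 years", {
  sc <- small_cohort()
  tr <- predict_trajectory(sc$fit, NULL, range = c(0, 1), step = 0.01)
  expect_equal(nrow(tr), 101)
  expect_equal(unique(round(diff(tr$age), 12)), 0.01)
})

test_that("basis evaluation agrees with direct polynomial arithmetic", {
  beta <- c(2.6, 0.8, -0.9, 0.3, -0.3, -1e-4, 2e-4)
  fit <- fake_fit(beta)
  tr <- predict_trajectory(fit, NULL, range = c(0, 15), step = 0.05)
  t <- tr$age
  direct <- beta[1] + beta[2] * t + beta[3] * t^2 + beta[4] * t^3 +
    beta[5] * pmax(t - 1, 0)^3 + beta[6] * pmax(t - 8, 0)^3 +
    beta[7] * pmax(t - 12, 0)^3
  expect_equal(tr$log_bmi, direct, tolerance = 1e-12)
})

test_that("constructed quartics yield AP/AR at their analytic extrema", {
  set.seed(31)
  ages <- seq(2 / 52, 17, by = 0.01)
  for (i in 1:50) {
    m1 <- stats::runif(1, 0.5, 1.2)
    m2 <- stats::runif(1, 3, 7)
    y <- quartic_curve(ages, m1, m2)
    res <- find_ap_ar(tibble::tibble(age = ages, log_bmi = y))
    expect_lt(abs(res$ap_age - m1), 0.01 + 1e-9)
    expect_lt(abs(res$ar_age - m2), 0.01 + 1e-9)
    expect_equal(res$ap_bmi, exp(y[which.min(abs(ages - res$ap_age))]),
                 tolerance = 1e-12)
  }
})

test_that("curves without the peak-then-rebound shape return missing", {
  ages <- seq(2 / 52, 17, by = 0.01)
  inc <- find_ap_ar(tibble::tibble(age = ages, log_bmi = 0.05 * ages))
  expect_true(all(is.na(unlist(inc))))
  # nadir first, then peak: ordering rule forces all missing
  y_rev <- -quartic_curve(ages, 0.8, 5)
  rev <- find_ap_ar(tibble::tibble(age = ages, log_bmi = y_rev))
  expect_true(all(is.na(unlist(rev))))
  # maximum before 0.25 years only: outside the search interval
  y_early <- quartic_curve(ages, 0.1, 0.2, 0.3)
  early <- find_ap_ar(tibble::tibble(age = ages, log_bmi = y_early))
  expect_true(is.na(early$ap_age) ||
                (early$ap_age >= 0.25 && early$ap_age <= 10))
})

test_that("window slopes are exact on linear and constant trajectories", {
  ages <- seq(0, 17, by = 0.01)
  lin <- tibble::tibble(age = ages, log_bmi = 0.1 * ages)
  expect_equal(window_slope(lin, 1.5, 3.5), 0.1, tolerance = 1e-12)
  expect_equal(window_slope(lin, 12, 17), 0.1, tolerance = 1e-12)
  flat <- tibble::tibble(age = ages, log_bmi = rep(2.8, length(ages)))
  expect_equal(window_slope(flat, 6.5, 10), 0)
  expect_true(is.na(window_slope(flat, 10, 20)))
})

test_that("spline-curve slopes match the analytic endpoint difference", {
  sc <- small_cohort()
  b <- blups(sc$fit, sc$males)[1, ]
  tr <- predict_trajectory(sc$fit, b, range = c(2 / 52, 17), step = 0.0001)
  co <- c(unname(sc$fit$beta))
  bi <- as.numeric(b[, -1])
  exact <- function(t) {
    drop(design_matrix(t, sc$fit$spec$fixed) %*% co) +
      drop(design_matrix(t, sc$fit$spec$random) %*% bi)
  }
  # compare at the ages the slope is actually evaluated at (grid snapping)
  ta <- tr$age[which.min(abs(tr$age - 1.5))]
  tb <- tr$age[which.min(abs(tr$age - 3.5))]
  want <- (exact(tb) - exact(ta)) / (tb - ta)
  expect_equal(window_slope(tr, 1.5, 3.5), want, tolerance = 1e-9)
})

test_that("window AUC matches quadrature and is additive", {
  sc <- small_cohort()
  b <- blups(sc$fit, sc$males)[2, ]
  co <- unname(sc$fit$beta)
  bi <- as.numeric(b[, -1])
  f <- function(t) {
    drop(design_matrix(t, sc$fit$spec$fixed) %*% co) +
      drop(design_matrix(t, sc$fit$spec$random) %*% bi)
  }
  for (w in list(c(2 / 52, 0.5), c(1.5, 3.5), c(6.5, 10), c(12, 17))) {
    expect_equal(window_auc(sc$fit, b, w[1], w[2]),
                 quadrature_auc(f, w[1], w[2], sc$fit$spec$fixed$knots),
                 tolerance = 1e-8)
  }
  expect_equal(window_auc(sc$fit, b, 1.5, 3.5),
               window_auc(sc$fit, b, 1.5, 2.2) +
                 window_auc(sc$fit, b, 2.2, 3.5),
               tolerance = 1e-10)
})

test_that("constant and linear curves integrate to textbook values", {
  spec <- model_spec(spline_spec("linear"), spline_spec("intercept"))
  const <- fake_fit(c(2.5, 0), spec = spec)
  expect_equal(window_auc(const, NULL, 1, 4), 2.5 * 3, tolerance = 1e-12)
  ramp <- fake_fit(c(0, 1), spec = spec)
  expect_equal(window_auc(ramp, NULL, 0, 1), 0.5, tolerance = 1e-12)
})

test_that("phenotypes do not depend on the prediction grid step", {
  sc <- small_cohort()
  sub <- sc$males[sc$males$iid %in% unique(sc$males$iid)[1:20], ]
  p1 <- derive_phenotypes(sc$fit, sub, step = 0.01)
  p2 <- derive_phenotypes(sc$fit, sub, step = 0.001)
  for (cl in grep("^(slope|auc)_", names(p1), value = TRUE)) {
    expect_equal(p1[[cl]], p2[[cl]], tolerance = 1e-6)
  }
  expect_true(all(abs(p1$ap_age - p2$ap_age) <= 0.01 + 1e-9, na.rm = TRUE))
})

test_that("ages at AP precede ages at AR whenever both are present", {
  sc <- small_cohort()
  ph <- derive_phenotypes(sc$fit, sc$males)
  both <- !is.na(ph$ap_age) & !is.na(ph$ar_age)
  expect_gt(mean(both), 0.8)
  expect_true(all(ph$ap_age[both] < ph$ar_age[both]))
  expect_true(all(ph$ap_age[both] >= 0.25 & ph$ap_age[both] <= 10))
})

test_that("adolescent phenotypes are missing for a short prediction range", {
  sc <- small_cohort()
  sub <- sc$males[sc$males$iid %in% unique(sc$males$iid)[1:10], ]
  ph <- derive_phenotypes(sc$fit, sub, range = c(2 / 52, 16))
  expect_true(all(is.na(ph$slope_adolescence)))
  expect_true(all(is.na(ph$auc_adolescence)))
  expect_false(any(is.na(ph$slope_infancy)))
})

test_that("twice-IQR exclusion flags gross outliers on any phenotype", {
  # {1,2,3,4,100}: type-7 quartiles 2 and 4, IQR 2, upper bound 4 + 4 = 8
  ph <- tibble::tibble(iid = letters[1:5], a = c(1, 2, 3, 4, 100),
                       b = c(5, 5, 5, 5, 5))
  ex <- iqr_exclusion(ph)
  expect_equal(ex$phenos$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(ex$bounds$upper[ex$bounds$phenotype == "a"], 8)
  expect_equal(ex$bounds$lower[ex$bounds$phenotype == "a"], -2)
  # all-identical values: IQR 0, nothing excluded
  same <- tibble::tibble(iid = letters[1:5], a = rep(7, 5))
  expect_false(any(iqr_exclusion(same)$phenos$outlier))
  # outlier on one phenotype removes the subject from the filtered table
  expect_false("e" %in% ex$filtered$iid)
})

test_that("phenotype summaries z-score cleanly and correlate as built", {
  sc <- small_cohort()
  ph <- derive_phenotypes(sc$fit, sc$males)
  ex <- iqr_exclusion(ph)
  sex <- tibble::tibble(iid = ph$iid, sex = "male")
  end_bmi <- tibble::tibble(
    iid = ph$iid,
    bmi = exp(vapply(seq_len(nrow(ph)), function(i) {
      predict_trajectory(sc$fit, blups(sc$fit, sc$males)[i, ],
                         range = c(16.99, 17), step = 0.01)$log_bmi[2]
    }, numeric(1))))
  sm <- phenotype_summaries(ex$filtered, sex, end_bmi)
  expect_equal(diag(sm$correlations), rep(1, ncol(sm$correlations)),
               ignore_attr = TRUE)
  # infancy slope and AP age share the same random-effect drivers
  expect_gt(sm$correlations["slope_infancy", "ap_age"], 0.5)
  # late AUC dominates end-of-trajectory BMI
  r2 <- sm$end_bmi_r2
  expect_gt(r2$adj_r2[r2$phenotype == "auc_adolescence"], 0.7)
})

test_that("phenotypes are robust to the residual-correlation structure", {
  sc <- small_cohort()
  sub <- sc$males[sc$males$iid %in% unique(sc$males$iid)[1:60], ]
  f0 <- fit_lmm(sub, eq1_spec())
  f1 <- fit_lmm(sub, eq1_spec("car1"))
  expect_false(f1$status == "error")
  p0 <- derive_phenotypes(f0, sub)
  p1 <- derive_phenotypes(f1, sub)
  for (cl in c("ap_age", "ar_age", "slope_infancy", "auc_childhood")) {
    ok <- !is.na(p0[[cl]]) & !is.na(p1[[cl]])
    expect_gte(stats::cor(p0[[cl]][ok], p1[[cl]][ok],
                          method = "spearman"), 0.9)
  }
})

test_that("log-slope to percent-change conversion is exponential", {
  expect_equal(slope_to_change(0.1), 100 * (exp(0.1) - 1))
  expect_equal(slope_to_change(0.5, dt = 2), 100 * (exp(1) - 1))
  expect_equal(slope_to_change(0.36, bmi0 = 14), 14 * (exp(0.36) - 1))
  expect_equal(slope_to_change(0), 0)
})
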