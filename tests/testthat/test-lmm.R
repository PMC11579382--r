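test_that("with zero between-subject variance the fit collapses to OLS", {
  # residuals centred within subject carry no between-subject component at
  # all, so the random-intercept variance is estimated exactly at the
  # boundary and the fit collapses to OLS
  cfg <- sim_config(n_subjects = 80, G = matrix(0, 4, 4), sigma = 0,
                    sex_ratio = 1, seed = 14)
  ch <- simulate_cohort(cfg)
  tab <- derive_analysis_set(flag_records(ch$records))
  set.seed(140)
  eps <- stats::rnorm(nrow(tab), sd = 0.04)
  tab$log_bmi <- tab$log_bmi + eps -
    stats::ave(eps, tab$iid, FUN = mean)
  spec <- model_spec(spline_spec("cubic_spline", c(1, 8, 12)),
                     spline_spec("intercept"))
  fit <- fit_lmm(tab, spec)
  X <- design_matrix(tab$age, cfg$fixed_spec)
  ols <- stats::lm.fit(X, tab$log_bmi)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
  # ML residual variance has the 1/n normalisation
  expect_equal(fit$sigma2, mean(ols$residuals^2), tolerance = 1e-6)
  expect_lt(fit$G[1, 1], 1e-10)
})

test_that("fixed effects are recovered within two standard errors", {
  cfg <- sim_config(n_subjects = 400, sex_ratio = 1, seed = 15)
  ch <- simulate_cohort(cfg)
  tab <- derive_analysis_set(flag_records(ch$records))
  fit <- fit_lmm(tab, eq1_spec())
  expect_equal(fit$status, "ok")
  td <- tidy(fit)
  # single replicate: a 3-SE sanity band (the calibrated 2-SE coverage
  # claim is asserted over replicates elsewhere)
  expect_true(all(abs(td$estimate - cfg$beta) <= 3 * td$std.error))
})

test_that("block marginal likelihood equals the naive full-matrix form", {
  sc <- small_cohort()
  toy <- sc$males[sc$males$iid %in% unique(sc$males$iid)[1:5], ]
  spec <- eq1_spec()
  ll_b <- lmm_loglik(toy, spec, sc$fit$beta, sc$fit$G, sc$fit$sigma2,
                     block = TRUE)
  ll_n <- lmm_loglik(toy, spec, sc$fit$beta, sc$fit$G, sc$fit$sigma2,
                     block = FALSE)
  expect_equal(ll_b, ll_n, tolerance = 1e-8)
})

test_that("engine log-likelihood matches the package's own evaluator", {
  sc <- small_cohort()
  ll <- lmm_loglik(sc$males, eq1_spec(), sc$fit$beta, sc$fit$G,
                   sc$fit$sigma2)
  expect_equal(ll, sc$fit$loglik, tolerance = 1e-4 * abs(sc$fit$loglik))
})

test_that("balanced random-intercept ML matches the one-way closed form", {
  set.seed(77)
  n_g <- 40
  n_per <- 6
  tau2 <- 0.04
  s2 <- 0.01
  b <- rep(stats::rnorm(n_g, sd = sqrt(tau2)), each = n_per)
  tab <- tibble::tibble(
    iid = rep(sprintf("g%02d", 1:n_g), each = n_per),
    age = rep(seq(1, 6), n_g),
    log_bmi = 3 + b + stats::rnorm(n_g * n_per, sd = sqrt(s2)))
  spec <- model_spec(spline_spec("intercept"), spline_spec("intercept"))
  fit <- fit_lmm(tab, spec)
  # closed-form ML for the balanced one-way random effects model
  ybar_g <- tapply(tab$log_bmi, tab$iid, mean)
  mu <- mean(tab$log_bmi)
  sse <- sum((tab$log_bmi - ybar_g[tab$iid])^2)
  ssa <- n_per * sum((ybar_g - mu)^2)
  sigma2_hat <- sse / (n_g * (n_per - 1))
  tau2_hat <- max(ssa / n_g / n_per - sigma2_hat / n_per, 0)
  expect_equal(unname(fit$beta[1]), mu, tolerance = 1e-6)
  expect_equal(fit$sigma2, sigma2_hat, tolerance = 1e-4)
  expect_equal(fit$G[1, 1], tau2_hat, tolerance = 1e-3)
})

test_that("BLUPs are zero when G is zero and shrink with fewer visits", {
  sc <- small_cohort()
  fitz <- fake_fit(sc$fit$beta, sigma2 = sc$fit$sigma2)  # G = 0
  bz <- blups(fitz, sc$males)
  expect_true(all(abs(as.matrix(bz[, -1])) < 1e-12))

  # same subjects, truncated to 2 visits: shrinkage pulls estimates in
  b_full <- blups(sc$fit, sc$males)
  short <- dplyr::slice_head(dplyr::group_by(sc$males, iid), n = 2)
  b_short <- blups(sc$fit, dplyr::ungroup(short))
  nf <- sqrt(rowSums(as.matrix(b_full[, -1])^2))
  ns <- sqrt(rowSums(as.matrix(b_short[, -1])^2))
  expect_lt(mean(ns), mean(nf))
})

test_that("a subject lying exactly on the fixed curve has a zero BLUP", {
  sc <- small_cohort()
  ages <- c(0.5, 2, 5, 9, 14)
  X <- design_matrix(ages, sc$fit$spec$fixed)
  tab <- tibble::tibble(iid = "EXACT", age = ages,
                        log_bmi = drop(X %*% sc$fit$beta[colnames(X)]))
  b <- blups(sc$fit, tab)
  expect_true(all(abs(as.matrix(b[, -1])) < 1e-8))
})

test_that("information criteria follow their definitions", {
  fit <- fake_fit(rep(0, 7))
  fit$loglik <- -100
  fit$n_params <- 5
  fit$n_obs <- 200
  expect_equal(-2 * fit$loglik + 2 * fit$n_params, 210)
  expect_equal(-2 * fit$loglik + log(fit$n_obs) * fit$n_params,
               200 + 5 * log(200))
  sc <- small_cohort()
  dg <- diagnostics(sc$fit, sc$males)
  expect_equal(dg$aic, -2 * sc$fit$loglik + 2 * sc$fit$n_params)
  expect_equal(dg$bic,
               -2 * sc$fit$loglik + log(sc$fit$n_obs) * sc$fit$n_params)
  expect_gte(dg$icc, 0)
  expect_lte(dg$icc, 1)
  expect_lte(dg$r2_marginal, dg$r2_conditional)
})

test_that("marginal and conditional R2 coincide when G is zero", {
  sc <- small_cohort()
  fit0 <- fake_fit(sc$fit$beta, sigma2 = sc$fit$sigma2)  # G = 0
  dg <- diagnostics(fit0, sc$males)
  expect_equal(dg$r2_marginal, dg$r2_conditional, tolerance = 1e-12)
  expect_equal(dg$icc, 0)
})

test_that("adding a knot never lowers the ML log-likelihood", {
  sc <- small_cohort()
  small_spec <- model_spec(spline_spec("cubic_spline", c(1, 8)),
                           spline_spec("linear"))
  big_spec <- model_spec(spline_spec("cubic_spline", c(1, 8, 12)),
                         spline_spec("linear"))
  f1 <- fit_lmm(sc$males, small_spec)
  f2 <- fit_lmm(sc$males, big_spec)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("the CAR(1) profile fit nests the independent-residual fit", {
  sc <- small_cohort()
  sub <- sc$males[sc$males$iid %in% unique(sc$males$iid)[1:60], ]
  f0 <- fit_lmm(sub, eq1_spec())
  f1 <- fit_lmm(sub, eq1_spec("car1"))
  expect_false(f1$status == "error")
  expect_gte(f1$loglik, f0$loglik - 1e-4)
  expect_gte(f1$phi, 0)
  expect_lt(f1$phi, 1)
  expect_equal(lmm_loglik(sub, eq1_spec("car1"), f1$beta, f1$G, f1$sigma2,
                          f1$phi),
               f1$loglik, tolerance = 1e-6 * abs(f1$loglik))
})

test_that("failures are reported as status, not exceptions", {
  tiny <- tibble::tibble(iid = c("a", "a", "b"), age = c(1, 2, 1),
                         log_bmi = c(2.7, 2.8, 2.75))
  fit <- fit_lmm(tiny, eq1_spec())
  expect_true(fit$status %in% c("warning", "error"))
  expect_s3_class(fit, "traj_lmm")
})
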