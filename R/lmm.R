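#' Mixed-model specification for a growth trajectory
#'
#' Pairs a fixed-effect spline with a (usually reduced) random-effect
#' function of age, an optional CAR(1) within-subject correlation structure,
#' and optional fixed covariates.
#'
#' @param fixed [spline_spec()] for the population mean curve.
#' @param random [spline_spec()] for subject-level deviations; its columns
#'   should be a subset or lower-degree reduction of the fixed design.
#' @param correlation `"none"` or `"car1"`.
#' @param covariates Character vector of extra fixed-effect columns in the
#'   data (e.g. a measurement-source indicator).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(spline_spec("cubic_spline", c(1, 8, 12)),
#'            spline_spec("cubic_slope"))
#' @export
model_spec <- function(fixed, random = spline_spec("cubic_slope"),
                       correlation = c("none", "car1"),
                       covariates = character()) {
  stopifnot(inherits(fixed, "spline_spec"), inherits(random, "spline_spec"))
  correlation <- match.arg(correlation)
  structure(list(fixed = fixed, random = random, correlation = correlation,
                 covariates = covariates), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> fixed: ", format_spec(x$fixed),
      " | random: ", format_spec(x$random),
      " | correlation: ", x$correlation, "\n", sep = "")
  invisible(x)
}

format_spec <- function(s) {
  if (length(s$knots)) paste0(s$form, "(", paste(s$knots, collapse = ","), ")")
  else s$form
}

# basis columns for both designs, with shared names where the bases coincide
lmm_data <- function(table, spec) {
  Xf <- design_matrix(table$age, spec$fixed, intercept = FALSE)
  Zr <- design_matrix(table$age, spec$random, intercept = FALSE)
  d <- data.frame(iid = factor(table$iid, levels = unique(table$iid)),
                  age = table$age, log_bmi = table$log_bmi,
                  check.names = FALSE)
  for (nm in colnames(Xf)) d[[nm]] <- Xf[, nm]
  for (nm in colnames(Zr)) d[[nm]] <- Zr[, nm]
  for (cv in spec$covariates) d[[cv]] <- table[[cv]]
  d
}

#' Fit a spline linear mixed model to longitudinal log BMI
#'
#' Estimates `log_bmi = X(age) beta + Z(age) b_i + eps` with
#' `b_i ~ MVN(0, G)` and residuals that are independent or CAR(1)-correlated
#' within subject. Estimation is by maximum likelihood (default, so
#' information criteria are comparable across fixed-effect structures) or
#' REML via \pkg{nlme}, with the random-effect covariance parameterised
#' through its log-Cholesky factor so it stays positive semi-definite.
#' Convergence problems never raise: the fit is returned with status
#' `"warning"` or `"error"` and the message recorded, so a model grid can
#' be run unattended.
#'
#' @param table Modelling tibble from [derive_analysis_set()] (columns
#'   `iid`, `age`, `log_bmi`, plus any covariates).
#' @param spec A [model_spec()].
#' @param method `"ML"` (default) or `"REML"`.
#' @return An object of class `traj_lmm`: a list with `beta`, `G`, `sigma2`,
#'   `phi`, `loglik`, `n_params`, `n_subjects`, `n_obs`, `status`,
#'   `message`, `spec`, `method` and the underlying \pkg{nlme} `fit` (NULL
#'   on error).
#' @export
fit_lmm <- function(table, spec, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  d <- lmm_data(table, spec)
  fx_terms <- c(spline_colnames(spec$fixed), spec$covariates)
  rn_terms <- spline_colnames(spec$random)

  # Rescale each basis column to [-1, 1] before optimisation: the cubic
  # terms span several orders of magnitude over 0-18 years and unscaled
  # they stall both engines. Estimates are mapped back to the natural
  # (years) scale below, so the returned fit is scale-free.
  basis_cols <- union(setdiff(fx_terms, spec$covariates), rn_terms)
  scales <- vapply(basis_cols, function(nm) max(abs(d[[nm]]), 1e-12),
                   numeric(1))
  d$.age_nat <- d$age  # CAR(1) distances stay in years
  for (nm in basis_cols) d[[nm]] <- d[[nm]] / scales[nm]

  warn_knots <- spec$fixed$knots
  if (length(warn_knots) &&
      (min(warn_knots) <= min(table$age) || max(warn_knots) >= max(table$age))) {
    knot_msg <- "knot outside the observed age range"
  } else {
    knot_msg <- NULL
  }

  status <- if (is.null(knot_msg)) "ok" else "warning"
  msg <- if (is.null(knot_msg)) "" else knot_msg
  note <- function(s, m) {
    if (s == "error") status <<- "error"
    else if (status == "ok") status <<- "warning"
    msg <<- trimws(paste(msg, m))
  }
  engine <- if (spec$correlation == "car1") "car1" else "lme4"

  fit <- withCallingHandlers(
    tryCatch(
      if (engine == "lme4") {
        fit_engine_lme4(d, fx_terms, rn_terms, method)
      } else {
        fit_engine_car1(d, fx_terms, rn_terms, method)
      },
      error = function(e) {
        note("error", conditionMessage(e))
        NULL
      }),
    warning = function(w) {
      note("warning", conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      note("warning", conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  q <- length(rn_terms) + 1L
  n_params <- length(fx_terms) + 1L + q * (q + 1L) / 2L + 1L +
    (spec$correlation == "car1")
  base <- list(beta = NULL, G = NULL, sigma2 = NA_real_, phi = NA_real_,
               loglik = NA_real_, n_params = n_params,
               n_subjects = length(unique(table$iid)), n_obs = nrow(table),
               status = status, message = msg, spec = spec, method = method,
               scales = scales, engine = engine, fit = NULL)
  class(base) <- "traj_lmm"
  if (is.null(fit)) {
    base$status <- "error"
    return(base)
  }

  # map back to the natural age scale: beta_j = beta_s_j / s_j and
  # G = D^-1 G_s D^-1 with D = diag(1, s_random)
  sf <- c(1, scales[setdiff(fx_terms, spec$covariates)],
          rep(1, length(spec$covariates)))
  beta <- fit$beta / sf
  names(beta) <- c("(Intercept)", fx_terms)
  Dr <- c(1, scales[rn_terms])
  G <- unname_matrix(fit$G / tcrossprod(Dr))

  base$beta <- beta
  base$G <- G
  base$sigma2 <- fit$sigma2
  base$phi <- if (spec$correlation == "car1") fit$phi else NA_real_
  base$loglik <- fit$loglik
  base$fit <- fit$object
  base
}

# engine backends operate on the scaled data and return raw (scaled)
# parameter estimates plus the engine object

fit_engine_lme4 <- function(d, fx_terms, rn_terms, method) {
  f <- stats::as.formula(paste(
    "log_bmi ~", paste(fx_terms, collapse = " + "), "+ (",
    if (length(rn_terms)) paste(rn_terms, collapse = " + ") else "1",
    "| iid)"))
  m <- lme4::lmer(f, data = d, REML = method == "REML",
                  control = lme4::lmerControl(calc.derivs = FALSE))
  if (lme4::isSingular(m)) {
    message("singular random-effect covariance (boundary fit)")
  }
  vc <- lme4::VarCorr(m)$iid
  G <- matrix(as.numeric(vc), nrow(vc))
  list(beta = unname(lme4::fixef(m)), G = G,
       sigma2 = stats::sigma(m)^2, phi = NA_real_,
       loglik = as.numeric(stats::logLik(m)), object = m)
}

# CAR(1) engine: direct (restricted) maximum likelihood by quasi-Newton on
# the unconstrained parameters (log-Cholesky factor of G, log sigma2,
# logit phi), with beta profiled out by GLS inside the objective. The
# per-subject block structure keeps each evaluation linear in subjects.
# Restarts from three deterministic initialisations (OLS residual variance
# split across the random intercept and the residual, phi at 0.2 / 0.6 /
# 0.05) before giving up.
fit_engine_car1 <- function(d, fx_terms, rn_terms, method) {
  X <- cbind(1, as.matrix(d[, fx_terms, drop = FALSE]))
  Z <- cbind(1, if (length(rn_terms)) as.matrix(d[, rn_terms, drop = FALSE]))
  y <- d$log_bmi
  q <- ncol(Z)
  p <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), d$iid)
  age_nat <- if (".age_nat" %in% names(d)) d$.age_nat else d$age
  blocks <- lapply(idx, function(g) {
    list(X = X[g, , drop = FALSE], Z = Z[g, , drop = FALSE], y = y[g],
         D = abs(outer(age_nat[g], age_nat[g], "-")))
  })
  reml <- method == "REML"
  ltri <- lower.tri(diag(q), diag = TRUE)
  unpack <- function(th) {
    L <- matrix(0, q, q)
    L[ltri] <- th[seq_len(q * (q + 1) / 2)]
    diag(L) <- exp(diag(L))
    sigma2 <- exp(th[q * (q + 1) / 2 + 1])
    phi <- stats::plogis(th[q * (q + 1) / 2 + 2])
    list(G = tcrossprod(L), sigma2 = sigma2, phi = phi)
  }
  negll <- function(th) {
    pr <- unpack(th)
    A <- matrix(0, p, p)
    bb <- numeric(p)
    yy <- 0
    logdet <- 0
    for (bl in blocks) {
      V <- bl$Z %*% pr$G %*% t(bl$Z) + pr$sigma2 * pr$phi^bl$D
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Wx <- backsolve(ch, bl$X, transpose = TRUE)
      Wy <- backsolve(ch, bl$y, transpose = TRUE)
      A <- A + crossprod(Wx)
      bb <- bb + crossprod(Wx, Wy)
      yy <- yy + sum(Wy^2)
      logdet <- logdet + 2 * sum(log(diag(ch)))
    }
    beta <- tryCatch(solve(A, bb), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    quad <- yy - 2 * sum(bb * beta) + drop(t(beta) %*% A %*% beta)
    ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
    if (reml) {
      ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * determinant(A)$modulus
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ols <- stats::lm.fit(X, y)
  v0 <- stats::var(ols$residuals)
  make_init <- function(gscale, phi0) {
    full <- matrix(0, q, q)
    diag(full) <- log(c(sqrt(v0 * gscale), rep(sqrt(v0) * 1e-2, q - 1)))
    c(full[ltri], log(v0 * (1 - gscale)), stats::qlogis(phi0))
  }
  # warm start at the independent-residual optimum (phi near zero), so the
  # CAR(1) fit can never fall meaningfully below the nested model
  warm <- tryCatch({
    g0 <- suppressWarnings(suppressMessages(
      fit_engine_lme4(d, fx_terms, rn_terms, method)))
    L0 <- t(chol(g0$G + diag(1e-10, q)))
    diag(L0) <- pmax(diag(L0), 1e-8)
    th <- matrix(0, q, q)
    th[ltri] <- L0[ltri]
    diag(th) <- log(diag(L0))
    c(th[ltri], log(g0$sigma2), stats::qlogis(0.05))
  }, error = function(e) NULL)
  inits <- list(make_init(0.5, 0.2), make_init(0.5, 0.6), make_init(0.1, 0.05))
  if (!is.null(warm)) {
    # candidate at the phi -> 0 boundary: the CAR(1) family contains the
    # independent-residual model in its closure, so its maximum can never
    # fall below that fit
    npar <- length(warm)
    boundary <- warm
    boundary[npar] <- -1e6  # plogis underflows to exactly zero
    inits <- c(list(warm), inits)
  }
  best <- NULL
  for (th0 in inits) {
    opt <- tryCatch(
      stats::optim(th0, negll, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12,
                                  ndeps = rep(1e-5, length(th0)))),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (!is.null(warm)) {
    vb <- negll(boundary)
    if (!is.null(best) && vb < best$value) {
      best <- list(par = boundary, value = vb, counts = c(1, 0),
                   convergence = 0L)
    }
  }
  if (is.null(best)) stop("CAR(1) likelihood optimisation failed from all starts")
  if (best$convergence != 0) {
    warning("CAR(1) optimiser did not report clean convergence (code ",
            best$convergence, ")")
  }
  pr <- unpack(best$par)
  # recover the profiled beta at the optimum
  A <- matrix(0, p, p)
  bb <- numeric(p)
  for (bl in blocks) {
    V <- bl$Z %*% pr$G %*% t(bl$Z) + pr$sigma2 * pr$phi^bl$D
    ch <- chol(V)
    Wx <- backsolve(ch, bl$X, transpose = TRUE)
    Wy <- backsolve(ch, bl$y, transpose = TRUE)
    A <- A + crossprod(Wx)
    bb <- bb + crossprod(Wx, Wy)
  }
  beta <- drop(solve(A, bb))
  if (pr$phi > 0.995) {
    warning("CAR(1) parameter at the upper bound")
  }
  list(beta = beta, G = pr$G, sigma2 = pr$sigma2, phi = pr$phi,
       loglik = -best$value,
       object = list(par = best$par, counts = best$counts,
                     convergence = best$convergence, vcov_beta = solve(A)))
}

unname_matrix <- function(M) {
  M <- as.matrix(M)
  dimnames(M) <- NULL
  M
}

#' @export
print.traj_lmm <- function(x, ...) {
  cat("<traj_lmm> ", format_spec(x$spec$fixed), " / ",
      format_spec(x$spec$random), " / ", x$spec$correlation,
      " [", x$method, "] status: ", x$status, "\n", sep = "")
  if (!is.null(x$beta)) {
    cat("  logLik ", format(x$loglik), ", sigma ", format(sqrt(x$sigma2)),
        if (is.finite(x$phi)) paste0(", phi ", format(x$phi)), "\n", sep = "")
  }
  invisible(x)
}

#' Marginal log-likelihood of a fitted (or hypothesised) trajectory model
#'
#' Evaluates the Gaussian marginal log-likelihood with per-subject covariance
#' `V_i = Z_i G Z_i' + sigma2 * C_i(phi)`, summing over subjects
#' (`block = TRUE`, the efficient route) or building the full block-diagonal
#' covariance explicitly (`block = FALSE`, the naive cross-check used in
#' tests). Independent of the fitting engine.
#'
#' @param table Modelling tibble (`iid`, `age`, `log_bmi`, covariates).
#' @param spec A [model_spec()].
#' @param beta,G,sigma2,phi Model parameters; `phi` ignored unless the spec
#'   has CAR(1) correlation.
#' @param block Use the per-subject block formula (default) or the full
#'   matrix.
#' @return The log-likelihood (a scalar).
#' @export
lmm_loglik <- function(table, spec, beta, G, sigma2, phi = 0, block = TRUE) {
  d <- lmm_data(table, spec)
  X <- cbind(1, as.matrix(d[, c(spline_colnames(spec$fixed), spec$covariates),
                            drop = FALSE]))
  rn <- spline_colnames(spec$random)
  Z <- cbind(1, if (length(rn)) as.matrix(d[, rn, drop = FALSE]))
  r <- d$log_bmi - drop(X %*% beta)
  use_phi <- if (spec$correlation == "car1") phi else 0
  idx <- split(seq_len(nrow(d)), d$iid)
  if (block) {
    ll <- 0
    for (g in idx) {
      Zi <- Z[g, , drop = FALSE]
      Vi <- Zi %*% G %*% t(Zi) + sigma2 * car1_matrix(d$age[g], use_phi)
      ch <- chol(Vi)
      ri <- r[g]
      ll <- ll - 0.5 * (length(g) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, ri, transpose = TRUE)^2))
    }
    ll
  } else {
    n <- nrow(d)
    V <- matrix(0, n, n)
    for (g in idx) {
      Zi <- Z[g, , drop = FALSE]
      V[g, g] <- Zi %*% G %*% t(Zi) + sigma2 * car1_matrix(d$age[g], use_phi)
    }
    ch <- chol(V)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, r, transpose = TRUE)^2))
  }
}

#' Best linear unbiased predictors of the subject random coefficients
#'
#' Computes `b_i = G Z_i' V_i^{-1} (y_i - X_i beta)` directly from the
#' estimated parameters, with `V_i = Z_i G Z_i' + sigma2 C_i(phi)`. Subjects
#' with no observations (or a zero `G`) get a zero vector; estimates are
#' shrunk toward zero, more strongly for subjects with few measurements.
#'
#' @param fit A converged (`ok` or `warning`) [fit_lmm()] object.
#' @param table The modelling tibble the model was fitted to (or new data
#'   with the same columns).
#' @return Tibble with `iid` and one column per random coefficient
#'   (`b0`, `b1`, ...).
#' @export
blups <- function(fit, table) {
  stopifnot(inherits(fit, "traj_lmm"))
  if (fit$status == "error") stop("cannot compute BLUPs from a failed fit")
  spec <- fit$spec
  d <- lmm_data(table, spec)
  X <- cbind(1, as.matrix(d[, c(spline_colnames(spec$fixed), spec$covariates),
                            drop = FALSE]))
  rn <- spline_colnames(spec$random)
  Z <- cbind(1, if (length(rn)) as.matrix(d[, rn, drop = FALSE]))
  r <- d$log_bmi - drop(X %*% fit$beta)
  q <- ncol(Z)
  use_phi <- if (spec$correlation == "car1") fit$phi else 0
  ids <- unique(as.character(d$iid))
  B <- matrix(0, length(ids), q)
  for (k in seq_along(ids)) {
    g <- which(as.character(d$iid) == ids[k])
    Zi <- Z[g, , drop = FALSE]
    Vi <- Zi %*% fit$G %*% t(Zi) +
      fit$sigma2 * car1_matrix(d$age[g], use_phi)
    B[k, ] <- drop(fit$G %*% t(Zi) %*% solve(Vi, r[g]))
  }
  colnames(B) <- paste0("b", seq_len(q) - 1L)
  dplyr::bind_cols(tibble::tibble(iid = ids), tibble::as_tibble(B))
}

#' Fit diagnostics for a trajectory mixed model
#'
#' AIC and BIC from the maximised log-likelihood and parameter count; RMSE
#' of the conditional (subject-level) residuals; residual SD; intraclass
#' correlation from the random-intercept variance,
#' `ICC = G[1,1] / (G[1,1] + sigma2)` (reported at age zero — a documented
#' simplification under random slopes); and marginal/conditional R² in the
#' variance-partition style: the fixed-curve variance over (fixed + average
#' random + residual) variance, with the conditional version adding the
#' random-effect variance to the numerator.
#'
#' @param fit A [fit_lmm()] object with status `ok` or `warning`.
#' @param table The modelling tibble.
#' @return A one-row tibble: `aic`, `bic`, `rmse`, `residual_sd`, `icc`,
#'   `r2_marginal`, `r2_conditional`.
#' @export
diagnostics <- function(fit, table) {
  stopifnot(inherits(fit, "traj_lmm"))
  if (fit$status == "error") {
    return(tibble::tibble(aic = NA_real_, bic = NA_real_, rmse = NA_real_,
                          residual_sd = NA_real_, icc = NA_real_,
                          r2_marginal = NA_real_, r2_conditional = NA_real_))
  }
  spec <- fit$spec
  d <- lmm_data(table, spec)
  X <- cbind(1, as.matrix(d[, c(spline_colnames(spec$fixed), spec$covariates),
                            drop = FALSE]))
  rn <- spline_colnames(spec$random)
  Z <- cbind(1, if (length(rn)) as.matrix(d[, rn, drop = FALSE]))
  fixed_pred <- drop(X %*% fit$beta)
  b <- blups(fit, table)
  bm <- as.matrix(b[, -1, drop = FALSE])[match(as.character(d$iid), b$iid), ,
                                         drop = FALSE]
  cond_pred <- fixed_pred + rowSums(Z * bm)
  res <- d$log_bmi - cond_pred
  var_f <- stats::var(fixed_pred)
  var_r <- mean(rowSums((Z %*% fit$G) * Z))  # average diag(Z G Z')
  tot <- var_f + var_r + fit$sigma2
  tibble::tibble(
    aic = -2 * fit$loglik + 2 * fit$n_params,
    bic = -2 * fit$loglik + log(fit$n_obs) * fit$n_params,
    rmse = sqrt(mean(res^2)),
    residual_sd = sqrt(fit$sigma2),
    icc = fit$G[1, 1] / (fit$G[1, 1] + fit$sigma2),
    r2_marginal = var_f / tot,
    r2_conditional = (var_f + var_r) / tot)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a trajectory mixed model
#'
#' @param x A [fit_lmm()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (empty for failed fits).
#' @export
tidy.traj_lmm <- function(x, ...) {
  if (x$status == "error" || is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  se_s <- if (x$engine == "lme4") {
    stats::coef(summary(x$fit))[, "Std. Error"]
  } else {
    sqrt(diag(x$fit$vcov_beta))
  }
  term <- names(x$beta)
  # engine worked on rescaled columns; undo the scaling for the SEs too
  sf <- c(1, x$scales[setdiff(term[-1], x$spec$covariates)],
          rep(1, length(x$spec$covariates)))
  se <- unname(se_s / sf)
  est <- unname(x$beta)
  tibble::tibble(term = term, estimate = est, std.error = se,
                 statistic = est / se,
                 p.value = 2 * stats::pnorm(-abs(est / se)))
}

#' One-row fit summary of a trajectory mixed model
#'
#' @param x A [fit_lmm()] object.
#' @param table Optional modelling tibble; when supplied the full
#'   [diagnostics()] are included.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.traj_lmm <- function(x, table = NULL, ...) {
  base <- tibble::tibble(status = x$status, logLik = x$loglik,
                         n_params = x$n_params, sigma = sqrt(x$sigma2),
                         phi = x$phi, n_subjects = x$n_subjects,
                         n_obs = x$n_obs,
                         AIC = -2 * x$loglik + 2 * x$n_params,
                         BIC = -2 * x$loglik + log(x$n_obs) * x$n_params)
  if (!is.null(table) && x$status != "error") {
    dg <- diagnostics(x, table)
    base <- dplyr::bind_cols(base, dg[, c("rmse", "icc", "r2_marginal",
                                          "r2_conditional")])
  }
  base
}
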