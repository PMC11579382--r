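# Default analysis windows (years): intervals of approximately linear change
# in log BMI, avoiding the adiposity peak and rebound. The infancy window
# starts at the two-week data floor but is conventionally labelled
# "0-6 months".
default_windows <- function() {
  list(infancy = c(2 / 52, 0.5), childhood = c(1.5, 3.5),
       late_childhood = c(6.5, 10), adolescence = c(12, 17))
}

# combined subject curve: named coefficient vectors for the fixed and random
# bases of a fit plus one subject's BLUP
subject_coefs <- function(fit, blup_row) {
  b <- as.numeric(blup_row[, startsWith(names(blup_row), "b")])
  list(fixed = unname(fit$beta[c("(Intercept)",
                                 spline_colnames(fit$spec$fixed))]),
       random = b)
}

#' Predict a subject's log-BMI trajectory on a fine age grid
#'
#' Evaluates `X(t) beta + Z(t) b_i` at fixed steps (default 0.01 years).
#' Covariates are held at their reference level (contribution zero), so the
#' curve reflects age alone.
#'
#' @param fit A converged [fit_lmm()] object.
#' @param blup One row of the [blups()] tibble (or `NULL` for the population
#'   fixed curve).
#' @param range Prediction range in years, default two weeks to 17 years
#'   (use 16 for cohorts without data beyond that age).
#' @param step Grid step in years (default 0.01).
#' @return Tibble with `age` and `log_bmi`.
#' @export
predict_trajectory <- function(fit, blup = NULL, range = c(2 / 52, 17),
                               step = 0.01) {
  stopifnot(inherits(fit, "traj_lmm"), fit$status != "error")
  ages <- seq(range[1], range[2], by = step)
  X <- design_matrix(ages, fit$spec$fixed)
  y <- drop(X %*% fit$beta[colnames(X)])
  if (!is.null(blup)) {
    Z <- design_matrix(ages, fit$spec$random)
    b <- as.numeric(blup[, startsWith(names(blup), "b")])
    y <- y + drop(Z %*% b)
  }
  tibble::tibble(age = ages, log_bmi = y)
}

#' Locate the adiposity peak and rebound on a predicted trajectory
#'
#' The adiposity peak (AP) is the first interior local maximum of predicted
#' log BMI between 0.25 and 10 years (a strict rise-then-fall sign change of
#' the discrete derivative); the adiposity rebound (AR) is the first
#' interior local minimum after the AP in the same interval. BMIs are
#' returned on the natural scale. If either point is absent, or the AP does
#' not precede the AR, all four values are `NA`.
#'
#' @param traj Tibble from [predict_trajectory()]; the grid must cover
#'   `search` for detection inside it.
#' @param search Two-element search interval in years (default
#'   `c(0.25, 10)`).
#' @return One-row tibble: `ap_age`, `ap_bmi`, `ar_age`, `ar_bmi`.
#' @export
find_ap_ar <- function(traj, search = c(0.25, 10)) {
  miss <- tibble::tibble(ap_age = NA_real_, ap_bmi = NA_real_,
                         ar_age = NA_real_, ar_bmi = NA_real_)
  y <- traj$log_bmi
  a <- traj$age
  d <- diff(y)
  # sign change of the discrete derivative at interior point i (position in y)
  sgn <- sign(d)
  turn <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-length(sgn)] != 0) + 1L
  turn <- turn[a[turn] >= search[1] & a[turn] <= search[2]]
  if (!length(turn)) return(miss)
  is_max <- sgn[turn - 1L] > 0
  ap_i <- turn[is_max][1]
  if (is.na(ap_i)) return(miss)
  ar_candidates <- turn[!is_max & turn > ap_i]
  ar_i <- ar_candidates[1]
  if (is.na(ar_i) || a[ap_i] >= a[ar_i]) return(miss)
  tibble::tibble(ap_age = a[ap_i], ap_bmi = exp(y[ap_i]),
                 ar_age = a[ar_i], ar_bmi = exp(y[ar_i]))
}

#' Slope of a predicted trajectory over a time window
#'
#' The chord slope `(y(b) - y(a)) / (b - a)` in log-BMI units per year,
#' with the endpoints snapped to the nearest grid ages.
#'
#' @param traj Tibble from [predict_trajectory()].
#' @param a,b Window bounds in years, `a < b`.
#' @return The slope, or `NA` if the window extends beyond the grid.
#' @export
window_slope <- function(traj, a, b) {
  stopifnot(a < b)
  rng <- range(traj$age)
  tol <- 1.5 * (traj$age[2] - traj$age[1])
  if (a < rng[1] - tol || b > rng[2] + tol) return(NA_real_)
  ia <- which.min(abs(traj$age - a))
  ib <- which.min(abs(traj$age - b))
  (traj$log_bmi[ib] - traj$log_bmi[ia]) / (traj$age[ib] - traj$age[ia])
}

#' Area under a subject's log-BMI curve over a time window
#'
#' Closed-form integral of the fitted curve (fixed plus subject random
#' parts) using the exact antiderivatives of the monomial and truncated
#' power basis terms — no quadrature, and exact across knots inside the
#' window. Units are log-BMI x years.
#'
#' @param fit A converged [fit_lmm()] object.
#' @param blup One row of the [blups()] tibble, or `NULL` for the
#'   population curve.
#' @param a,b Window bounds in years, `a < b`.
#' @return The AUC (a scalar).
#' @export
window_auc <- function(fit, blup, a, b) {
  stopifnot(inherits(fit, "traj_lmm"), a < b)
  co <- fit$beta[c("(Intercept)", spline_colnames(fit$spec$fixed))]
  auc <- integrate_spline(fit$spec$fixed, unname(co), a, b)
  if (!is.null(blup)) {
    b_i <- as.numeric(blup[, startsWith(names(blup), "b")])
    auc <- auc + integrate_spline(fit$spec$random, b_i, a, b)
  }
  auc
}

#' Derive the trajectory phenotype set for every subject
#'
#' Runs [blups()], predicts each subject's trajectory on the 0.01-year grid,
#' and assembles the twelve estimated phenotypes: age and BMI at the
#' adiposity peak and rebound, and the slope and AUC over each analysis
#' window. Windows that extend beyond the prediction range (e.g. adolescence
#' in a cohort followed only to 16 years) come back `NA`.
#'
#' @param fit A converged [fit_lmm()] object.
#' @param table The modelling tibble the fit was estimated from.
#' @param windows Named list of analysis windows (years); see
#'   [default_windows()].
#' @param range Prediction range passed to [predict_trajectory()].
#' @param step Grid step (years).
#' @return Tibble with one row per subject: `iid`, `ap_age`, `ap_bmi`,
#'   `ar_age`, `ar_bmi`, then `slope_<window>` and `auc_<window>` per
#'   window.
#' @export
derive_phenotypes <- function(fit, table, windows = default_windows(),
                              range = c(2 / 52, 17), step = 0.01) {
  b <- blups(fit, table)
  B <- as.matrix(b[, startsWith(names(b), "b"), drop = FALSE])
  ages <- seq(range[1], range[2], by = step)
  # shared grid design: every subject curve is fixed_curve + Zg b_i
  Xg <- design_matrix(ages, fit$spec$fixed)
  Zg <- design_matrix(ages, fit$spec$random)
  fixed_curve <- drop(Xg %*% fit$beta[colnames(Xg)])
  co_fixed <- unname(fit$beta[c("(Intercept)",
                                spline_colnames(fit$spec$fixed))])

  win_ok <- vapply(windows, function(w) {
    w[1] >= range[1] - step && w[2] <= range[2] + step
  }, logical(1))
  # slopes use the exact window endpoints evaluated from the coefficients,
  # so they do not depend on the grid step
  win_X <- lapply(windows, function(w) design_matrix(w, fit$spec$fixed))
  win_Z <- lapply(windows, function(w) design_matrix(w, fit$spec$random))

  out <- vector("list", nrow(b))
  for (k in seq_len(nrow(b))) {
    y <- fixed_curve + drop(Zg %*% B[k, ])
    ph <- find_ap_ar(tibble::tibble(age = ages, log_bmi = y))
    for (w in names(windows)) {
      if (!win_ok[[w]]) {
        ph[[paste0("slope_", w)]] <- NA_real_
        ph[[paste0("auc_", w)]] <- NA_real_
      } else {
        yw <- drop(win_X[[w]] %*% fit$beta[colnames(win_X[[w]])]) +
          drop(win_Z[[w]] %*% B[k, ])
        ph[[paste0("slope_", w)]] <-
          (yw[2] - yw[1]) / (windows[[w]][2] - windows[[w]][1])
        ph[[paste0("auc_", w)]] <-
          integrate_spline(fit$spec$fixed, co_fixed,
                           windows[[w]][1], windows[[w]][2]) +
          integrate_spline(fit$spec$random, B[k, ],
                           windows[[w]][1], windows[[w]][2])
      }
    }
    out[[k]] <- ph
  }
  dplyr::bind_cols(tibble::tibble(iid = b$iid), dplyr::bind_rows(out))
}

#' Flag phenotype outliers by twice the interquartile range
#'
#' For each phenotype, bounds are `[Q1 - 2 IQR, Q3 + 2 IQR]` (quartiles by
#' linear interpolation, R type 7). A subject outside the bounds on any one
#' phenotype is excluded from all downstream analyses — an intentionally
#' conservative rule, since one aberrant phenotype usually means the whole
#' predicted curve is suspect.
#'
#' @param phenos Phenotype tibble from [derive_phenotypes()].
#' @param k Multiplier on the IQR (default 2).
#' @return List with `phenos` (input plus logical `outlier` column),
#'   `filtered` (outlier rows removed) and `bounds` (tibble of per-phenotype
#'   limits).
#' @export
iqr_exclusion <- function(phenos, k = 2) {
  cols <- setdiff(names(phenos), c("iid", "outlier"))
  out <- rep(FALSE, nrow(phenos))
  bounds <- list()
  for (cl in cols) {
    v <- phenos[[cl]]
    if (all(is.na(v))) {
      warning("phenotype ", cl, " is entirely missing; skipped")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                         type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    bounds[[cl]] <- tibble::tibble(phenotype = cl, lower = lo, upper = hi)
    out <- out | (!is.na(v) & (v < lo | v > hi))
  }
  phenos$outlier <- out
  list(phenos = phenos, filtered = phenos[!out, ],
       bounds = dplyr::bind_rows(bounds))
}

#' Descriptive validation of the estimated phenotypes
#'
#' Per-sex means and SDs, the pairwise-complete Pearson correlation matrix,
#' and — when an end-of-trajectory BMI is supplied — the adjusted R² of each
#' phenotype (z-scored within cohort) against end BMI (also z-scored),
#' adjusting for sex.
#'
#' @param phenos Filtered phenotype tibble (outliers removed).
#' @param sex Tibble with `iid` and `sex` for the same subjects.
#' @param end_bmi Optional tibble with `iid` and `bmi` at the end of the
#'   trajectory.
#' @return List with `summary` (per-sex mean/SD long tibble), `correlations`
#'   (matrix) and `end_bmi_r2` (tibble, or `NULL`).
#' @export
phenotype_summaries <- function(phenos, sex, end_bmi = NULL) {
  cols <- setdiff(names(phenos), c("iid", "outlier"))
  x <- dplyr::left_join(phenos, sex, by = "iid")
  long <- tidyr::pivot_longer(x[, c("sex", cols)], -"sex",
                              names_to = "phenotype")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$phenotype),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  cors <- stats::cor(as.matrix(phenos[, cols]),
                     use = "pairwise.complete.obs")
  r2 <- NULL
  if (!is.null(end_bmi)) {
    z <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    xx <- dplyr::inner_join(x, end_bmi, by = "iid")
    rows <- lapply(cols, function(cl) {
      keep <- !is.na(xx[[cl]]) & !is.na(xx$bmi)
      if (sum(keep) < 10) {
        return(tibble::tibble(phenotype = cl, adj_r2 = NA_real_))
      }
      fit <- if (length(unique(xx$sex[keep])) > 1) {
        stats::lm(z(xx$bmi[keep]) ~ z(xx[[cl]][keep]) +
                    factor(xx$sex[keep]))
      } else {
        stats::lm(z(xx$bmi[keep]) ~ z(xx[[cl]][keep]))
      }
      tibble::tibble(phenotype = cl,
                     adj_r2 = summary(fit)$adj.r.squared)
    })
    r2 <- dplyr::bind_rows(rows)
  }
  list(summary = summary, correlations = cors, end_bmi_r2 = r2)
}

#' Percent BMI change implied by a log-scale slope
#'
#' A slope `s` in log-BMI units per year sustained over `dt` years changes
#' BMI by `100 (e^{s dt} - 1)` percent; the absolute change from a starting
#' BMI is `bmi0 (e^{s dt} - 1)`. This is the conversion used to read the
#' estimated slopes on the clinical BMI scale (e.g. an infancy slope of 0.56
#' is a 75% rise over a year).
#'
#' @param slope Slope in log-BMI units per year.
#' @param dt Duration in years (default 1).
#' @param bmi0 Optional starting BMI; when given, the absolute change in
#'   kg/m^2 is returned instead of a percentage.
#' @return Percent change (or absolute change when `bmi0` is given).
#' @export
slope_to_change <- function(slope, dt = 1, bmi0 = NULL) {
  f <- exp(slope * dt) - 1
  if (is.null(bmi0)) 100 * f else bmi0 * f
}
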