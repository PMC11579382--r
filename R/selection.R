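#' The default candidate-model grid
#'
#' Sixteen cells: eight fixed/random structures crossed with residual
#' correlation in {none, CAR(1)}. The structures pair a cubic slope with
#' polynomial random effects of decreasing degree, linear splines (knots
#' 5.5 and 11 years, placed at the rebound and the pubertal onset) with
#' matching random splines, and cubic splines (knots 2, 8, 12 years) with
#' random effects stepping down from a full cubic spline to a cubic slope.
#'
#' @param cubic_knots Knots of the cubic-spline cells (default
#'   `c(2, 8, 12)`).
#' @param linear_knots Knots of the linear-spline cells (default
#'   `c(5.5, 11)`).
#' @param covariates Covariate columns passed to every cell.
#' @return A list of [model_spec()] objects (length 16).
#' @export
default_model_grid <- function(cubic_knots = c(2, 8, 12),
                               linear_knots = c(5.5, 11),
                               covariates = character()) {
  cs <- spline_spec("cubic_spline", cubic_knots)
  ls <- spline_spec("linear_spline", linear_knots)
  qs <- spline_spec("quadratic_spline", cubic_knots)
  structures <- list(
    list(fixed = spline_spec("cubic_slope"), random = spline_spec("cubic_slope")),
    list(fixed = spline_spec("cubic_slope"), random = spline_spec("quadratic")),
    list(fixed = spline_spec("cubic_slope"), random = spline_spec("linear")),
    list(fixed = ls, random = ls),
    list(fixed = cs, random = cs),
    list(fixed = cs, random = qs),
    list(fixed = cs, random = ls),
    list(fixed = cs, random = spline_spec("cubic_slope")))
  grid <- list()
  for (st in structures) {
    for (corr in c("none", "car1")) {
      grid[[length(grid) + 1]] <- model_spec(st$fixed, st$random,
                                             correlation = corr,
                                             covariates = covariates)
    }
  }
  grid
}

#' Fit every candidate model, per sex
#'
#' Fits each [model_spec()] in the grid separately within each sex (growth
#' curves are sex-specific throughout). Failures are caught per cell and
#' recorded with status `"error"`; nothing escapes the runner.
#'
#' @param table Modelling tibble ([derive_analysis_set()] output).
#' @param grid List of [model_spec()] objects, default
#'   [default_model_grid()].
#' @param method `"ML"` or `"REML"`.
#' @param keep_fits Keep the fitted objects in a list column (default
#'   `FALSE` to save memory).
#' @return Tibble with one row per (cell, sex): spec descriptors, `status`,
#'   `message`, `logLik`, `AIC`, `BIC`, `rmse`, `icc`, `r2_marginal`,
#'   `r2_conditional`, `runtime_s`, and `fit` when requested.
#' @export
run_model_grid <- function(table, grid = default_model_grid(),
                           method = "ML", keep_fits = FALSE) {
  sexes <- sort(unique(table$sex))
  rows <- list()
  for (sx in sexes) {
    sub <- table[table$sex == sx, ]
    for (ci in seq_along(grid)) {
      spec <- grid[[ci]]
      t0 <- proc.time()[["elapsed"]]
      fit <- tryCatch(fit_lmm(sub, spec, method = method),
                      error = function(e) {
                        f <- list(status = "error",
                                  message = conditionMessage(e),
                                  loglik = NA_real_, n_params = NA_integer_,
                                  n_obs = nrow(sub), spec = spec)
                        class(f) <- "traj_lmm"
                        f
                      })
      dt <- proc.time()[["elapsed"]] - t0
      dg <- if (fit$status != "error") diagnostics(fit, sub) else
        tibble::tibble(aic = NA_real_, bic = NA_real_, rmse = NA_real_,
                       residual_sd = NA_real_, icc = NA_real_,
                       r2_marginal = NA_real_, r2_conditional = NA_real_)
      row <- tibble::tibble(
        cell = ci, sex = sx,
        fixed = format_spec(spec$fixed), random = format_spec(spec$random),
        correlation = spec$correlation,
        status = fit$status, message = fit$message %||% "",
        logLik = fit$loglik, n_params = fit$n_params,
        AIC = dg$aic, BIC = dg$bic, rmse = dg$rmse, icc = dg$icc,
        r2_marginal = dg$r2_marginal, r2_conditional = dg$r2_conditional,
        runtime_s = dt)
      if (keep_fits) row$fit <- list(fit)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$sex,
                        factor(.data$status, c("ok", "warning", "error")),
                        .data$AIC)
  dplyr::mutate(dplyr::group_by(out, .data$sex),
                rank = dplyr::row_number()) |> dplyr::ungroup()
}

#' Select the preferred model across cohorts
#'
#' A spec is eligible only if it fitted with status `ok` in every cohort
#' and sex. Among eligible specs the summed AIC decides, with summed BIC
#' and then parameter count as tie-breaks. Better-AIC specs that were
#' ineligible (a warning or error somewhere) are reported alongside, since
#' they are the natural sensitivity models.
#'
#' @param grids Named list of [run_model_grid()] tibbles, one per cohort.
#' @param grid The model grid the tibbles came from (to return the chosen
#'   [model_spec()]).
#' @return List with `spec` (chosen [model_spec()]), `cell` (its grid
#'   index), `table` (per-cell summary across cohorts) and `ineligible_better`
#'   (cells with smaller summed AIC that were excluded).
#' @export
select_preferred <- function(grids, grid = default_model_grid()) {
  stopifnot(length(grids) >= 1)
  all_rows <- dplyr::bind_rows(grids, .id = "cohort")
  per_cell <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$cell, .data$fixed, .data$random,
                    .data$correlation),
    n_fits = dplyr::n(),
    n_ok = sum(.data$status == "ok"),
    n_warning = sum(.data$status == "warning"),
    n_error = sum(.data$status == "error"),
    sum_aic = sum(.data$AIC, na.rm = TRUE), sum_bic = sum(.data$BIC, na.rm = TRUE),
    n_params = max(.data$n_params), .groups = "drop")
  per_cell$sum_aic[per_cell$n_ok + per_cell$n_warning == 0] <- Inf
  per_cell$eligible <- per_cell$n_ok == per_cell$n_fits
  elig <- per_cell[per_cell$eligible & is.finite(per_cell$sum_aic), ]
  if (nrow(elig) == 0) {
    # fall back to the fewest-failure spec
    per_cell <- dplyr::arrange(per_cell, .data$n_error + .data$n_warning,
                               .data$sum_aic)
    chosen <- per_cell[1, ]
    warning("no spec converged cleanly everywhere; falling back to the ",
            "fewest-failure spec (cell ", chosen$cell, ")")
  } else {
    elig <- dplyr::arrange(elig, .data$sum_aic, .data$sum_bic, .data$n_params)
    chosen <- elig[1, ]
  }
  ineligible_better <- per_cell[!per_cell$eligible &
                                  is.finite(per_cell$sum_aic) &
                                  per_cell$sum_aic < chosen$sum_aic, ]
  list(spec = grid[[chosen$cell]], cell = chosen$cell, table = per_cell,
       ineligible_better = ineligible_better)
}

#' Refine cubic-spline knot placement
#'
#' Fits the base model over a grid of first and second knots (third knot
#' held fixed), and reports, per combination and sex, the information
#' criteria together with the mean estimated ages at the adiposity peak and
#' rebound. The recommended combination is the lowest summed AIC among
#' combinations whose mean AP age falls inside a plausibility window
#' (default 0.5-1.0 years, consistent with the reported average peak near
#' nine months).
#'
#' @param table Modelling tibble.
#' @param base_spec A cubic-spline [model_spec()]; knots are replaced by
#'   the grid values.
#' @param knot1,knot2 Candidate first/second knots (defaults
#'   `c(1, 1.5, 2)` and `c(6, 7, 8)`).
#' @param knot3 Fixed third knot (default 12).
#' @param ap_window Plausible mean AP age window (years).
#' @param range Prediction range for phenotype estimation.
#' @return List with `report` (one row per combination x sex) and
#'   `recommended` (the chosen `c(knot1, knot2, knot3)`, or `NULL` when all
#'   cells failed).
#' @export
refine_knots <- function(table, base_spec, knot1 = c(1, 1.5, 2),
                         knot2 = c(6, 7, 8), knot3 = 12,
                         ap_window = c(0.5, 1.0), range = c(2 / 52, 17)) {
  stopifnot(base_spec$fixed$form == "cubic_spline")
  sexes <- sort(unique(table$sex))
  rows <- list()
  for (k1 in knot1) {
    for (k2 in knot2) {
      knots <- c(k1, k2, knot3)
      spec <- model_spec(spline_spec("cubic_spline", knots),
                         base_spec$random, base_spec$correlation,
                         base_spec$covariates)
      for (sx in sexes) {
        sub <- table[table$sex == sx, ]
        fit <- tryCatch(fit_lmm(sub, spec), error = function(e) NULL)
        if (is.null(fit) || fit$status == "error") {
          rows[[length(rows) + 1]] <- tibble::tibble(
            knot1 = k1, knot2 = k2, knot3 = knot3, sex = sx,
            status = "error", AIC = NA_real_, BIC = NA_real_,
            mean_ap_age = NA_real_, mean_ar_age = NA_real_)
          next
        }
        ph <- derive_phenotypes(fit, sub, range = range)
        dg <- diagnostics(fit, sub)
        rows[[length(rows) + 1]] <- tibble::tibble(
          knot1 = k1, knot2 = k2, knot3 = knot3, sex = sx,
          status = fit$status, AIC = dg$aic, BIC = dg$bic,
          mean_ap_age = mean(ph$ap_age, na.rm = TRUE),
          mean_ar_age = mean(ph$ar_age, na.rm = TRUE))
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  agg <- dplyr::summarise(
    dplyr::group_by(report, .data$knot1, .data$knot2, .data$knot3),
    all_ok = all(.data$status != "error"),
    sum_aic = sum(.data$AIC),
    ap = mean(.data$mean_ap_age), .groups = "drop")
  agg <- agg[agg$all_ok & is.finite(agg$sum_aic), ]
  plaus <- agg[!is.na(agg$ap) & agg$ap >= ap_window[1] &
                 agg$ap <= ap_window[2], ]
  pick <- if (nrow(plaus)) plaus else agg
  recommended <- if (nrow(pick)) {
    pick <- dplyr::arrange(pick, .data$sum_aic)
    c(pick$knot1[1], pick$knot2[1], pick$knot3[1])
  } else {
    NULL
  }
  list(report = report, recommended = recommended)
}
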