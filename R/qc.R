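#' QC configuration for longitudinal anthropometry cleaning
#'
#' Thresholds for the implausible-value flag taxonomy applied by
#' [flag_records()]. Defaults: extreme robust z cutoff 25, unit-switch
#' detection window (|z| > 5 falling to |z| < 2 after conversion), 3 cm
#' sequential height decrease, EWMA half-life 0.5 years with a 3-robust-SD
#' moderate-outlier cutoff, and an error-load threshold of 0.5 (subjects with
#' more than half their records flagged are excluded entirely).
#'
#' @param z_extreme Robust z-score beyond which a value is an extreme error.
#' @param z_unit_high,z_unit_low Unit-switch rule: flag when |z| exceeds
#'   `z_unit_high` and the value divided (or multiplied) by 2.2046 has
#'   |z| below `z_unit_low`.
#' @param height_drop_cm Maximum tolerated sequential height decrease (cm).
#' @param ewma_halflife Half-life (years) of the exponentially weighted
#'   moving average used for moderate outliers.
#' @param ewma_c Moderate-outlier cutoff in robust SD units.
#' @param error_load Flagged fraction above which a subject's remaining
#'   records are also excluded.
#' @param pair_z Single-measurement height/weight z mismatch cutoff.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(z_extreme = 25, z_unit_high = 5, z_unit_low = 2,
                      height_drop_cm = 3, ewma_halflife = 0.5, ewma_c = 3,
                      error_load = 0.5, pair_z = 5) {
  structure(as.list(environment()), class = "qc_config")
}

lb_per_kg <- 2.2046

# Robust z within sex x age bin against the cohort median/MAD. Bins are
# quarter-years in infancy (where weight doubles within months), half-years
# from 1 to 2 and whole years above; bins with fewer than 20 records give
# NA (no z-based flagging there - a sparse bin cannot provide a stable
# reference and false flags would cluster at the age extremes).
qc_age_bin <- function(age) {
  ifelse(age < 1, floor(age * 4) / 4,
         ifelse(age < 2, floor(age * 2) / 2, floor(age)))
}

robust_z <- function(value, age, sex, candidate = NULL) {
  key <- paste(sex, qc_age_bin(age))
  n_bin <- stats::ave(value, key, FUN = length)
  med <- stats::ave(value, key, FUN = function(v) stats::median(v, na.rm = TRUE))
  mad <- stats::ave(value, key, FUN = function(v) {
    m <- stats::mad(v, na.rm = TRUE)
    if (!is.finite(m) || m == 0) stats::sd(v, na.rm = TRUE) else m
  })
  mad[!is.finite(mad) | mad == 0] <- Inf
  target <- if (is.null(candidate)) value else candidate
  z <- (target - med) / mad
  z[n_bin < 20] <- NA_real_
  z
}

# EWMA of the subject's *other* measurements, weighted by age distance
ewma_other <- function(value, age, halflife) {
  n <- length(value)
  if (n < 3) return(rep(NA_real_, n))
  out <- numeric(n)
  lam <- log(2) / halflife
  for (j in seq_len(n)) {
    w <- exp(-lam * abs(age - age[j]))
    w[j] <- 0
    ok <- is.finite(value) & w > 0
    out[j] <- if (any(ok)) sum(w[ok] * value[ok]) / sum(w[ok]) else NA_real_
  }
  out
}

#' Flag implausible values in longitudinal height/weight data
#'
#' Applies, in order: missing/non-positive components; same-day duplicates
#' (first record kept); carried-forward values (height and weight both
#' identical to the previous visit); weight unit switches (robust z collapses
#' from beyond `z_unit_high` to within `z_unit_low` after converting by
#' 2.2046); extreme robust z-scores; sequential height decreases beyond
#' `height_drop_cm`; single-measurement height/weight z mismatch; moderate
#' outliers against an exponentially weighted moving average of the subject's
#' other measurements; and finally error load (subjects with a large flagged
#' fraction are excluded entirely). Robust z-scores are computed against the
#' cohort median/MAD within sex and age bins, so no external growth
#' reference is needed.
#'
#' @param records Tibble with columns `iid`, `sex`, `age`, `weight_kg`,
#'   `height_cm`, sorted by (`iid`, `age`).
#' @param config A [qc_config()].
#' @return List with `records` (input plus a `flag` character column, `""`
#'   when clean) and `summary` (tibble of counts per flag).
#' @export
flag_records <- function(records, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  req <- c("iid", "sex", "age", "weight_kg", "height_cm")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(records$sex %in% c("male", "female"))) {
    stop("unknown sex code; expected 'male'/'female'")
  }
  ord <- order(records$iid, records$age)
  if (!identical(ord, seq_len(nrow(records)))) {
    stop("records must be sorted by (iid, age)")
  }
  x <- records
  x$flag <- rep("", nrow(x))
  mark <- function(idx, f) {
    new <- idx[x$flag[idx] == ""]
    x$flag[new] <<- f
    invisible(new)
  }

  # 1. missing or non-positive component
  mark(which(!is.finite(x$weight_kg) | !is.finite(x$height_cm) |
               x$weight_kg <= 0 | x$height_cm <= 0), "missing_component")

  # 2. same-day duplicate: identical subject and day; keep first in file order
  day <- round(x$age * 365.25)
  mark(which(duplicated(paste(x$iid, day))), "same_day_duplicate")

  # 3. carried forward: both measures identical to the previous visit
  prev_same <- c(FALSE, x$iid[-1] == x$iid[-nrow(x)])
  cf <- prev_same &
    x$weight_kg == dplyr::lag(x$weight_kg) &
    x$height_cm == dplyr::lag(x$height_cm)
  mark(which(cf %in% TRUE), "carried_forward")

  ok <- x$flag == ""
  zw <- rep(NA_real_, nrow(x))
  zw[ok] <- robust_z(x$weight_kg[ok], x$age[ok], x$sex[ok])
  zh <- rep(NA_real_, nrow(x))
  zh[ok] <- robust_z(x$height_cm[ok], x$age[ok], x$sex[ok])

  # 4. unit switch: z collapses after converting pounds<->kg
  zw_div <- rep(NA_real_, nrow(x))
  zw_mul <- rep(NA_real_, nrow(x))
  zw_div[ok] <- robust_z_sub(x$weight_kg[ok] / lb_per_kg,
                             x$weight_kg[ok], x$age[ok], x$sex[ok])
  zw_mul[ok] <- robust_z_sub(x$weight_kg[ok] * lb_per_kg,
                             x$weight_kg[ok], x$age[ok], x$sex[ok])
  us <- (abs(zw) > config$z_unit_high) &
    (abs(zw_div) < config$z_unit_low | abs(zw_mul) < config$z_unit_low)
  mark(which(us %in% TRUE), "unit_switch")

  # 5. extreme z
  mark(which((abs(zw) > config$z_extreme | abs(zh) > config$z_extreme) %in% TRUE),
       "extreme_z")

  # 6. sequential height decrease > threshold (against last unflagged height)
  hd <- logical(nrow(x))
  for (g in split(seq_len(nrow(x)), x$iid)) {
    last <- NA_real_
    for (j in g) {
      if (x$flag[j] != "") next
      if (is.finite(last) && x$height_cm[j] < last - config$height_drop_cm) {
        hd[j] <- TRUE
      } else {
        last <- x$height_cm[j]
      }
    }
  }
  mark(which(hd), "height_decrease")

  # 7. single measurement whose height and weight z disagree wildly
  n_per <- stats::ave(seq_len(nrow(x)), x$iid, FUN = length)
  pm <- n_per == 1 & abs(zw - zh) > config$pair_z &
    pmin(abs(zw), abs(zh)) > config$z_unit_low
  mark(which(pm %in% TRUE), "single_measure_pair_mismatch")

  # 8. moderate outliers vs subject EWMA, scaled by the cohort-wide robust
  # SD of EWMA residuals for that measure. Two normalisations matter here:
  # the comparison runs on the log scale (measurement error in anthropometry
  # is multiplicative, so kg-scale residuals at 18 years dwarf infancy ones
  # and a common threshold would misflag all older records), and on
  # age-adjusted values (cohort sex/age-bin median removed: raw growth
  # curves trend upward, so at a subject's first or last visit an EWMA of
  # the remaining visits is one-sided and would flag the trajectory tails).
  ok <- x$flag == ""
  for (measure in c("weight_kg", "height_cm")) {
    lv <- log(x[[measure]])
    lv[!is.finite(lv)] <- NA_real_
    adj <- lv - median_curve(lv, x$age, x$sex)
    resid <- rep(NA_real_, nrow(x))
    for (g in split(which(ok), x$iid[ok])) {
      if (length(g) < 3) next
      mu <- ewma_other(adj[g], x$age[g], config$ewma_halflife)
      resid[g] <- adj[g] - mu
    }
    scale <- 1.4826 * stats::median(abs(resid), na.rm = TRUE)
    if (is.finite(scale) && scale > 0) {
      mark(which((abs(resid) > config$ewma_c * scale) %in% TRUE),
           "moderate_outlier_ewma")
    }
  }

  # 9. error load: subjects with too high a flagged fraction lose all records
  frac <- stats::ave(x$flag != "", x$iid, FUN = mean)
  mark(which(frac > config$error_load), "error_load")

  counts <- table(x$flag[x$flag != ""])
  summary <- tibble::tibble(flag = names(counts), n = as.integer(counts),
                            pct = round(100 * as.integer(counts) / nrow(x), 2))
  list(records = x, summary = summary)
}

# z of a candidate replacement value against the *original* cohort bins
robust_z_sub <- function(candidate, value, age, sex) {
  robust_z(value, age, sex, candidate = candidate)
}

# Cohort median growth curve evaluated at each record's exact age: per-sex
# bin medians at the bin centres, linearly interpolated. A step-function
# median leaves the within-bin growth trend in the residuals, which in
# infancy is many times the measurement noise.
median_curve <- function(lv, age, sex) {
  out <- rep(NA_real_, length(lv))
  for (sx in unique(sex)) {
    s <- sex == sx
    bin <- qc_age_bin(age[s])
    meds <- tapply(lv[s], bin, stats::median, na.rm = TRUE)
    centres <- as.numeric(names(meds)) +
      ifelse(as.numeric(names(meds)) < 1, 0.125,
             ifelse(as.numeric(names(meds)) < 2, 0.25, 0.5))
    keep <- is.finite(meds)
    if (sum(keep) >= 2) {
      out[s] <- stats::approx(centres[keep], meds[keep], xout = age[s],
                              rule = 2)$y
    } else if (sum(keep) == 1) {
      out[s] <- meds[keep]
    }
  }
  out
}

#' Derive the log-BMI modelling table from flagged records
#'
#' Drops every flagged record, excludes multiple births when an indicator
#' column is present, restricts to the analysis age window, and computes
#' `log_bmi = log(weight_kg / height_m^2)`.
#'
#' @param flagged Output of [flag_records()], or a records tibble already
#'   carrying a `flag` column.
#' @param min_age,max_age Analysis window in years (default two weeks to 18
#'   years; use 16 for cohorts with sparse data beyond that age).
#' @return Tibble with `iid`, `sex`, `age`, `log_bmi` and any `source`
#'   column, one row per retained measurement.
#' @export
derive_analysis_set <- function(flagged, min_age = 2 / 52, max_age = 18) {
  x <- if (is.list(flagged) && !is.data.frame(flagged)) flagged$records else flagged
  if (!"flag" %in% names(x)) stop("records must be flagged first")
  x <- x[x$flag == "", ]
  if ("multiple_birth" %in% names(x)) x <- x[!(x$multiple_birth %in% TRUE), ]
  x <- x[x$age >= min_age & x$age <= max_age, ]
  h_m <- x$height_cm / 100
  out <- tibble::tibble(iid = x$iid, sex = x$sex, age = x$age,
                        log_bmi = log(x$weight_kg / h_m^2))
  if ("source" %in% names(x)) out$source <- x$source
  out
}
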