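# Default population mean curve on the log-BMI scale: cubic spline in age
# with knots at 1, 8 and 12 years, chosen so the implied BMI curve shows the
# canonical childhood shape (rise to an adiposity peak just before age 1,
# decline to a rebound near age 5.5, rise through adolescence; ~14 kg/m^2 at
# two weeks, ~17.9 at the peak, ~15.5 at the rebound, ~22 at 18 years).
sim_default_beta <- c(2.6430937, 0.8268557, -0.8997274, 0.3027894,
                      -0.3030102, -0.00014390, 0.00017540)

# Random cubic-slope covariance (intercept, age, age^2, age^3). Scales and
# correlations chosen so subject-level SDs are realistic for child BMI:
# ~5% of BMI in infancy growing to ~20% at 18 years, adiposity-peak BMI SD
# near 1 kg/m^2 and rebound-age SD slightly above 1 year. The strong
# negative correlations between adjacent polynomial terms keep individual
# curves from diverging at the upper end of the age range.
sim_default_G <- local({
  s <- c(0.05, 0.03, 0.004, 0.00012)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.2
  R[1, 3] <- R[3, 1] <- 0.1
  R[1, 4] <- R[4, 1] <- -0.1
  R[2, 3] <- R[3, 2] <- -0.9
  R[2, 4] <- R[4, 2] <- 0.75
  R[3, 4] <- R[4, 3] <- -0.95
  G <- diag(s) %*% R %*% diag(s)
  dimnames(G) <- list(c("(Intercept)", "age", "age2", "age3"),
                      c("(Intercept)", "age", "age2", "age3"))
  G
})

# Typical well-child / school visit ages (years), two weeks to 18 years;
# with jitter this yields 8-20 usable measures per child.
sim_default_schedule <- list(
  ages = c(2 / 52, 0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10,
           12, 14, 16, 18),
  jitter_sd = 0.08)

#' Simulation configuration for a synthetic growth cohort
#'
#' Collects every parameter of the generative model: a spline mean curve for
#' log BMI, a multivariate-normal distribution of subject-level random
#' coefficients, residual noise with optional CAR(1) serial correlation, a
#' simple visit schedule, and (optionally) SNP dosages whose effects act
#' additively on named random coefficients. Defaults emulate a
#' population-based birth cohort followed from two weeks to 18 years.
#'
#' @param n_subjects Number of children.
#' @param visit_schedule List with `ages` (mean visit ages, years) and
#'   `jitter_sd` (SD of Normal jitter, truncated to `age_range`).
#' @param age_range Two-element numeric, minimum and maximum age in years.
#' @param beta Fixed-effect coefficients for `fixed_spec`.
#' @param fixed_spec [spline_spec()] of the mean curve.
#' @param random_spec [spline_spec()] of the subject-level deviations.
#' @param G Random-effect covariance matrix (symmetric PSD, dimension equal
#'   to the random design).
#' @param sigma Residual SD on the log-BMI scale.
#' @param phi CAR(1) residual correlation parameter in `[0, 1)`; 0 means
#'   independent residuals.
#' @param sex_ratio Fraction male.
#' @param female_shift Added to `beta` for girls (recycled against `beta`);
#'   default lowers the whole curve by 0.025 log units (~0.4 kg/m^2 at the
#'   adiposity peak), matching the typical male-female gap.
#' @param error_rates Named list of per-record fault-injection probabilities
#'   (see [inject_errors()]); all zero by default.
#' @param n_snps Number of simulated variants.
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param snp_effects Data frame with columns `snp` (index in `1:n_snps`),
#'   `coef` (index of the random coefficient hit) and `effect` (added per
#'   dosage unit), or `NULL`.
#' @param seed Integer seed; every random draw is keyed to it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 500,
                       visit_schedule = sim_default_schedule,
                       age_range = c(2 / 52, 18),
                       beta = sim_default_beta,
                       fixed_spec = spline_spec("cubic_spline", c(1, 8, 12)),
                       random_spec = spline_spec("cubic_slope"),
                       G = sim_default_G,
                       sigma = 0.05,
                       phi = 0,
                       sex_ratio = 0.5,
                       female_shift = c(-0.025, rep(0, length(beta) - 1)),
                       error_rates = list(),
                       n_snps = 0,
                       maf_range = c(0.05, 0.5),
                       snp_effects = NULL,
                       seed = 1L) {
  if (length(visit_schedule$ages) == 0) stop("visit schedule must be non-empty")
  if (!isTRUE(all.equal(G, t(G))) || min(eigen(G, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-10) {
    stop("G must be symmetric positive semi-definite")
  }
  stopifnot(sigma >= 0, phi >= 0, phi < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            length(beta) == ncol(design_matrix(0, fixed_spec)),
            nrow(G) == ncol(design_matrix(0, random_spec)))
  if (!is.null(snp_effects)) {
    stopifnot(all(c("snp", "coef", "effect") %in% names(snp_effects)),
              all(snp_effects$snp <= n_snps),
              all(snp_effects$coef <= nrow(G)))
  }
  bad <- setdiff(names(error_rates),
                 c("same_day_duplicate", "unit_switch", "carried_forward",
                   "height_decrease", "gross_outlier"))
  if (length(bad)) stop("unknown error types: ", paste(bad, collapse = ", "))
  if (length(error_rates) && (any(unlist(error_rates) < 0) ||
                              any(unlist(error_rates) > 1))) {
    stop("error rates must lie in [0, 1]")
  }
  structure(list(n_subjects = n_subjects, visit_schedule = visit_schedule,
                 age_range = age_range, beta = beta, fixed_spec = fixed_spec,
                 random_spec = random_spec, G = G, sigma = sigma, phi = phi,
                 sex_ratio = sex_ratio, female_shift = female_shift,
                 error_rates = error_rates, n_snps = n_snps,
                 maf_range = maf_range, snp_effects = snp_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-subject sub-streams so subject i's data do not depend
# on how many other subjects are generated. Seeds are drawn from one
# well-mixed global stream keyed by the master seed (the i-th draw depends
# only on the master seed and i): seeding subject streams from a linear
# formula in i leaves detectable cross-stream correlation that inflates the
# sampling variance of cohort-level estimates.
subject_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  as.integer(floor(stats::runif(n) * 2147483645)) + 1L
}

# simple monotone stature curve (m): normalised logistic from 0.50 m at birth
# to 1.72 m at 18 years; only monotonicity and rough plausibility matter,
# since BMI is simulated directly and weight is back-derived
sim_height_m <- function(age) {
  L <- function(t) 1 / (1 + exp(-0.25 * (t - 5)))
  0.50 + (1.72 - 0.50) * (L(age) - L(0)) / (L(18) - L(0))
}

#' Simulate a longitudinal growth cohort with known ground truth
#'
#' Draws visit ages from the schedule, subject random coefficients from
#' `MVN(0, G)`, residuals from `MVN(0, sigma^2 C(phi))` with a CAR(1)
#' correlation matrix, and sets
#' `log BMI = X beta + Z b_i + eps`. Height follows a fixed monotone growth
#' curve with small subject and measurement variation, and weight is
#' back-derived so that `weight / height_m^2` reproduces the simulated BMI
#' exactly. SNP dosages are Binomial(2, MAF) and any configured SNP effects
#' are added to the named random coefficient before trajectories are formed,
#' so genetic effects on slopes/AUCs have known truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `records` (tibble:
#'   `iid`, `sex`, `age`, `weight_kg`, `height_cm`, `source`), `subjects`
#'   (truth tibble of random coefficients per subject, including any genetic
#'   shift), `genotypes` (dosage matrix, subjects x SNPs, or `NULL`),
#'   `variants` (tibble of SNP metadata or `NULL`), `ledger` (planted-fault
#'   ledger from [inject_errors()], empty when no error rates are set) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  iid <- sprintf("S%05d", seq_len(n))

  set.seed(config$seed)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")

  genotypes <- NULL
  variants <- NULL
  if (config$n_snps > 0) {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    genotypes <- vapply(maf, function(m) stats::rbinom(n, 2, m), numeric(n))
    rownames(genotypes) <- iid
    colnames(genotypes) <- sprintf("rs%06d", seq_len(config$n_snps))
    # allele pairs are a deterministic function of the variant index, so
    # cohorts simulated with different seeds share an imputation panel
    pairs <- list(c("A", "G"), c("T", "C"), c("A", "C"), c("T", "G"))
    pr <- pairs[1 + (seq_len(config$n_snps) - 1) %% 4]
    variants <- tibble::tibble(
      snp = colnames(genotypes),
      chrom = as.character(1 + (seq_len(config$n_snps) - 1) %% 22),
      pos = 1e6 + 5e4 * seq_len(config$n_snps),
      ea = vapply(pr, `[`, "", 1), oa = vapply(pr, `[`, "", 2),
      eaf = maf, info = 1)
  }

  q <- nrow(config$G)
  Lg <- chol_psd(config$G)
  recs <- vector("list", n)
  b_true <- matrix(0, n, q)
  sseeds <- subject_seeds(config$seed + 1L, n)
  for (i in seq_len(n)) {
    set.seed(sseeds[i])
    ages <- config$visit_schedule$ages +
      stats::rnorm(length(config$visit_schedule$ages),
                   sd = config$visit_schedule$jitter_sd)
    ages <- sort(pmin(pmax(ages, config$age_range[1]), config$age_range[2]))
    b <- drop(Lg %*% stats::rnorm(q))
    if (!is.null(config$snp_effects) && config$n_snps > 0) {
      for (r in seq_len(nrow(config$snp_effects))) {
        se_r <- config$snp_effects[r, ]
        b[se_r$coef] <- b[se_r$coef] + genotypes[i, se_r$snp] * se_r$effect
      }
    }
    b_true[i, ] <- b
    beta_i <- config$beta +
      if (sex[i] == "female") config$female_shift else 0
    X <- design_matrix(ages, config$fixed_spec)
    Z <- design_matrix(ages, config$random_spec)
    mu <- drop(X %*% beta_i + Z %*% b)
    eps <- if (config$sigma > 0) {
      Ce <- car1_matrix(ages, config$phi)
      drop(chol_psd(Ce) %*% stats::rnorm(length(ages))) * config$sigma
    } else {
      rep(0, length(ages))
    }
    log_bmi <- mu + eps
    h <- sim_height_m(ages) * exp(stats::rnorm(1, sd = 0.02)) +
      stats::rnorm(length(ages), sd = 0.003)
    w <- exp(log_bmi) * h^2
    recs[[i]] <- tibble::tibble(iid = iid[i], sex = sex[i], age = ages,
                                weight_kg = w, height_cm = h * 100,
                                source = "clinic")
  }
  records <- dplyr::bind_rows(recs)
  colnames(b_true) <- paste0("b", seq_len(q) - 1)
  subjects <- tibble::tibble(iid = iid, sex = sex)
  subjects <- dplyr::bind_cols(subjects, tibble::as_tibble(b_true))

  ledger <- tibble::tibble(iid = character(), age = numeric(),
                           type = character())
  if (length(config$error_rates) && any(unlist(config$error_rates) > 0)) {
    inj <- inject_errors(records, config$error_rates,
                         seed = config$seed + 7L)
    records <- inj$records
    ledger <- inj$ledger
  }
  structure(list(records = records, subjects = subjects,
                 genotypes = genotypes, variants = variants,
                 ledger = ledger, config = config),
            class = "sim_cohort")
}

# Cholesky-like factor that tolerates PSD (zero-variance) matrices
chol_psd <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", x$config$n_subjects, " subjects, ",
      nrow(x$records), " records, ",
      if (is.null(x$genotypes)) 0 else ncol(x$genotypes), " SNPs, ",
      nrow(x$ledger), " planted faults\n", sep = "")
  invisible(x)
}

#' Plant data errors in a measurement table
#'
#' Injects the fault types a growth-data cleaning step must catch:
#' same-day duplicate rows, weight unit switches (kg recorded as pounds,
#' i.e. multiplied by 2.2046), carried-forward values (height and weight
#' copied from the previous visit), height decreases of more than 3 cm
#' between sequential visits, and gross outliers. Every planted fault is
#' written to a ledger so cleaning sensitivity/specificity can be scored.
#'
#' @param records Clean measurement tibble as produced by
#'   [simulate_cohort()].
#' @param error_rates Named list of per-record probabilities for
#'   `same_day_duplicate`, `unit_switch`, `carried_forward`,
#'   `height_decrease`, `gross_outlier`.
#' @param seed Integer seed.
#' @return List with `records` (faulted table) and `ledger` (tibble:
#'   `iid`, `age`, `type`).
#' @export
inject_errors <- function(records, error_rates, seed = 1L) {
  rates <- unlist(error_rates)
  if (length(rates) && (any(rates < 0) || any(rates > 1))) {
    stop("error rates must lie in [0, 1]")
  }
  get_rate <- function(nm) if (is.null(error_rates[[nm]])) 0 else error_rates[[nm]]
  set.seed(as.integer(seed))
  out <- records
  out$.row <- seq_len(nrow(out))
  ledger <- list()
  note <- function(rows, type) {
    if (length(rows)) {
      ledger[[length(ledger) + 1]] <<- tibble::tibble(
        iid = out$iid[match(rows, out$.row)],
        age = out$age[match(rows, out$.row)], type = type)
    }
  }

  # carried forward: overwrite a record with the previous visit's values
  r <- get_rate("carried_forward")
  if (r > 0) {
    eligible <- which(!duplicated(out$iid))  # first visit has no previous
    eligible <- setdiff(seq_len(nrow(out)), eligible)
    hit <- eligible[stats::runif(length(eligible)) < r]
    for (j in hit) {
      out$weight_kg[j] <- out$weight_kg[j - 1]
      out$height_cm[j] <- out$height_cm[j - 1]
    }
    note(out$.row[hit], "carried_forward")
  }

  # unit switch: weight recorded in pounds
  r <- get_rate("unit_switch")
  if (r > 0) {
    hit <- which(stats::runif(nrow(out)) < r)
    out$weight_kg[hit] <- out$weight_kg[hit] * 2.2046
    note(out$.row[hit], "unit_switch")
  }

  # height decrease: drop one height by 3-6 cm relative to the previous visit
  r <- get_rate("height_decrease")
  if (r > 0) {
    eligible <- setdiff(seq_len(nrow(out)), which(!duplicated(out$iid)))
    hit <- eligible[stats::runif(length(eligible)) < r]
    for (j in hit) {
      out$height_cm[j] <- out$height_cm[j - 1] - (3 + stats::runif(1, 0.1, 3))
    }
    note(out$.row[hit], "height_decrease")
  }

  # gross outlier: implausible weight (z-score far beyond 25)
  r <- get_rate("gross_outlier")
  if (r > 0) {
    hit <- which(stats::runif(nrow(out)) < r)
    out$weight_kg[hit] <- out$weight_kg[hit] * 40
    note(out$.row[hit], "gross_outlier")
  }

  # same-day duplicates: append a copy of the record at the same age
  r <- get_rate("same_day_duplicate")
  if (r > 0) {
    hit <- which(stats::runif(nrow(out)) < r)
    if (length(hit)) {
      dup <- out[hit, ]
      dup$weight_kg <- dup$weight_kg * exp(stats::rnorm(nrow(dup), sd = 0.005))
      dup$.row <- -seq_along(hit)
      out <- dplyr::bind_rows(out, dup)
      out <- dplyr::arrange(out, .data$iid, .data$age, dplyr::desc(.data$.row >= 0))
      note(dup$.row, "same_day_duplicate")
    }
  }

  ledger <- if (length(ledger)) dplyr::bind_rows(ledger) else
    tibble::tibble(iid = character(), age = numeric(), type = character())
  out$.row <- NULL
  list(records = out, ledger = ledger)
}
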