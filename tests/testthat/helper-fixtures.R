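# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

eq1_spec <- function(correlation = "none") {
  model_spec(spline_spec("cubic_spline", c(1, 8, 12)),
             spline_spec("cubic_slope"), correlation = correlation)
}

# a small clean cohort plus its male modelling table and fit
small_cohort <- function() {
  cached("small_cohort", function() {
    cfg <- sim_config(n_subjects = 200, seed = 101)
    ch <- simulate_cohort(cfg)
    tab <- derive_analysis_set(flag_records(ch$records))
    males <- tab[tab$sex == "male", ]
    fit <- fit_lmm(males, eq1_spec())
    list(cfg = cfg, cohort = ch, tab = tab, males = males, fit = fit)
  })
}

# hand-built fit object for closed-form checks (no estimation involved)
fake_fit <- function(beta, spec = eq1_spec(), G = NULL, sigma2 = 1e-4) {
  q <- ncol(design_matrix(0, spec$random))
  if (is.null(G)) G <- diag(q) * 0
  fit <- list(beta = stats::setNames(beta,
                                     c("(Intercept)",
                                       trajgwas:::spline_colnames(spec$fixed))),
              G = G, sigma2 = sigma2, phi = NA_real_, loglik = NA_real_,
              n_params = length(beta), n_subjects = 0L, n_obs = 0L,
              status = "ok", message = "", spec = spec, method = "ML",
              scales = NULL, engine = "manual", fit = NULL)
  class(fit) <- "traj_lmm"
  fit
}

# quartic with known interior maximum at m1 and minimum at m2:
# y'(t) = -(t - m1)(t - m2)(t - m3), m3 outside the search window
quartic_curve <- function(ages, m1, m2, m3 = 12, scale = 0.01) {
  s <- m1 + m2 + m3
  p <- m1 * m2 + m1 * m3 + m2 * m3
  q <- m1 * m2 * m3
  # integral of -(t^3 - s t^2 + p t - q)
  scale * (-(ages^4) / 4 + s * ages^3 / 3 - p * ages^2 / 2 + q * ages)
}

# integration oracle: adaptive quadrature split at the knots so the
# integrand is smooth on each piece
quadrature_auc <- function(f, a, b, knots) {
  cuts <- sort(unique(c(a, b, knots[knots > a & knots < b])))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(f, cuts[i], cuts[i + 1],
                                      rel.tol = 1e-12,
                                      abs.tol = 1e-12)$value
  }
  total
}

# ten-row association fixture in which every row trips a pre-meta filter:
# one monomorphic, one multiallelic pair, two indels (REF and ALT side),
# low n, low MAC, beta and se at the >= 10 boundary, low INFO
filter_fixture <- function() {
  base <- tibble::tibble(
    snp = sprintf("rs%02d", 1:10),
    chrom = as.character(1:10), pos = seq(1e6, by = 1e6, length.out = 10),
    ea = "A", oa = "G", eaf = 0.3, info = 0.9, n = 1000,
    beta = 0.05, se = 0.02, p = 0.01, monomorphic = FALSE)
  base$monomorphic[1] <- TRUE
  base$beta[1] <- NA
  base$se[1] <- NA
  base$p[1] <- NA
  base$chrom[2] <- base$chrom[3] <- "11"       # same position twice
  base$pos[2] <- base$pos[3] <- 5e6            # -> multiallelic pair
  base$ea[4] <- "AT"                           # indel
  base$n[5] <- 19                              # low n
  base$eaf[6] <- 0.001                         # MAC = 2*1000*0.001 = 2
  base$beta[7] <- 10                           # extreme beta (boundary)
  base$se[8] <- 10                             # extreme se (boundary)
  base$info[9] <- 0.39                         # low info
  base$oa[10] <- "GG"                          # indel on the other allele
  base
}
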