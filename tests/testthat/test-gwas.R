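gwas_fixture <- function() {
  cached("gwas_fixture", function() {
    cfg <- sim_config(n_subjects = 600, seed = 202, n_snps = 40,
                      snp_effects = data.frame(snp = 3, coef = 2,
                                               effect = 0.02))
    ch <- simulate_cohort(cfg)
    tab <- derive_analysis_set(flag_records(ch$records))
    fits <- lapply(split(tab, tab$sex), fit_lmm, spec = eq1_spec())
    ph <- dplyr::bind_rows(lapply(names(fits), function(sx) {
      derive_phenotypes(fits[[sx]], tab[tab$sex == sx, ])
    }))
    ex <- iqr_exclusion(ph)
    covar <- tibble::tibble(iid = ch$subjects$iid, sex = ch$subjects$sex)
    list(cohort = ch, phenos = ex$filtered, covar = covar)
  })
}

test_that("per-variant OLS equals a full lm refit, planted effect recovered", {
  fx <- gwas_fixture()
  g <- run_gwas(fx$phenos[, c("iid", "slope_infancy")], fx$cohort$genotypes,
                fx$cohort$variants, fx$covar)
  dd <- data.frame(iid = fx$phenos$iid, y = fx$phenos$slope_infancy)
  dd$sex <- fx$covar$sex[match(dd$iid, fx$covar$iid)]
  for (j in c(1, 3, 17)) {
    dd$dos <- fx$cohort$genotypes[dd$iid, j]
    cf <- summary(stats::lm(y ~ dos + sex, dd))$coefficients["dos", ]
    expect_equal(g$beta[j], unname(cf["Estimate"]), tolerance = 1e-10)
    expect_equal(g$se[j], unname(cf["Std. Error"]), tolerance = 1e-10)
    expect_equal(g$p[j], unname(cf["Pr(>|t|)"]), tolerance = 1e-10)
  }
  # SNP 3 carries a +0.02 effect on the linear random coefficient. BLUP
  # shrinkage attenuates per-subject slopes toward the mean, so the GWAS
  # effect is recovered up to a modest shrinkage distortion.
  expect_gt(g$beta[3], 0.5 * 0.02)
  expect_lt(g$beta[3], 1.5 * 0.02)
  expect_lt(g$p[3], 1e-6)
})

test_that("constant dosages are flagged monomorphic, never crash", {
  fx <- gwas_fixture()
  dos <- fx$cohort$genotypes
  dos[, 2] <- 0
  g <- run_gwas(fx$phenos[, c("iid", "slope_infancy")], dos,
                fx$cohort$variants, fx$covar)
  expect_true(g$monomorphic[2])
  expect_true(is.na(g$beta[2]))
  expect_false(any(g$monomorphic[-2]))
})

test_that("each pre-meta filter removes its constructed row", {
  fx <- filter_fixture()
  res <- cohort_filters(fx)
  expect_equal(nrow(res$kept), 0)
  expect_equal(sum(res$ledger$n), 10)
  want <- c(monomorphic = 1, multiallelic = 2, indel = 2, low_n = 1,
            low_mac = 1, extreme_estimate = 2, low_info = 1)
  got <- stats::setNames(res$ledger$n, res$ledger$rule)
  expect_equal(got[names(want)], want)
})

test_that("filter boundaries behave as printed", {
  base <- filter_fixture()[10, ]
  base$oa <- "G"
  ok <- base
  ok$se <- 9.999
  expect_equal(nrow(cohort_filters(ok)$kept), 1)     # just under: kept
  bad <- base
  bad$se <- 10
  expect_equal(nrow(cohort_filters(bad)$kept), 0)    # boundary: removed
  mac3 <- base
  mac3$eaf <- 3 / (2 * mac3$n)                       # MAC exactly 3
  expect_equal(nrow(cohort_filters(mac3)$kept), 0)
  mac4 <- base
  mac4$eaf <- 4 / (2 * mac4$n)                       # MAC 4: kept
  expect_equal(nrow(cohort_filters(mac4)$kept), 1)
  lown <- base
  lown$n <- 19
  expect_equal(cohort_filters(lown)$removed$reason, "low_n")
})

assoc_row <- function(snp = "rs1", chrom = "1", pos = 1e6, ea = "A",
                      oa = "G", eaf = 0.3, beta = 0.05, se = 0.02,
                      n = 1000) {
  tibble::tibble(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa,
                 eaf = eaf, info = 1, n = n, beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)), monomorphic = FALSE)
}

test_that("allele harmonisation flips swapped strands and drops ambiguity", {
  a <- assoc_row()
  b <- assoc_row(ea = "G", oa = "A", eaf = 0.7, beta = -0.05)
  h <- harmonize(list(A = a, B = b))
  expect_equal(h$cohorts$B$beta, 0.05)
  expect_equal(h$cohorts$B$eaf, 0.3)
  expect_equal(h$cohorts$B$ea, "A")

  # A/T variant at EAF 0.49 is unresolvable
  amb <- assoc_row(ea = "A", oa = "T", eaf = 0.49)
  h2 <- harmonize(list(A = amb, B = amb))
  expect_equal(nrow(h2$cohorts$A), 0)
  expect_true("strand_ambiguous" %in% h2$dropped$reason)
  # the same pair away from 0.5 is retained
  amb2 <- assoc_row(ea = "A", oa = "T", eaf = 0.2)
  expect_equal(nrow(harmonize(list(A = amb2, B = amb2))$cohorts$A), 1)

  # identical tables pass through untouched
  h3 <- harmonize(list(A = a, B = a))
  expect_equal(h3$cohorts$B$beta, a$beta)
  expect_equal(nrow(h3$dropped), 0)

  # irreconcilable allele pairs are dropped with a reason
  bad <- assoc_row(ea = "C", oa = "A")
  h4 <- harmonize(list(A = a, B = bad))
  expect_true(all(nrow(h4$cohorts$B) == 0))

  # large EAF differences are flagged but kept
  drift <- assoc_row(eaf = 0.65)
  h5 <- harmonize(list(A = a, B = drift))
  expect_length(h5$eaf_flags, 1)
  expect_equal(nrow(h5$cohorts$B), 1)
})

test_that("IVW meta-analysis identities hold exactly", {
  one <- assoc_row()
  m1 <- ivw_meta(list(A = one))
  expect_equal(m1$beta, one$beta)
  expect_equal(m1$se, one$se)
  expect_equal(m1$direction, "+")

  # equal-se averaging and the Q closed form
  a <- assoc_row(beta = 0.1, se = 0.05)
  b <- assoc_row(beta = 0.3, se = 0.05)
  m2 <- ivw_meta(list(A = a, B = b))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$q_stat, (0.1 - 0.2)^2 / 0.05^2 + (0.3 - 0.2)^2 / 0.05^2)
  expect_equal(m2$q_df, 1)

  # K identical cohorts: se scales as 1/sqrt(K)
  K <- 4
  mk <- ivw_meta(stats::setNames(rep(list(one), K), paste0("C", 1:K)))
  expect_equal(mk$se, one$se / sqrt(K), tolerance = 1e-12)
  expect_equal(mk$direction, "++++")

  # three arbitrary cohorts against brute-force arithmetic
  x <- list(A = assoc_row(beta = 0.12, se = 0.031),
            B = assoc_row(beta = -0.05, se = 0.044),
            C = assoc_row(beta = 0.07, se = 0.025))
  m3 <- ivw_meta(x)
  w <- c(1 / 0.031^2, 1 / 0.044^2, 1 / 0.025^2)
  bvec <- c(0.12, -0.05, 0.07)
  bbar <- sum(w * bvec) / sum(w)
  expect_equal(m3$beta, bbar, tolerance = 1e-12)
  expect_equal(m3$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(m3$q_stat, sum(w * (bvec - bbar)^2), tolerance = 1e-12)
  expect_equal(m3$p, 2 * stats::pnorm(-abs(bbar * sqrt(sum(w)))),
               tolerance = 1e-12)
  expect_equal(m3$direction, "+-+")
  expect_true(m3$i2 >= 0 && m3$i2 <= 100)
})

test_that("Cochran's Q under a common effect has mean near its df", {
  set.seed(99)
  K <- 5
  n_var <- 1000
  se <- 0.05
  cohorts <- lapply(1:K, function(k) {
    assoc_row(snp = sprintf("rs%04d", 1:n_var), chrom = "1",
              pos = seq(1e6, by = 1e4, length.out = n_var),
              beta = 0.1 + stats::rnorm(n_var, sd = se), se = se)
  })
  names(cohorts) <- paste0("C", 1:K)
  m <- ivw_meta(cohorts)
  expect_lt(abs(mean(m$q_stat) - (K - 1)), 0.1 * (K - 1))
})

test_that("post-meta filters apply the cohort-count and MAF rules", {
  a <- assoc_row(snp = c("rs1", "rs2", "rs3"), chrom = "1",
                 pos = c(1e6, 2e6, 3e6))
  b <- a[1:2, ]
  c3 <- a[1, ]
  m <- ivw_meta(list(A = a, B = b, C = c3, D = a, E = a))
  # rs3 present in 3/5 cohorts (>= ceil(5/2) = 3): kept; drop if in 2
  res <- post_meta_filters(m, 5)
  expect_true(all(res$kept$n_cohorts >= 3))
  m2 <- ivw_meta(list(A = a, B = a[1:2, ], C = a[1:2, ], D = a[1:2, ],
                      E = a[1:2, ]))
  res2 <- post_meta_filters(m2, 5)
  expect_false("rs3" %in% res2$kept$snp)
  # MAF < 0.005 dropped
  rare <- assoc_row(eaf = 0.004)
  res3 <- post_meta_filters(ivw_meta(list(A = rare)), 1)
  expect_equal(nrow(res3$kept), 0)
  # two hits 100 kb apart collapse to one clump lead
  hits <- assoc_row(snp = c("rsA", "rsB"), chrom = "2",
                    pos = c(1e6, 1.1e6), beta = c(0.3, 0.28),
                    se = 0.02)
  res4 <- post_meta_filters(ivw_meta(list(A = hits)), 1)
  expect_equal(nrow(res4$hits), 2)
  expect_equal(nrow(res4$leads), 1)
})

test_that("lambda_gc is the median chi-square ratio", {
  set.seed(7)
  p <- stats::runif(5e4)
  expect_equal(lambda_gc(p), 1, tolerance = 0.03)
  expect_gt(lambda_gc(p^2), 1)  # enriched small p inflates lambda
})
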