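#' Additive-dosage GWAS of an estimated phenotype
#'
#' Per-variant ordinary least squares of the phenotype on allelic dosage
#' plus covariates (sex, ancestry PCs, cohort-specific terms). Covariates
#' are projected out of the phenotype and every dosage column once
#' (Frisch-Waugh-Lovell), so the per-variant pass is a handful of vector
#' products — numerically identical to refitting the full model per SNP.
#' Effects are per effect-allele copy; p-values are two-sided t.
#'
#' @param phenotypes Tibble with `iid` and one column per phenotype.
#' @param dosages Numeric matrix, subjects in rows (rownames = iid),
#'   variants in columns.
#' @param variants Tibble of variant metadata: `snp`, `chrom`, `pos`, `ea`,
#'   `oa`, and optionally `eaf` and `info` (recomputed / defaulted when
#'   absent).
#' @param covariates Tibble with `iid` and covariate columns; character
#'   columns are expanded to indicators.
#' @param phenotype Name of the phenotype column to analyse.
#' @return Tibble with one row per variant: `snp`, `chrom`, `pos`, `ea`,
#'   `oa`, `eaf`, `info`, `n`, `beta`, `se`, `p`, `monomorphic`.
#' @export
run_gwas <- function(phenotypes, dosages, variants, covariates,
                     phenotype = setdiff(names(phenotypes), "iid")[1]) {
  stopifnot(phenotype %in% names(phenotypes), "iid" %in% names(covariates))
  ids <- Reduce(intersect, list(phenotypes$iid, rownames(dosages),
                                covariates$iid))
  y <- phenotypes[[phenotype]][match(ids, phenotypes$iid)]
  keep <- !is.na(y)
  ids <- ids[keep]
  y <- y[keep]
  Dm <- dosages[ids, , drop = FALSE]
  cv <- covariates[match(ids, covariates$iid), setdiff(names(covariates), "iid"),
                   drop = FALSE]
  # drop constant covariates (e.g. sex in a single-sex analysis set)
  keep_cv <- vapply(cv, function(v) length(unique(v[!is.na(v)])) > 1,
                    logical(1))
  cv <- cv[, keep_cv, drop = FALSE]
  C <- if (ncol(cv)) {
    stats::model.matrix(~ ., data = as.data.frame(cv))
  } else {
    matrix(1, length(y), 1)
  }
  n <- length(y)
  pcov <- qr(C)
  ry <- qr.resid(pcov, y)
  RG <- qr.resid(pcov, Dm)
  gg <- colSums(RG^2)
  mono <- gg < 1e-12 | matrixStats_colVars(Dm) < 1e-12
  gy <- colSums(RG * ry)
  beta <- gy / gg
  df <- n - pcov$rank - 1L
  rss <- sum(ry^2) - beta^2 * gg
  se <- sqrt(pmax(rss, 0) / df / gg)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  eaf <- if ("eaf" %in% names(variants)) {
    variants$eaf
  } else {
    colMeans(Dm) / 2
  }
  info <- if ("info" %in% names(variants)) variants$info else 1
  out <- tibble::tibble(
    snp = variants$snp, chrom = as.character(variants$chrom),
    pos = variants$pos, ea = variants$ea, oa = variants$oa,
    eaf = eaf, info = info, n = n,
    beta = unname(beta), se = unname(se), p = unname(p),
    monomorphic = unname(mono))
  out$beta[mono] <- NA_real_
  out$se[mono] <- NA_real_
  out$p[mono] <- NA_real_
  out
}

# column variances without an extra dependency
matrixStats_colVars <- function(M) {
  mu <- colMeans(M)
  colSums(M^2) / nrow(M) - mu^2
}

#' Pre-meta-analysis variant filters for one cohort
#'
#' Removes, in order: monomorphic variants, multiallelic sites and indels
#' (alleles longer than one base), low sample size (n < 20), low minor
#' allele count (MAC = 2 n min(eaf, 1-eaf) <= 3), extreme estimates
#' (|beta| >= 10 or se >= 10 phenotype units per allele, boundary
#' inclusive), and poor imputation (INFO < 0.4). Each removal is counted
#' once, against the first rule it trips.
#'
#' @param assoc Association tibble from [run_gwas()].
#' @param mac_min,beta_max,se_max,info_min,n_min Filter thresholds.
#' @return List with `kept` (filtered tibble) and `ledger` (tibble of
#'   per-rule removal counts).
#' @export
cohort_filters <- function(assoc, mac_min = 3, beta_max = 10, se_max = 10,
                           info_min = 0.4, n_min = 20) {
  x <- assoc
  reason <- rep(NA_character_, nrow(x))
  hit <- function(cond, why) {
    idx <- which(is.na(reason) & cond %in% TRUE)
    reason[idx] <<- why
  }
  hit(x$monomorphic | is.na(x$beta), "monomorphic")
  multi <- duplicated(paste(x$chrom, x$pos)) |
    duplicated(paste(x$chrom, x$pos), fromLast = TRUE)
  hit(multi, "multiallelic")
  hit(nchar(x$ea) > 1 | nchar(x$oa) > 1, "indel")
  hit(x$n < n_min, "low_n")
  mac <- 2 * x$n * pmin(x$eaf, 1 - x$eaf)
  hit(mac <= mac_min, "low_mac")
  hit(abs(x$beta) >= beta_max | x$se >= se_max, "extreme_estimate")
  hit(x$info < info_min, "low_info")
  ledger <- tibble::tibble(rule = c("monomorphic", "multiallelic", "indel",
                                    "low_n", "low_mac", "extreme_estimate",
                                    "low_info"))
  ledger$n <- vapply(ledger$rule, function(r) sum(reason %in% r), integer(1))
  list(kept = x[is.na(reason), ], ledger = ledger,
       removed = dplyr::bind_cols(x[!is.na(reason), ],
                                  tibble::tibble(reason = reason[!is.na(reason)])))
}

is_ambiguous <- function(ea, oa) {
  p <- paste(pmin(toupper(ea), toupper(oa)), pmax(toupper(ea), toupper(oa)))
  p %in% c("A T", "C G")
}

#' Harmonise per-cohort association tables to a common effect allele
#'
#' Variants are keyed by chromosome, position and the unordered allele pair.
#' The first cohort acts as the reference: where another cohort reports the
#' alleles swapped, its beta sign and EAF are flipped. Strand-ambiguous
#' (A/T, C/G) variants with EAF near 0.5 (within `ambiguous_eaf_window`)
#' are dropped everywhere, as their orientation cannot be resolved; variants
#' whose allele pairs cannot be reconciled are dropped; EAF differences
#' above `eaf_diff_max` across cohorts are flagged but retained.
#'
#' @param cohorts Named list of filtered association tibbles.
#' @param ambiguous_eaf_window Half-width of the EAF window around 0.5 in
#'   which ambiguous variants are removed (default 0.08).
#' @param eaf_diff_max Cross-cohort EAF difference that triggers a flag
#'   (default 0.2).
#' @return List with `cohorts` (aligned tibbles, same names), `dropped`
#'   (tibble of variant keys and reasons) and `eaf_flags` (keys with large
#'   frequency differences).
#' @export
harmonize <- function(cohorts, ambiguous_eaf_window = 0.08,
                      eaf_diff_max = 0.2) {
  stopifnot(length(cohorts) >= 1)
  key_of <- function(x) {
    paste(sub("^chr", "", x$chrom), x$pos,
          pmin(toupper(x$ea), toupper(x$oa)),
          pmax(toupper(x$ea), toupper(x$oa)), sep = ":")
  }
  ref <- cohorts[[1]]
  ref_key <- key_of(ref)
  dropped <- list()
  out <- vector("list", length(cohorts))
  names(out) <- names(cohorts)
  drop_keys <- character()

  for (nm in names(cohorts)) {
    x <- cohorts[[nm]]
    k <- key_of(x)
    m <- match(k, ref_key)
    in_ref <- !is.na(m)
    x <- x[in_ref, ]
    k <- k[in_ref]
    m <- m[in_ref]
    swap <- toupper(x$ea) != toupper(ref$ea[m])
    irreconcilable <- swap & toupper(x$ea) != toupper(ref$oa[m])
    if (any(irreconcilable)) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        key = k[irreconcilable], cohort = nm, reason = "allele_mismatch")
      drop_keys <- union(drop_keys, k[irreconcilable])
    }
    flip <- swap & !irreconcilable
    x$beta[flip] <- -x$beta[flip]
    x$eaf[flip] <- 1 - x$eaf[flip]
    tmp <- x$ea[flip]
    x$ea[flip] <- x$oa[flip]
    x$oa[flip] <- tmp
    amb <- is_ambiguous(x$ea, x$oa) &
      abs(x$eaf - 0.5) < ambiguous_eaf_window
    if (any(amb)) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        key = k[amb], cohort = nm, reason = "strand_ambiguous")
      drop_keys <- union(drop_keys, k[amb])
    }
    x$key <- k
    out[[nm]] <- x
  }
  for (nm in names(out)) out[[nm]] <- out[[nm]][!(out[[nm]]$key %in% drop_keys), ]

  # flag (not drop) large frequency differences against the reference
  eaf_flags <- character()
  ref_out <- out[[1]]
  for (nm in names(out)[-1]) {
    x <- out[[nm]]
    m <- match(x$key, ref_out$key)
    big <- !is.na(m) & abs(x$eaf - ref_out$eaf[m]) > eaf_diff_max
    eaf_flags <- union(eaf_flags, x$key[big])
  }
  list(cohorts = out,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
         tibble::tibble(key = character(), cohort = character(),
                        reason = character()),
       eaf_flags = eaf_flags)
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools harmonised per-cohort estimates with weights `w_k = 1/se_k^2`:
#' the combined effect is the weighted mean, its standard error
#' `1/sqrt(sum w_k)`, and the p-value two-sided normal. Heterogeneity is
#' summarised by Cochran's Q (with K-1 degrees of freedom and a chi-square
#' p-value) and `I^2 = max(0, (Q - df)/Q) * 100`. The direction string
#' records the sign of each cohort's effect in input order (`?` when the
#' variant is absent).
#'
#' @param cohorts Named list of aligned association tibbles (from
#'   [harmonize()]; a `key` column is added if missing).
#' @return Tibble with one row per variant: identifiers from the first
#'   cohort carrying the variant, `eaf` (sample-size weighted), `n` (summed),
#'   `beta`, `se`, `p`, `n_cohorts`, `direction`, `q_stat`, `q_df`, `q_p`,
#'   `i2`.
#' @export
ivw_meta <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  for (nm in names(cohorts)) {
    if (!"key" %in% names(cohorts[[nm]])) {
      x <- cohorts[[nm]]
      cohorts[[nm]]$key <- paste(sub("^chr", "", x$chrom), x$pos,
                                 pmin(toupper(x$ea), toupper(x$oa)),
                                 pmax(toupper(x$ea), toupper(x$oa)),
                                 sep = ":")
    }
  }
  all_keys <- unique(unlist(lapply(cohorts, function(x) x$key)))
  K <- length(cohorts)
  first <- dplyr::bind_rows(cohorts)[match(all_keys,
                                           dplyr::bind_rows(cohorts)$key), ]
  B <- SE <- N <- EAF <- matrix(NA_real_, length(all_keys), K)
  for (k in seq_len(K)) {
    m <- match(cohorts[[k]]$key, all_keys)
    B[m, k] <- cohorts[[k]]$beta
    SE[m, k] <- cohorts[[k]]$se
    N[m, k] <- cohorts[[k]]$n
    EAF[m, k] <- cohorts[[k]]$eaf
  }
  W <- 1 / SE^2
  sw <- rowSums(W, na.rm = TRUE)
  beta <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  p <- 2 * stats::pnorm(-abs(beta / se))
  q <- rowSums(W * (B - beta)^2, na.rm = TRUE)
  n_coh <- rowSums(!is.na(B))
  q_df <- pmax(n_coh - 1, 0)
  q_p <- ifelse(q_df > 0, stats::pchisq(q, q_df, lower.tail = FALSE), NA_real_)
  i2 <- ifelse(q > 0, pmax(0, (q - q_df) / q) * 100, 0)
  dir <- apply(B, 1, function(r) {
    paste(ifelse(is.na(r), "?", ifelse(r >= 0, "+", "-")), collapse = "")
  })
  tibble::tibble(
    key = all_keys, snp = first$snp, chrom = first$chrom, pos = first$pos,
    ea = first$ea, oa = first$oa,
    eaf = rowSums(EAF * N, na.rm = TRUE) / rowSums(N * !is.na(EAF), na.rm = TRUE),
    n = rowSums(N, na.rm = TRUE),
    beta = beta, se = se, p = p, n_cohorts = n_coh, direction = dir,
    q_stat = q, q_df = q_df, q_p = q_p, i2 = i2)
}

#' Post-meta-analysis filters, significance and distance clumping
#'
#' Drops variants present in fewer than half the cohorts (ceiling rule) or
#' with meta MAF < 0.005, marks genome-wide significant hits
#' (p < 5e-8), and reduces hits to clump leads: the best p-value within a
#' +/-500 kb window per chromosome.
#'
#' @param meta Tibble from [ivw_meta()].
#' @param total_cohorts Number of cohorts contributing to the analysis.
#' @param maf_min Minimum meta minor allele frequency (default 0.005).
#' @param p_threshold Genome-wide significance level (default 5e-8).
#' @param clump_kb Clump half-window in kilobases (default 500).
#' @return List with `kept` (filtered meta table with a logical `hit`
#'   column), `hits` (significant rows) and `leads` (clump lead rows).
#' @export
post_meta_filters <- function(meta, total_cohorts, maf_min = 0.005,
                              p_threshold = 5e-8, clump_kb = 500) {
  need <- ceiling(total_cohorts / 2)
  maf <- pmin(meta$eaf, 1 - meta$eaf)
  kept <- meta[meta$n_cohorts >= need & maf >= maf_min, ]
  kept$hit <- kept$p < p_threshold
  hits <- kept[kept$hit, ]
  leads <- hits[0, ]
  if (nrow(hits)) {
    hits <- dplyr::arrange(hits, .data$p)
    taken <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (taken[i]) next
      same <- hits$chrom == hits$chrom[i] &
        abs(hits$pos - hits$pos[i]) <= clump_kb * 1000
      taken[same] <- TRUE
      taken[i] <- TRUE
      leads <- dplyr::bind_rows(leads, hits[i, ])
    }
  }
  list(kept = kept, hits = hits, leads = leads)
}

#' Genomic inflation factor
#'
#' Median association chi-square over its null expectation
#' (`qchisq(0.5, 1)`); values near 1 indicate a well-calibrated test.
#'
#' @param p Vector of p-values.
#' @return Lambda (a scalar).
#' @export
lambda_gc <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, 1)
}
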