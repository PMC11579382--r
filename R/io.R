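#' Write a cohort's tables to disk
#'
#' Long-format measurement CSV (`iid, sex, age_years, weight_kg, height_cm,
#' source`), truth tables as TSV, and dosages either as TSV (subjects x
#' variants) or as a minimal VCF with a `DS` FORMAT field. Every file opens
#' with a comment header carrying the generator seed, so outputs are
#' self-describing.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param dosage_format `"tsv"` or `"vcf"`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, dosage_format = c("tsv", "vcf")) {
  dosage_format <- match.arg(dosage_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# trajgwas simulated cohort; seed=%d", cohort$config$seed)
  files <- character()
  wt <- function(df, path, sep = ",") {
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = sep, append = TRUE,
                                        row.names = FALSE, quote = FALSE))
    files <<- c(files, path)
  }
  rec <- cohort$records
  names(rec)[names(rec) == "age"] <- "age_years"
  wt(rec, file.path(dir, "measurements.csv"))
  wt(cohort$subjects, file.path(dir, "subjects_truth.tsv"), sep = "\t")
  if (!is.null(cohort$ledger) && nrow(cohort$ledger)) {
    wt(cohort$ledger, file.path(dir, "fault_ledger.tsv"), sep = "\t")
  }
  if (!is.null(cohort$genotypes)) {
    if (dosage_format == "tsv") {
      d <- data.frame(iid = rownames(cohort$genotypes), cohort$genotypes,
                      check.names = FALSE)
      wt(d, file.path(dir, "dosages.tsv"), sep = "\t")
      wt(cohort$variants, file.path(dir, "variants.tsv"), sep = "\t")
    } else {
      files <- c(files, write_dosage_vcf(cohort$genotypes, cohort$variants,
                                         file.path(dir, "dosages.vcf")))
    }
  }
  invisible(files)
}

#' Write a dosage matrix as a VCF with a DS FORMAT field
#'
#' Minimal VCFv4.2 writer: one line per variant, `DS` (expected alternate
#' allele dosage) per sample, effect allele written as ALT. Imputation
#' INFO scores are carried in the INFO column.
#'
#' @param dosages Matrix, subjects in rows (rownames = iid).
#' @param variants Tibble with `snp`, `chrom`, `pos`, `ea`, `oa`, optional
#'   `info`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(dosages, variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosages)), collapse = "\t")),
             con)
  info <- if ("info" %in% names(variants)) variants$info else rep(1, nrow(variants))
  for (j in seq_len(nrow(variants))) {
    row <- c(sub("^chr", "", variants$chrom[j]), variants$pos[j],
             variants$snp[j], variants$oa[j], variants$ea[j], ".", "PASS",
             sprintf("INFO=%.4g", info[j]), "DS",
             sprintf("%.4g", dosages[, j]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with a DS field
#'
#' Uses \pkg{vcfR} to parse the file and extracts the `DS` FORMAT field
#' into a subjects-by-variants matrix, with variant metadata (ALT as the
#' effect allele, dosage-based EAF, INFO score when present).
#'
#' @param path VCF path.
#' @return List with `dosages` (matrix) and `variants` (tibble).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  dosages <- t(ds)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_raw <- vcfR::extract.info(v, element = "INFO", as.numeric = TRUE)
  variants <- tibble::tibble(
    snp = fix$ID, chrom = sub("^chr", "", fix$CHROM),
    pos = as.numeric(fix$POS), ea = fix$ALT, oa = fix$REF,
    eaf = colMeans(dosages, na.rm = TRUE) / 2,
    info = if (all(is.na(info_raw))) 1 else as.numeric(info_raw))
  list(dosages = dosages, variants = variants)
}

#' Read a dosage TSV pair written by [write_cohort()]
#'
#' @param dosage_path TSV with an `iid` column then one column per variant.
#' @param variant_path TSV of variant metadata.
#' @return List with `dosages` (matrix) and `variants` (tibble).
#' @export
read_dosage_tsv <- function(dosage_path, variant_path) {
  d <- utils::read.delim(dosage_path, comment.char = "#",
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$iid
  v <- tibble::as_tibble(utils::read.delim(variant_path, comment.char = "#",
                                           check.names = FALSE))
  v$chrom <- as.character(v$chrom)
  list(dosages = m, variants = v)
}

#' Serialise a fitted trajectory model to JSON
#'
#' Stores the parameter estimates, specification and status — everything
#' needed to reproduce trajectories and phenotypes — without the engine
#' object.
#'
#' @param fit A [fit_lmm()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    spec = list(
      fixed = list(form = fit$spec$fixed$form, knots = fit$spec$fixed$knots),
      random = list(form = fit$spec$random$form, knots = fit$spec$random$knots),
      correlation = fit$spec$correlation, covariates = fit$spec$covariates),
    method = fit$method, status = fit$status, message = fit$message,
    beta = as.list(fit$beta), G = fit$G, sigma2 = fit$sigma2, phi = fit$phi,
    loglik = fit$loglik, n_params = fit$n_params,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit serialised by [write_fit_json()]
#'
#' @param path JSON path.
#' @return A `traj_lmm` object (without the engine object; all derived
#'   quantities — BLUPs, trajectories, phenotypes — still work).
#' @export
read_fit_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(
    fixed = spline_spec(o$spec$fixed$form,
                        as.numeric(unlist(o$spec$fixed$knots))),
    random = spline_spec(o$spec$random$form,
                         as.numeric(unlist(o$spec$random$knots))),
    correlation = o$spec$correlation,
    covariates = as.character(unlist(o$spec$covariates)))
  fit <- list(beta = unlist(o$beta), G = matrix(unlist(o$G), nrow(o$G)),
              sigma2 = o$sigma2, phi = o$phi %||% NA_real_,
              loglik = o$loglik, n_params = o$n_params,
              n_subjects = o$n_subjects, n_obs = o$n_obs, status = o$status,
              message = o$message %||% "", spec = spec, method = o$method,
              scales = NULL, engine = "restored", fit = NULL)
  class(fit) <- "traj_lmm"
  fit
}

#' @importFrom rlang %||% .data
NULL

#' Write a summary-statistics table with a provenance header
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param header Character vector of `#`-prefixed comment lines.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(x, path, header = character()) {
  if (length(header)) writeLines(paste0("# ", header), path)
  suppressWarnings(utils::write.table(x, path, sep = "\t",
                                      append = length(header) > 0,
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}
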