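#' Configuration for an end-to-end pipeline run
#'
#' @param cohorts Named list of [sim_config()] objects (one synthetic cohort
#'   each) or lists with pre-loaded `records`/`genotypes`/`variants`
#'   elements.
#' @param model The [model_spec()] fitted in every cohort (sex-stratified).
#' @param windows Analysis windows, see [default_windows()].
#' @param age_window Modelling age window in years.
#' @param pred_range Trajectory prediction range; must lie within
#'   `age_window`.
#' @param gwas_phenotypes Phenotype columns to take to GWAS and
#'   meta-analysis.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param seed Integer master seed recorded in every output header.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts, model,
                            windows = default_windows(),
                            age_window = c(2 / 52, 18),
                            pred_range = c(2 / 52, 17),
                            gwas_phenotypes = c("slope_infancy",
                                                "auc_childhood"),
                            out_dir = NULL, seed = 1L) {
  if (pred_range[1] < age_window[1] - 1e-9 ||
      pred_range[2] > age_window[2] + 1e-9) {
    stop("prediction range must lie within the modelling age window")
  }
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  structure(list(cohorts = cohorts, model = model, windows = windows,
                 age_window = age_window, pred_range = pred_range,
                 gwas_phenotypes = gwas_phenotypes, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_header <- function(config, stage) {
  c(sprintf("trajgwas %s", stage),
    sprintf("config_hash=%s", rlang::hash(config[setdiff(names(config),
                                                         "out_dir")])),
    sprintf("seed=%d", config$seed))
}

#' Run the full analysis pipeline on one or more cohorts
#'
#' For each cohort: simulate (or accept) measurement and genotype tables,
#' clean them ([flag_records()], [derive_analysis_set()]), fit the chosen
#' model separately by sex, derive the trajectory phenotypes, apply the
#' 2 x IQR exclusion, and run the additive-dosage GWAS for each configured
#' phenotype (sex-combined, with sex as a covariate). Cohort results are
#' then harmonised and combined by inverse-variance fixed-effects
#' meta-analysis with post-filters. Any stage failure halts with an error
#' naming the stage; artifacts written so far are preserved.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `qc` (per-cohort exclusion
#'   summaries), `fits` (per cohort/sex), `phenotypes` (per cohort, outlier
#'   mask applied), `gwas` (per cohort, per phenotype), `meta` (per
#'   phenotype, filtered, with hits) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  qc <- list()
  fits <- list()
  phenos <- list()
  gwas <- list()
  cohort_data <- list()

  for (nm in names(config$cohorts)) {
    cd <- config$cohorts[[nm]]
    cohort <- stage(paste0("simulate:", nm), {
      if (inherits(cd, "sim_config")) simulate_cohort(cd) else cd
    })
    cohort_data[[nm]] <- cohort
    flagged <- stage(paste0("qc:", nm), flag_records(cohort$records))
    qc[[nm]] <- flagged$summary
    tab <- stage(paste0("derive:", nm),
                 derive_analysis_set(flagged, config$age_window[1],
                                     config$age_window[2]))
    ph_sex <- list()
    for (sx in sort(unique(tab$sex))) {
      sub <- tab[tab$sex == sx, ]
      fit <- stage(paste0("fit:", nm, ":", sx),
                   fit_lmm(sub, config$model))
      if (fit$status == "error") {
        stop("pipeline stage 'fit:", nm, ":", sx, "' failed: ", fit$message,
             call. = FALSE)
      }
      fits[[paste(nm, sx, sep = ":")]] <- fit
      ph_sex[[sx]] <- stage(paste0("phenotypes:", nm, ":", sx),
                            derive_phenotypes(fit, sub,
                                              windows = config$windows,
                                              range = config$pred_range))
    }
    ph <- dplyr::bind_rows(ph_sex)
    excl <- stage(paste0("iqr:", nm), iqr_exclusion(ph))
    phenos[[nm]] <- excl$phenos
    if (!is.null(out_dir)) {
      write_sumstats(excl$phenos, file.path(out_dir,
                                            paste0(nm, "_phenotypes.tsv")),
                     pipeline_header(config, paste0("phenotypes:", nm)))
    }
    if (!is.null(cohort$genotypes)) {
      covar <- tibble::tibble(
        iid = cohort$subjects$iid,
        sex = cohort$subjects$sex)
      for (phn in config$gwas_phenotypes) {
        assoc <- stage(paste0("gwas:", nm, ":", phn),
                       run_gwas(excl$filtered[, c("iid", phn)],
                                cohort$genotypes, cohort$variants, covar,
                                phenotype = phn))
        filt <- cohort_filters(assoc)
        gwas[[phn]][[nm]] <- filt$kept
        if (!is.null(out_dir)) {
          write_sumstats(filt$kept,
                         file.path(out_dir,
                                   paste0(nm, "_", phn, "_gwas.tsv")),
                         pipeline_header(config, paste0("gwas:", nm)))
        }
      }
    }
  }

  meta <- list()
  for (phn in names(gwas)) {
    if (length(gwas[[phn]]) == 0) next
    harm <- stage(paste0("harmonize:", phn), harmonize(gwas[[phn]]))
    mt <- stage(paste0("meta:", phn), ivw_meta(harm$cohorts))
    meta[[phn]] <- stage(paste0("postfilter:", phn),
                         post_meta_filters(mt, length(gwas[[phn]])))
    if (!is.null(out_dir)) {
      write_sumstats(meta[[phn]]$kept,
                     file.path(out_dir, paste0("meta_", phn, ".tsv")),
                     pipeline_header(config, paste0("meta:", phn)))
    }
  }
  structure(list(qc = qc, fits = fits, phenotypes = phenos, gwas = gwas,
                 meta = meta, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$qc), " cohort(s), ",
      length(x$fits), " fits, ", length(x$meta),
      " meta-analysed phenotype(s)\n", sep = "")
  invisible(x)
}
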