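#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates simulate -> kernels -> model fits -> heritability and
#' phenotypic-selection accuracy -> cross-validation -> heterosis into
#' one reproducible run directory.  Every stage consumes only artifacts
#' of earlier stages; a manifest records the configuration, package
#' version, and MD5 of every file written, so a rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param config a list with elements:
#'   * `sim`: a [sim_config()] (required; the simulated study drives the
#'     run),
#'   * `traits`: traits to analyse (default: all simulated),
#'   * `stages`: subset of `c("simulate", "kernels", "fit",
#'     "heritability", "accuracy", "cv", "heterosis")` (default all, in
#'     dependency order),
#'   * `fit_stages`: model stages to fit per trait (default the six
#'     hybrid-value/GCA stages),
#'   * `cv`: list of options for [male_gca_cv()] (`male_gca`) and
#'     [hybrid_tset_cv()] (`hybrid_tset`); set an element to `NULL` to
#'     skip that scheme.
#'   May also be the path of a YAML file with the same structure (the
#'   `sim` block holding [sim_config()] arguments).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the run directory path; side effect: CSV/TSV/JSON
#'   artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    raw <- yaml::read_yaml(config)
    raw$sim <- do.call(sim_config, raw$sim %||% list())
    config <- raw
  }
  if (!inherits(config$sim, "sim_config"))
    stop("config$sim must be a sim_config()")
  stages_all <- c(
    "simulate", "kernels", "fit", "heritability", "accuracy", "cv", "heterosis"
  )
  stages <- config$stages %||% stages_all
  stopifnot(all(stages %in% stages_all))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name, writer = utils::write.csv) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  csv <- function(obj, name)
    emit(obj, name, function(o, p) utils::write.csv(o, p, row.names = FALSE))

  study <- simulate_study(config$sim)
  traits <- config$traits %||% names(config$sim$traits)
  if ("simulate" %in% stages) {
    emit(study$female_genotypes, "females.tsv", write_dosage_tsv)
    emit(study$male_genotypes, "males.tsv", write_dosage_tsv)
    csv(as.data.frame(study$design), "design.csv")
    csv(study$phenotypes, "phenotypes.csv")
    truth <- do.call(rbind, lapply(traits, function(tn) {
      tv <- study$true_values[[tn]]
      data.frame(
        trait = tn,
        level = c(names(tv$female_gca), names(tv$male_gca), names(tv$hybrid_value)),
        term = c(
          rep("F", length(tv$female_gca)), rep("M", length(tv$male_gca)),
          rep("hybrid_value", length(tv$hybrid_value))
        ),
        value = c(tv$female_gca, tv$male_gca, tv$hybrid_value),
        stringsAsFactors = FALSE
      )
    }))
    csv(truth, "truth.csv")
  }
  kernels <- study$kernels
  if (any(c("kernels", "fit", "heritability", "accuracy", "cv") %in% stages)) {
    kernels$G_H <- hybrid_kernel(study)
    if ("kernels" %in% stages) {
      emit(kernels$G_F, "G_F.tsv", write_kernel_tsv)
      emit(kernels$G_M, "G_M.tsv", write_kernel_tsv)
      emit(kernels$G_H, "G_H.tsv", write_kernel_tsv)
    }
  }
  fit_stages <- config$fit_stages %||% c(
    "hybrid_value", "hybrid_value_genomic", "gca", "gca_sca",
    "gca_genomic", "gca_sca_genomic"
  )
  fits <- list()
  if (any(c("fit", "heritability", "accuracy") %in% stages)) {
    rows <- list()
    for (tn in traits) {
      fits[[tn]] <- list()
      for (stg in fit_stages) {
        fit <- fit_reml(model_catalog(tn, stg, study$phenotypes, kernels))
        fits[[tn]][[stg]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tn, stage = stg, component = names(fit$sigma2),
          sigma2 = unname(fit$sigma2), boundary = unname(fit$boundary),
          logLik = fit$logLik, AIC = fit$AIC, BIC = fit$BIC,
          converged = fit$converged, stringsAsFactors = FALSE
        )
      }
    }
    if ("fit" %in% stages) csv(do.call(rbind, rows), "variance_components.csv")
  }
  if ("heritability" %in% stages) {
    rows <- lapply(traits, function(tn) {
      hm <- design_harmonic_means(
        study$phenotypes[study$phenotypes$type == "hybrid", ], tn
      )
      em <- entry_mean_h2(fits[[tn]][["hybrid_value"]], hm$h_j, hm$h_t)
      ns <- narrow_sense_h2(fits[[tn]][["hybrid_value_genomic"]])
      data.frame(
        trait = tn, entry_mean_H2 = em$value, entry_mean_se = em$se,
        narrow_sense_h2 = ns$value, narrow_sense_se = ns$se
      )
    })
    csv(do.call(rbind, rows), "heritability.csv")
  }
  if ("accuracy" %in% stages) {
    rows <- list()
    for (tn in traits) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tn, target = "hybrid_value", stage = "hybrid_value",
        accuracy = phenotypic_selection_accuracy(
          fits[[tn]][["hybrid_value"]], "H")$accuracy
      )
      for (stg in intersect(c("gca", "gca_sca"), fit_stages)) {
        for (term in c("F", "M")) {
          acc <- tryCatch(
            phenotypic_selection_accuracy(fits[[tn]][[stg]], term)$accuracy,
            warning = function(w) NA_real_
          )
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tn, target = paste0(term, "_gca"), stage = stg,
            accuracy = acc
          )
        }
      }
    }
    csv(do.call(rbind, rows), "phenotypic_accuracy.csv")
  }
  if ("cv" %in% stages) {
    cv_cfg <- config$cv %||% list(
      male_gca = list(n_folds = 10), hybrid_tset = list(n_reps = 20)
    )
    for (tn in traits) {
      if (!is.null(cv_cfg$male_gca)) {
        args <- c(list(
          data = study$phenotypes, trait = tn, kernels = kernels,
          seed = config$sim$seed
        ), cv_cfg$male_gca)
        res <- do.call(male_gca_cv, args)
        csv(res$per_fold, sprintf("cv_male_gca_%s_folds.csv", tn))
        csv(data.frame(
          trait = tn, stage = res$stage, mean_ability = res$mean_ability,
          se_ability = res$se_ability, full_data_corr = res$full_data_corr,
          accuracy = res$accuracy
        ), sprintf("cv_male_gca_%s.csv", tn))
      }
      if (!is.null(cv_cfg$hybrid_tset)) {
        args <- c(list(
          data = study$phenotypes, trait = tn, kernels = kernels,
          seed = config$sim$seed
        ), cv_cfg$hybrid_tset)
        res <- do.call(hybrid_tset_cv, args)
        out <- res$summary
        out$trait <- tn; out$stage <- res$stage
        out$full_data_corr <- res$full_data_corr
        csv(out, sprintf("cv_hybrid_%s.csv", tn))
      }
    }
  }
  if ("heterosis" %in% stages) {
    all_rec <- list(); all_tests <- list()
    for (tn in traits) {
      rec <- heterosis_records(study, tn)
      all_rec[[tn]] <- rec
      tst <- sdaf_mph_tests(rec)
      tst$trait <- tn
      all_tests[[tn]] <- tst
      cm <- attr(rec, "crp")
      if (!is.null(cm)) {
        csv(data.frame(
          trait = tn, check = colnames(cm),
          mean_crp = colMeans(cm, na.rm = TRUE),
          sd_crp = apply(cm, 2, stats::sd, na.rm = TRUE),
          min_crp = apply(cm, 2, min, na.rm = TRUE),
          max_crp = apply(cm, 2, max, na.rm = TRUE)
        ), sprintf("crp_summary_%s.csv", tn))
      }
    }
    csv(do.call(rbind, lapply(all_rec, function(r) {
      attr(r, "crp") <- NULL; attr(r, "fit") <- NULL; r
    })), "heterosis_records.csv")
    csv(do.call(rbind, all_tests), "sdaf_mph_tests.csv")
  }
  manifest <- list(
    package = "gcablup",
    version = as.character(utils::packageVersion("gcablup")),
    seed = config$sim$seed,
    stages = stages, traits = traits,
    files = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files)
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
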