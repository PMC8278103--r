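#' Fit the genotype-value model with an inbred/hybrid indicator
#'
#' Fits the heterosis-stage model (fixed inbred-vs-F1 indicator, random
#' genotype, environment, genotype-by-environment and block effects) and
#' composes per-genotype values as `mu + class effect + genotype BLUP`.
#' The indicator absorbs the hybrid-inbred mean difference so genotype
#' BLUPs shrink toward their class mean; a genotype with no records gets
#' `mu + class effect + 0`.
#'
#' @param data plot table containing both hybrid and inbred records.
#' @param trait response column.
#' @param ... passed to [fit_reml()].
#' @return List with the `fit` and `genotype_values` (data frame:
#'   `genotype`, `type`, `value`).
#' @export
fit_genotype_model <- function(data, trait, ...) {
  spec <- model_catalog(trait, "heterosis", data)
  fit <- fit_reml(spec, ...)
  g <- extract_blups(fit, "G")
  type_of <- stats::setNames(spec$data$type, spec$data$genotype)
  type <- as.character(type_of[g$level])
  # values are put on the trial-mean scale: the mean environment and block
  # BLUPs are folded in (they are ~0 in any regular fit, but the
  # environment mean is confounded with the intercept when the residual
  # variance degenerates)
  design_mean <- sum(vapply(
    intersect(c("E", "B"), names(fit$blups)),
    function(tm) mean(extract_blups(fit, tm)$blup), numeric(1)
  ))
  class_eff <- design_mean + ifelse(type == "hybrid",
    fit$beta[["(Intercept)"]] + fit$beta[["typehybrid"]],
    fit$beta[["(Intercept)"]]
  )
  list(
    fit = fit,
    genotype_values = data.frame(
      genotype = g$level, type = type,
      value = class_eff + g$blup, stringsAsFactors = FALSE
    )
  )
}

#' Mid-parent heterosis
#'
#' `MPH = (H - MP) / MP` with `MP` the mean of the two parental genotype
#' values.  Symmetric in the parents and invariant to multiplying all
#' values by a positive constant.  Undefined (NA, with a warning) when
#' the mid-parent value is zero.
#'
#' @param hybrid_value,female_parent_value,male_parent_value genotype
#'   values on the same scale (vectorized).
#' @return MPH as a proportion.
#' @export
mph <- function(hybrid_value, female_parent_value, male_parent_value) {
  mp <- (female_parent_value + male_parent_value) / 2
  bad <- is.finite(mp) & mp == 0
  if (any(bad)) warning(sum(bad), " mid-parent value(s) are zero: MPH undefined")
  out <- (hybrid_value - mp) / mp
  out[bad] <- NA_real_
  out
}

#' Commercial relative performance
#'
#' `CRP = (H - C) / C` against a check genotype value from the same fit.
#' Undefined (NA, with a warning) for a zero check value.
#'
#' @param hybrid_value,check_value genotype values on the same scale.
#' @return CRP as a proportion.
#' @export
crp <- function(hybrid_value, check_value) {
  bad <- is.finite(check_value) & check_value == 0
  if (any(bad)) warning(sum(bad), " zero check value(s): CRP undefined")
  out <- (hybrid_value - check_value) / check_value
  out[is.finite(check_value) & check_value == 0] <- NA_real_
  out
}

#' Per-hybrid heterosis records for a study
#'
#' Fits the genotype-value model for a trait, resolves parental values
#' (CMS females through their maintainer lines, the TGMS female through
#' its own records), and returns one record per phenotyped hybrid with
#' its genotype value, mid-parent value, MPH, parental SDAF, and CRP
#' against each check.
#'
#' @param study a `sim_study` (or a list with the same fields:
#'   `phenotypes`, `design`, `female_genotypes`, `male_genotypes`,
#'   `maintainer_map`, `checks`).
#' @param trait response column.
#' @param ... passed to [fit_reml()].
#' @return A data frame of heterosis records (one row per hybrid) with a
#'   `"crp"` attribute (hybrid x check matrix) and the underlying `"fit"`.
#' @export
heterosis_records <- function(study, trait, ...) {
  gm <- fit_genotype_model(study$phenotypes, trait, ...)
  gv <- stats::setNames(gm$genotype_values$value, gm$genotype_values$genotype)
  phen_hyb <- unique(
    study$phenotypes[study$phenotypes$type == "hybrid" &
      !is.na(study$phenotypes[[trait]]),
      c("genotype", "female", "male")]
  )
  phen_hyb <- phen_hyb[phen_hyb$genotype %in% names(gv), , drop = FALSE]
  f_pheno_id <- study$maintainer_map[phen_hyb$female]
  fv <- gv[f_pheno_id]
  mv <- gv[phen_hyb$male]
  hv <- gv[phen_hyb$genotype]
  freq_f <- allele_frequencies(study$female_genotypes)$per_individual
  freq_m <- allele_frequencies(study$male_genotypes)$per_individual
  shared <- intersect(colnames(freq_f), colnames(freq_m))
  sdaf_v <- vapply(seq_len(nrow(phen_hyb)), function(i) {
    sdaf(freq_f[phen_hyb$female[i], shared], freq_m[phen_hyb$male[i], shared])
  }, numeric(1))
  out <- data.frame(
    hybrid = phen_hyb$genotype, female = phen_hyb$female,
    male = phen_hyb$male, trait = trait,
    hybrid_value = unname(hv), mid_parent_value = unname((fv + mv) / 2),
    mph = mph(hv, fv, mv), sdaf = sdaf_v,
    stringsAsFactors = FALSE
  )
  checks <- intersect(study$checks, names(gv))
  crp_mat <- sapply(checks, function(ck) crp(hv, gv[[ck]]))
  if (length(checks)) {
    crp_mat <- matrix(crp_mat, ncol = length(checks),
      dimnames = list(out$hybrid, checks))
    attr(out, "crp") <- crp_mat
  }
  attr(out, "fit") <- gm$fit
  out
}

#' Correlation tests of SDAF against mid-parent heterosis
#'
#' Pearson correlation of parental SDAF with MPH, overall and/or within
#' families of hybrids sharing a female parent, with
#' `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided P from the t
#' distribution on `n - 2` degrees of freedom, and a 95% confidence
#' interval by the Fisher z transformation (reported as bounds and as a
#' half-width).  Groups with fewer than 3 records or zero variance in
#' either variable yield a flagged row with `r = NA`.
#'
#' @param records data frame with columns `female`, `sdaf`, `mph` (and
#'   optionally `trait`), e.g. from [heterosis_records()].
#' @param grouping `"overall"`, `"by_female_family"`, or both (default).
#' @param conf_level confidence level (default 0.95).
#' @return Data frame: one row per group with `group`, `n`, `r`,
#'   `ci_lower`, `ci_upper`, `ci_halfwidth`, `t`, `df`, `p`, `flag`.
#' @export
sdaf_mph_tests <- function(records,
                           grouping = c("overall", "by_female_family"),
                           conf_level = 0.95) {
  grouping <- match.arg(grouping, several.ok = TRUE)
  groups <- list()
  if ("overall" %in% grouping) groups[["overall"]] <- records
  if ("by_female_family" %in% grouping) {
    for (f in sort(unique(records$female)))
      groups[[f]] <- records[records$female == f, , drop = FALSE]
  }
  one <- function(name, d) {
    n <- sum(is.finite(d$sdaf) & is.finite(d$mph))
    base <- data.frame(
      group = name, n = n, r = NA_real_, ci_lower = NA_real_,
      ci_upper = NA_real_, ci_halfwidth = NA_real_, t = NA_real_,
      df = n - 2L, p = NA_real_, flag = "", stringsAsFactors = FALSE
    )
    if (n < 3) { base$flag <- "too_few"; return(base) }
    ok <- is.finite(d$sdaf) & is.finite(d$mph)
    x <- d$sdaf[ok]; y <- d$mph[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      base$flag <- "zero_variance"; return(base)
    }
    r <- stats::cor(x, y)
    df <- n - 2
    t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    zse <- 1 / sqrt(n - 3)
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- tanh(z - crit * zse); hi <- tanh(z + crit * zse)
    base$r <- r; base$t <- t; base$p <- p
    base$ci_lower <- lo; base$ci_upper <- hi
    base$ci_halfwidth <- (hi - lo) / 2
    base
  }
  out <- do.call(rbind, Map(one, names(groups), groups))
  rownames(out) <- NULL
  out
}
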