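#' Harmonic mean
#'
#' `n / sum(1 / counts)`; the effective replication number entering
#' entry-mean heritability for unbalanced designs.
#'
#' @param counts positive counts.
#' @return Scalar harmonic mean.
#' @export
harmonic_mean <- function(counts) {
  if (!length(counts)) stop("empty count list")
  if (any(counts <= 0)) stop("counts must be positive")
  length(counts) / sum(1 / counts)
}

#' Harmonic-mean replication numbers of a trial
#'
#' `h_j` is the harmonic mean of the number of observations of each
#' genotype within an environment (over genotype-by-environment cells with
#' data); `h_t` the harmonic mean of the total observations per genotype.
#' `h_j <= h_t` whenever both are defined.
#'
#' @param data plot table with `genotype` and `env` columns.
#' @param trait response column (rows with missing values are ignored).
#' @return List with `h_j` and `h_t`.
#' @export
design_harmonic_means <- function(data, trait) {
  d <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (!nrow(d)) stop("no observations of trait ", trait)
  per_env <- table(paste(d$genotype, d$env, sep = ":"))
  per_geno <- table(d$genotype)
  list(h_j = harmonic_mean(as.numeric(per_env)),
    h_t = harmonic_mean(as.numeric(per_geno)))
}

varcomp_of <- function(fit_or_components) {
  if (inherits(fit_or_components, "gblup_fit")) fit_or_components$sigma2
  else fit_or_components
}

delta_se <- function(fit, labels, grad) {
  if (!inherits(fit, "gblup_fit") || is.null(fit$vcov_sigma2)) return(NA_real_)
  if (!all(labels %in% rownames(fit$vcov_sigma2))) return(NA_real_)
  V <- fit$vcov_sigma2[labels, labels, drop = FALSE]
  as.numeric(sqrt(pmax(t(grad) %*% V %*% grad, 0)))
}

#' Entry-mean heritability for an unbalanced RCBD
#'
#' For a trait observed in several environments,
#' `H2 = s2_H / (s2_H + s2_HE / h_j + s2_e / h_t)`; with a single
#' environment the genotype-by-environment term drops and
#' `H2 = s2_H / (s2_H + s2_e / h_t)`.  The standard error (when a fit is
#' supplied) comes from the delta method on the average-information
#' covariance of the variance components; a delete-one-genotype jackknife
#' is available via `se_method = "jackknife"` (it refits the model once
#' per genotype and is correspondingly slow).
#'
#' @param fit a [fit_reml()] result with terms `H` (and `HE` for the
#'   two-environment form), or a named numeric vector of components
#'   (`H`, optionally `HE`, and `residual`).
#' @param h_j,h_t harmonic-mean replication numbers
#'   ([design_harmonic_means()]); `h_j` is unused in the single-
#'   environment form.
#' @param se_method `"delta"` (default) or `"jackknife"` (fit objects
#'   only).
#' @return A `heritability` list: `value`, `se`, `scope`, `components`,
#'   `h_j`, `h_t`.
#' @export
entry_mean_h2 <- function(fit, h_j = NULL, h_t, se_method = c("delta", "jackknife")) {
  se_method <- match.arg(se_method)
  s <- varcomp_of(fit)
  if (!all(c("H", "residual") %in% names(s)))
    stop("need variance components 'H' and 'residual'")
  two_env <- "HE" %in% names(s)
  if (two_env && is.null(h_j)) stop("two-environment form needs h_j")
  denom <- if (two_env) s[["H"]] + s[["HE"]] / h_j + s[["residual"]] / h_t
  else s[["H"]] + s[["residual"]] / h_t
  value <- if (denom == 0) 0 else s[["H"]] / denom
  se <- NA_real_
  if (inherits(fit, "gblup_fit")) {
    if (se_method == "delta") {
      # d/ds of H2 = sH / D with D as above
      if (two_env) {
        D <- denom
        grad <- c(
          (D - s[["H"]]) / D^2, -s[["H"]] / (h_j * D^2),
          -s[["H"]] / (h_t * D^2)
        )
        se <- delta_se(fit, c("H", "HE", "residual"), grad)
      } else {
        D <- denom
        grad <- c((D - s[["H"]]) / D^2, -s[["H"]] / (h_t * D^2))
        se <- delta_se(fit, c("H", "residual"), grad)
      }
    } else {
      se <- jackknife_h2_se(fit, h_j, h_t)
    }
  }
  structure(list(
    value = unname(value), se = se, scope = "entry_mean",
    components = s[intersect(c("H", "HE", "residual"), names(s))],
    h_j = if (two_env) h_j else NA_real_, h_t = h_t
  ), class = "heritability")
}

jackknife_h2_se <- function(fit, h_j, h_t) {
  data <- fit$spec$data
  genos <- unique(data$genotype)
  if (length(genos) > 200) genos <- genos[seq(1, length(genos), length.out = 200)]
  vals <- vapply(genos, function(g) {
    sub <- data[data$genotype != g, , drop = FALSE]
    sp <- fit$spec; sp$data <- sub
    fi <- tryCatch(
      suppressWarnings(fit_reml(sp, init = fit$sigma2, max_iter = 50)),
      error = function(e) NULL
    )
    if (is.null(fi)) return(NA_real_)
    hm <- design_harmonic_means(sub, fit$spec$response)
    entry_mean_h2(fi$sigma2, hm$h_j, hm$h_t)$value
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  g <- length(vals)
  sqrt((g - 1) / g * sum((vals - mean(vals))^2))
}

#' Narrow-sense heritability on a single-plant basis
#'
#' `h2 = s2_H / (s2_H + s2_HE + s2_e)` (or without the interaction term
#' for single-environment traits), where `s2_H` is the additive variance
#' from a genomic fit of the hybrid-value model (`H` carrying the hybrid
#' relationship kernel).  No division by replication numbers: the scale is
#' a single plot.  Refuses components from a non-genomic fit, whose `s2_H`
#' is a total (not additive) genetic variance.
#'
#' @param fit a [fit_reml()] result from [model_catalog()] stage
#'   `hybrid_value_genomic`.
#' @return A `heritability` list.
#' @export
narrow_sense_h2 <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (!isTRUE(fit$spec$genomic))
    stop("narrow-sense h2 needs a genomic fit: sigma2_H from an identity ",
      "kernel is total, not additive, genetic variance")
  s <- fit$sigma2
  two_env <- "HE" %in% names(s)
  denom <- s[["H"]] + (if (two_env) s[["HE"]] else 0) + s[["residual"]]
  value <- if (denom == 0) 0 else s[["H"]] / denom
  labels <- if (two_env) c("H", "HE", "residual") else c("H", "residual")
  D <- denom
  grad <- c((D - s[["H"]]) / D^2, rep(-s[["H"]] / D^2, length(labels) - 1))
  structure(list(
    value = unname(value), se = delta_se(fit, labels, grad),
    scope = "narrow_sense", components = s[labels],
    h_j = NA_real_, h_t = NA_real_
  ), class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("<heritability %s> %.3f%s\n", x$scope, x$value,
    if (is.finite(x$se)) sprintf(" +/- %.3f", x$se) else ""))
  invisible(x)
}

#' PEV-based reliability of the BLUPs of a term
#'
#' Per-level reliability `r2_l = 1 - PEV_l / sigma2_term`, clipped to
#' [0, 1] (REML noise can push a PEV slightly above the component; the
#' number of clipped levels is reported).  The term reliability is the
#' mean over levels with data.  Undefined (with a warning) when the
#' component sits at its boundary floor.
#'
#' @param fit a [fit_reml()] result.
#' @param term random term label.
#' @param sigma2 variance used in the denominator; defaults to the fitted
#'   component of `term`.
#' @return List with `per_level` (data frame), `mean` (term reliability),
#'   and `n_clipped`.
#' @export
reliability_from_pev <- function(fit, term, sigma2 = NULL) {
  b <- extract_blups(fit, term)
  if (is.null(sigma2)) sigma2 <- fit$sigma2[[term]]
  if (inherits(fit, "gblup_fit") && isTRUE(fit$boundary[[term]])) {
    warning("sigma2_", term, " at boundary floor: reliability undefined")
    return(list(per_level = NULL, mean = NA_real_, n_clipped = 0L))
  }
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  raw <- 1 - b$pev / sigma2
  clipped <- pmin(pmax(raw, 0), 1)
  n_clipped <- sum(raw != clipped)
  if (n_clipped)
    message(sprintf("reliability: clipped %d level(s) to [0, 1]", n_clipped))
  per_level <- data.frame(
    level = b$level, reliability = clipped, n_obs = b$n_obs,
    stringsAsFactors = FALSE
  )
  with_data <- b$n_obs > 0
  list(
    per_level = per_level,
    mean = mean(clipped[with_data]),
    n_clipped = n_clipped
  )
}

#' Accuracy of phenotypic selection on a term's BLUPs
#'
#' The square root of the mean PEV-based reliability of the term's BLUPs
#' from a non-genomic fit (identity kernels): the expected correlation of
#' the BLUPs with the true effects.
#'
#' @param fit a non-genomic [fit_reml()] result.
#' @param term random term label (`"H"`, `"F"`, or `"M"`).
#' @return An `accuracy_result` list with `reliability` and `accuracy`.
#' @export
phenotypic_selection_accuracy <- function(fit, term) {
  rel <- reliability_from_pev(fit, term)
  structure(list(
    target = term, stage = fit$spec$stage %||% "custom",
    reliability = rel$mean,
    accuracy = sqrt(rel$mean),
    n = if (is.null(rel$per_level)) 0L else nrow(rel$per_level)
  ), class = "accuracy_result")
}

#' Genomic prediction accuracy from predictive ability
#'
#' Accuracy is predictive ability divided by the square root of the
#' reliability of the truth proxy; here the divisor is supplied directly
#' as the full-data correlation between the genomic and the conventional
#' BLUP of the same effects (itself an estimate of that square root).
#'
#' @param ability predictive ability (correlation), in [-1, 1].
#' @param full_data_corr full-data GBLUP-BLUP correlation, in (0, 1].
#' @return An `accuracy_result` list.
#' @export
genomic_accuracy <- function(ability, full_data_corr) {
  if (!is.finite(full_data_corr) || full_data_corr <= 0)
    stop("full-data correlation must be > 0")
  stopifnot(abs(ability) <= 1)
  structure(list(
    target = "genomic", stage = NA_character_,
    predictive_ability = ability,
    reliability = full_data_corr^2,
    accuracy = ability / full_data_corr,
    n = NA_integer_
  ), class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy %s> accuracy %.3f (reliability %.3f)\n",
    x$target, x$accuracy, x$reliability))
  invisible(x)
}

#' Convert grams per plant to tons per hectare
#'
#' At the trial spacing of 25 cm between and 20 cm within rows there are
#' 20 plants per square meter, i.e. 200,000 plants per hectare; yield in
#' t/ha is then `g_per_plant * plants_per_m2 / 100`.
#'
#' @param g_per_plant yield in grams per plant.
#' @param plants_per_m2 planting density (default 20).
#' @return Yield in tons per hectare.
#' @export
gplant_to_tha <- function(g_per_plant, plants_per_m2 = 20) {
  g_per_plant * plants_per_m2 * 1e4 / 1e6
}
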