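#' Classify untested hybrids by parental membership in a training set
#'
#' `T2` if both parents have progeny in the training set, `T1F` if only
#' the female, `T1M` if only the male, `T0` if neither.  The union stratum
#' `T1 = T1F + T1M` is reported alongside in the cross-validation
#' summaries.
#'
#' @param female,male parent ids (vectorized).
#' @param train_females,train_males parents represented in the training
#'   set.
#' @return Character vector of strata.
#' @export
classify_tset <- function(female, male, train_females, train_males) {
  fin <- female %in% train_females
  min_ <- male %in% train_males
  ifelse(fin & min_, "T2", ifelse(fin, "T1F", ifelse(min_, "T1M", "T0")))
}

predict_hybrid_values <- function(fit, pairs) {
  bF <- extract_blups(fit, "F"); bM <- extract_blups(fit, "M")
  pred <- bF$blup[match(pairs$female, bF$level)] +
    bM$blup[match(pairs$male, bM$level)]
  if ("FM" %in% names(fit$blups)) {
    bFM <- extract_blups(fit, "FM")
    fm <- paste(pairs$female, pairs$male, sep = "/")
    sca <- bFM$blup[match(fm, bFM$level)]
    sca[is.na(sca)] <- 0
    pred <- pred + sca
  }
  pred
}

safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Ten-fold cross-validation of genomic male-GCA prediction
#'
#' Partitions the phenotyped males into `n_folds` folds (or, when
#' `fold_size` is given, draws that many males per fold at random, with
#' replacement across folds).  In each fold every hybrid plot whose male
#' is held out is masked, the genomic stage model is refit on the masked
#' data, and the predictive ability is the correlation, over held-out
#' males, of their masked-fit GBLUP of male GCA with their BLUP of male
#' GCA from the full-data fit of the matching identity-kernel model.
#' Accuracy divides the fold-mean ability by the full-data GBLUP-BLUP
#' correlation.  Folds too small to correlate (< 3 males) trigger a
#' pooled fallback: predictions are pooled across folds and correlated
#' once.  Deterministic given `seed`.
#'
#' @param data plot-level phenotype table.
#' @param trait response column.
#' @param kernels named kernel list (needs `G_F`, `G_M`, and `G_FM` for
#'   the SCA stage — built from the parents if absent).
#' @param stage `"gca_genomic"` or `"gca_sca_genomic"`.
#' @param n_folds number of folds (default 10).
#' @param fold_size optional number of males masked per fold (sampling
#'   with replacement across folds instead of partitioning).
#' @param seed integer seed for fold assignment.
#' @param ... passed to [fit_reml()].
#' @return A `cv_result` list: per-fold table, mean ability with standard
#'   error, `full_data_corr`, and `accuracy`.
#' @export
male_gca_cv <- function(data, trait, kernels,
                        stage = c("gca_genomic", "gca_sca_genomic"),
                        n_folds = 10, fold_size = NULL, seed = 1, ...) {
  stage <- match.arg(stage)
  plain_stage <- sub("_genomic", "", stage)
  hyb <- data[data$type == "hybrid" & !is.na(data[[trait]]), , drop = FALSE]
  males <- sort(unique(hyb$male))
  if (length(males) < n_folds) stop("fewer phenotyped males than folds")
  if (grepl("sca", stage) && is.null(kernels$G_FM))
    kernels$G_FM <- scale_kernel(sca_kernel_pairs(
      kernels$G_F, kernels$G_M, unique(hyb[c("female", "male")])
    ))
  fit_g_full <- fit_reml(model_catalog(trait, stage, data, kernels), ...)
  fit_p_full <- fit_reml(model_catalog(trait, plain_stage, data), ...)
  gb_full <- extract_blups(fit_g_full, "M")
  pb_full <- extract_blups(fit_p_full, "M")
  blup_full <- stats::setNames(pb_full$blup, pb_full$level)
  full_corr <- safe_cor(
    gb_full$blup[match(males, gb_full$level)], blup_full[males]
  )
  set.seed(seed)
  folds <- if (is.null(fold_size)) {
    split(sample(males), rep_len(seq_len(n_folds), length(males)))
  } else {
    lapply(seq_len(n_folds), function(i) sample(males, fold_size))
  }
  per_fold <- data.frame(
    fold = seq_len(n_folds), n_males = NA_integer_, ability = NA_real_
  )
  pooled_pred <- pooled_true <- numeric(0)
  for (i in seq_len(n_folds)) {
    hold <- folds[[i]]
    masked <- data
    mask_rows <- masked$type == "hybrid" & masked$male %in% hold
    masked[[trait]][mask_rows] <- NA
    if (!any(!is.na(masked[[trait]][masked$type == "hybrid"])))
      stop("fold ", i, " empties the training set")
    fit_i <- fit_reml(
      model_catalog(trait, stage, masked, kernels, keep_all_levels = TRUE),
      init = fit_g_full$sigma2, ...
    )
    gb <- extract_blups(fit_i, "M")
    pred <- gb$blup[match(hold, gb$level)]
    truth <- blup_full[hold]
    per_fold$n_males[i] <- length(hold)
    per_fold$ability[i] <- safe_cor(pred, truth)
    pooled_pred <- c(pooled_pred, pred)
    pooled_true <- c(pooled_true, truth)
  }
  pooled <- anyNA(per_fold$ability)
  mean_ability <- if (pooled) safe_cor(pooled_pred, pooled_true)
  else mean(per_fold$ability)
  se_ability <- if (pooled) NA_real_
  else stats::sd(per_fold$ability) / sqrt(n_folds)
  structure(list(
    scheme = "male_gca", stage = stage, trait = trait,
    per_fold = per_fold, pooled = pooled,
    mean_ability = mean_ability, se_ability = se_ability,
    full_data_corr = full_corr,
    accuracy = mean_ability / full_corr
  ), class = "cv_result")
}

# Sample a training set of hybrids covering every sampled parent at least
# once: pure rejection first, then constructive coverage (one progeny per
# uncovered parent, remainder at random).
sample_training <- function(candidates, n_training, need_f, need_m,
                            retries = 1000) {
  ids <- seq_len(nrow(candidates))
  covers <- function(take) {
    all(need_f %in% candidates$female[take]) &&
      all(need_m %in% candidates$male[take])
  }
  for (i in seq_len(retries)) {
    take <- sample(ids, n_training)
    if (covers(take)) return(take)
  }
  take <- integer(0)
  for (m in need_m) {
    rows <- setdiff(which(candidates$male == m), take)
    if (!length(rows)) return(NULL)
    take <- c(take, if (length(rows) == 1) rows else sample(rows, 1))
  }
  for (f in setdiff(need_f, candidates$female[take])) {
    rows <- setdiff(which(candidates$female == f), take)
    if (!length(rows)) return(NULL)
    take <- c(take, if (length(rows) == 1) rows else sample(rows, 1))
  }
  if (length(take) > n_training) return(NULL)
  rest <- setdiff(ids, take)
  extra <- n_training - length(take)
  if (extra > 0) {
    if (length(rest) < extra) return(NULL)
    take <- c(take, if (length(rest) == 1) rest else sample(rest, extra))
  }
  take
}

#' Training-set cross-validation of hybrid genetic value prediction
#'
#' Replicated evaluation of genomic prediction of untested hybrids.  Each
#' replicate samples `n_females_sample` females and `n_males_sample`
#' males crossed to at least one of them, then a training set of
#' `n_training` phenotyped hybrids of those parents such that every
#' sampled parent has at least one training progeny (rejection sampling
#' with a bounded retry budget, then a constructive coverage draw).  The
#' stage model is fit on the training plots only; predicted genetic
#' values (female GCA + male GCA, plus SCA when in the stage) of all
#' phenotyped non-training hybrids are correlated with their full-data
#' BLUPs of hybrid value (the truth proxy), separately within the
#' parental-membership strata T0, T1F, T1M, their union T1, and T2.
#' Accuracy divides each stratum's mean ability by the full-data
#' correlation between genomic and conventional hybrid-value BLUPs.
#' Per-replicate seeds are drawn once from `seed`, so replicates are
#' independent and order-insensitive.
#'
#' @param data plot-level phenotype table.
#' @param trait response column.
#' @param kernels named kernel list (`G_F`, `G_M`; `G_FM` built on the
#'   fly for SCA stages).
#' @param stage `"gca_genomic"` or `"gca_sca_genomic"`.
#' @param n_reps number of replicates (study design: 500; scale to your
#'   budget).
#' @param n_females_sample,n_males_sample,n_training sampling design per
#'   replicate.
#' @param seed integer master seed.
#' @param retries rejection-sampling budget per replicate (default 1000).
#' @param ... passed to [fit_reml()].
#' @return A `cv_result` list: per-replicate stratum table, per-stratum
#'   mean ability and standard error, `full_data_corr`, per-stratum
#'   accuracies, and the number of skipped replicates.
#' @export
hybrid_tset_cv <- function(data, trait, kernels,
                           stage = c("gca_genomic", "gca_sca_genomic"),
                           n_reps = 500, n_females_sample = 4,
                           n_males_sample = 127, n_training = 150,
                           seed = 1, retries = 1000, ...) {
  stage <- match.arg(stage)
  hyb <- data[data$type == "hybrid" & !is.na(data[[trait]]), , drop = FALSE]
  phen_hybrids <- unique(hyb[c("genotype", "female", "male")])
  names(phen_hybrids)[1] <- "hybrid"
  if (grepl("sca", stage) && is.null(kernels$G_FM))
    kernels$G_FM <- scale_kernel(sca_kernel_pairs(
      kernels$G_F, kernels$G_M, phen_hybrids[c("female", "male")]
    ))
  fit_hv <- fit_reml(model_catalog(trait, "hybrid_value", data), ...)
  hv <- extract_blups(fit_hv, "H")
  truth <- stats::setNames(hv$blup, hv$level)
  fit_g_full <- fit_reml(
    model_catalog(trait, stage, data, kernels, keep_all_levels = TRUE), ...
  )
  pred_full <- predict_hybrid_values(fit_g_full, phen_hybrids)
  full_corr <- safe_cor(pred_full, truth[phen_hybrids$hybrid])
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  strata <- c("T0", "T1", "T1F", "T1M", "T2")
  recs <- list()
  n_skipped <- 0L
  for (rep_i in seq_len(n_reps)) {
    set.seed(rep_seeds[rep_i])
    females_all <- unique(phen_hybrids$female)
    fs <- sample(females_all, min(n_females_sample, length(females_all)))
    males_avail <- unique(phen_hybrids$male[phen_hybrids$female %in% fs])
    if (length(males_avail) < 2) { n_skipped <- n_skipped + 1L; next }
    ms <- sample(males_avail, min(n_males_sample, length(males_avail)))
    cand <- phen_hybrids[
      phen_hybrids$female %in% fs & phen_hybrids$male %in% ms, , drop = FALSE
    ]
    if (nrow(cand) <= max(n_training, length(ms))) {
      n_skipped <- n_skipped + 1L
      warning("replicate ", rep_i, ": too few candidate hybrids; skipped")
      next
    }
    take <- sample_training(cand, n_training, fs, ms, retries)
    if (is.null(take)) {
      n_skipped <- n_skipped + 1L
      warning("replicate ", rep_i, ": training constraint unsatisfiable; skipped")
      next
    }
    train_hybrids <- cand$hybrid[take]
    train <- data
    drop_rows <- train$type == "hybrid" & !train$genotype %in% train_hybrids
    train[[trait]][drop_rows] <- NA
    fit_t <- fit_reml(
      model_catalog(trait, stage, train, kernels, keep_all_levels = TRUE),
      init = fit_g_full$sigma2, ...
    )
    eval_set <- phen_hybrids[!phen_hybrids$hybrid %in% train_hybrids, , drop = FALSE]
    stopifnot(!any(eval_set$hybrid %in% train_hybrids))  # leakage guard
    pred <- predict_hybrid_values(fit_t, eval_set)
    tf <- unique(cand$female[take]); tm <- unique(cand$male[take])
    strat <- classify_tset(eval_set$female, eval_set$male, tf, tm)
    obs <- truth[eval_set$hybrid]
    for (s in strata) {
      in_s <- if (s == "T1") strat %in% c("T1F", "T1M") else strat == s
      recs[[length(recs) + 1L]] <- data.frame(
        replicate = rep_i, stratum = s, n = sum(in_s),
        ability = safe_cor(pred[in_s], obs[in_s])
      )
    }
  }
  per_rep <- do.call(rbind, recs)
  summary <- do.call(rbind, lapply(strata, function(s) {
    a <- per_rep$ability[per_rep$stratum == s]
    a <- a[is.finite(a)]
    data.frame(
      stratum = s, n_reps = length(a),
      mean_ability = if (length(a)) mean(a) else NA_real_,
      se_ability = if (length(a) > 1) stats::sd(a) / sqrt(length(a)) else NA_real_
    )
  }))
  summary$accuracy <- summary$mean_ability / full_corr
  structure(list(
    scheme = "hybrid_tset", stage = stage, trait = trait,
    per_replicate = per_rep, summary = summary,
    full_data_corr = full_corr, n_skipped = n_skipped
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s/%s trait=%s>\n", x$scheme, x$stage, x$trait))
  if (x$scheme == "male_gca") {
    cat(sprintf(
      "  ability %.3f +/- %.3f  full-data corr %.3f  accuracy %.3f\n",
      x$mean_ability, x$se_ability, x$full_data_corr, x$accuracy
    ))
  } else {
    print(x$summary, row.names = FALSE)
    cat(sprintf("  full-data corr %.3f  (%d replicate(s) skipped)\n",
      x$full_data_corr, x$n_skipped))
  }
  invisible(x)
}
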