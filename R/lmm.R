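#' Random-effect term with an optional covariance kernel
#'
#' @param label term label (e.g. `"F"`, `"M"`, `"FM"`, `"H"`, `"E"`).
#' @param factors character vector of column names in the model data; when
#'   several are given the effect is on their interaction (levels pasted
#'   with `":"`).
#' @param kernel a [relationship_matrix()] (or labeled symmetric matrix)
#'   whose ids cover every observed level, or `NULL` for an identity
#'   covariance over the observed levels.
#' @return A `rand_term` list.
#' @export
rand_term <- function(label, factors, kernel = NULL) {
  stopifnot(is.character(label), length(label) == 1, is.character(factors))
  if (!is.null(kernel)) {
    kernel <- as.matrix(kernel)
    if (is.null(rownames(kernel))) stop("kernel must carry level ids as dimnames")
  }
  structure(list(label = label, factors = factors, kernel = kernel),
    class = "rand_term")
}

#' Declarative mixed-model specification
#'
#' Describes the model `y = X b + sum_t Z_t u_t + e` with
#' `u_t ~ N(0, K_t sigma2_t)` and `e ~ N(0, I sigma2_e)`.  Rows with a
#' missing response are dropped (complete-case per trait).
#'
#' @param response name of the response column.
#' @param data a data frame of plot-level records (one row per experimental
#'   unit).
#' @param fixed one-sided formula for the fixed effects (default `~ 1`).
#' @param random list of [rand_term()]s.
#' @return A `mixed_model_spec` list with the complete-case data attached.
#' @export
mixed_model_spec <- function(response, data, fixed = ~1, random = list()) {
  stopifnot(is.character(response), response %in% names(data))
  for (tm in random) {
    stopifnot(inherits(tm, "rand_term"))
    missing_cols <- setdiff(tm$factors, names(data))
    if (length(missing_cols))
      stop(sprintf(
        "term '%s': column(s) %s not in data", tm$label,
        paste(missing_cols, collapse = ", ")
      ))
  }
  labels <- vapply(random, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate random term labels")
  keep <- !is.na(data[[response]])
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop("no non-missing observations for response ", response)
  structure(
    list(response = response, fixed = fixed, random = random, data = data),
    class = "mixed_model_spec"
  )
}

term_levels_observed <- function(spec, tm) {
  vals <- spec$data[tm$factors]
  obs <- if (length(tm$factors) == 1) as.character(vals[[1]]) else
    do.call(paste, c(vals, sep = ":"))
  obs
}

# Build the numerical skeleton shared by all evaluations of one spec:
# response, fixed design, per-term incidence and kernel inverses, and the
# (unscaled) normal-equation blocks M0 = W'W, rhs0 = W'y.
prepare_mm <- function(spec) {
  data <- spec$data
  y <- data[[spec$response]]
  n <- length(y)
  X <- stats::model.matrix(spec$fixed, data)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular fixed-effect design; check for redundant covariates")
  terms <- lapply(spec$random, function(tm) {
    obs <- term_levels_observed(spec, tm)
    if (is.null(tm$kernel)) {
      levels <- sort(unique(obs))
      K <- NULL
    } else {
      levels <- rownames(tm$kernel)
      extra <- setdiff(unique(obs), levels)
      if (length(extra))
        stop(sprintf(
          "term '%s': kernel lacks observed level(s) %s", tm$label,
          paste(utils::head(extra, 5), collapse = ", ")
        ))
      K <- tm$kernel
    }
    q <- length(levels)
    j <- match(obs, levels)
    Z <- Matrix::sparseMatrix(
      i = seq_len(n), j = j, x = 1,
      dims = c(n, q), dimnames = list(NULL, levels)
    )
    if (is.null(K)) {
      Kinv <- Matrix::Diagonal(q)
      logdetK <- 0
    } else {
      ch <- chol_with_jitter(K)
      Kinv <- chol2inv(ch$chol)
      logdetK <- 2 * sum(log(diag(ch$chol)))
    }
    n_obs_level <- tabulate(j, nbins = q)
    list(
      label = tm$label, levels = levels, q = q, Z = Z,
      K = K, Kinv = as.matrix(Kinv), logdetK = logdetK,
      n_obs_level = n_obs_level
    )
  })
  W <- cbind(Matrix::Matrix(X, sparse = TRUE),
    do.call(cbind, lapply(terms, `[[`, "Z")))
  M0 <- as.matrix(Matrix::crossprod(W))
  rhs0 <- as.numeric(Matrix::crossprod(W, y))
  qs <- vapply(terms, `[[`, 0L, "q")
  ends <- p + cumsum(qs)
  starts <- c(p + 1, utils::head(ends, -1) + 1)
  idx <- Map(seq, starts, ends)
  list(
    y = y, n = n, X = X, p = p, W = W, M0 = M0, rhs0 = rhs0,
    yty = sum(y^2), terms = terms, idx = idx, r = length(terms)
  )
}

chol_with_jitter <- function(K, max_tries = 6) {
  K <- as.matrix(K)
  jit <- 0
  base <- mean(diag(K))
  for (i in seq_len(max_tries)) {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = jit))
    jit <- if (jit == 0) 1e-10 * max(base, 1) else jit * 100
  }
  stop("kernel is numerically singular even after jitter")
}

# Assemble and factor the (sigma-scaled) MME coefficient matrix
#   C = [X'X  X'Z; Z'X  Z'Z] / s_e + blockdiag(0, Kinv_t / s_t)
# and solve for (beta, u).  Returns enough to evaluate the REML deviance:
#   -2 logL = n log s_e + sum_t (q_t log s_t + log|K_t|)
#             + log|C| + y'Py + (n - p) log 2 pi
mme_eval <- function(prep, sigma, want_inverse = FALSE) {
  r <- prep$r
  s_e <- sigma[r + 1]
  C <- prep$M0 / s_e
  for (t in seq_len(r)) {
    it <- prep$idx[[t]]
    C[it, it] <- C[it, it] + prep$terms[[t]]$Kinv / sigma[t]
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    C <- C + diag(1e-8 * mean(diag(C)), nrow(C))
    ch <- chol(C)
  }
  rhs <- prep$rhs0 / s_e
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  yPy <- (prep$yty - sum(sol * prep$rhs0)) / s_e
  logdetC <- 2 * sum(log(diag(ch)))
  m2ll <- prep$n * log(s_e) + logdetC + yPy +
    (prep$n - prep$p) * log(2 * pi)
  for (t in seq_len(r))
    m2ll <- m2ll + prep$terms[[t]]$q * log(sigma[t]) + prep$terms[[t]]$logdetK
  out <- list(
    sigma = sigma, chol = ch, sol = sol, yPy = yPy, m2ll = m2ll
  )
  if (want_inverse) out$Tinv <- chol2inv(ch)
  out
}

# Scores, EM updates and the average-information matrix at `sigma`.
mme_derivs <- function(prep, ev) {
  r <- prep$r
  sigma <- ev$sigma
  s_e <- sigma[r + 1]
  Tinv <- ev$Tinv
  ehat <- prep$y - as.numeric(prep$W %*% ev$sol)
  Py <- ehat / s_e
  trPA <- uKu <- trKT <- numeric(r)
  score <- numeric(r + 1)
  em <- numeric(r + 1)
  Fm <- matrix(0, prep$n, r + 1)
  for (t in seq_len(r)) {
    it <- prep$idx[[t]]
    term <- prep$terms[[t]]
    Ttt <- Tinv[it, it, drop = FALSE]
    trKT[t] <- sum(term$Kinv * Ttt)
    u <- ev$sol[it]
    uKu[t] <- as.numeric(crossprod(u, term$Kinv %*% u))
    trPA[t] <- (term$q - trKT[t] / sigma[t]) / sigma[t]
    score[t] <- -0.5 * (trPA[t] - uKu[t] / sigma[t]^2)
    em[t] <- (uKu[t] + trKT[t]) / term$q
    w <- as.numeric(Matrix::crossprod(term$Z, Py))
    Kw <- if (is.null(term$K)) w else as.numeric(term$K %*% w)
    Fm[, t] <- as.numeric(term$Z %*% Kw)
  }
  trP <- (prep$n - prep$p - sum(sigma[seq_len(r)] * trPA)) / s_e
  score[r + 1] <- -0.5 * (trP - sum(ehat^2) / s_e^2)
  em[r + 1] <- (prep$yty - sum(ev$sol * prep$rhs0)) / (prep$n - prep$p)
  Fm[, r + 1] <- Py
  rhsF <- as.matrix(Matrix::crossprod(prep$W, Fm)) / s_e
  solF <- backsolve(ev$chol, backsolve(ev$chol, rhsF, transpose = TRUE))
  PF <- (Fm - as.matrix(prep$W %*% solF)) / s_e
  AI <- 0.5 * crossprod(Fm, PF)
  AI <- (AI + t(AI)) / 2
  list(score = score, em = em, AI = AI, ehat = ehat)
}

#' Build Henderson's mixed-model equations
#'
#' Exposes the coefficient matrix and right-hand side of the mixed-model
#' equations for a specification at given variance components, in the
#' scaling whose inverse directly contains prediction error (co)variances:
#' `C = [X'X, X'Z; Z'X, Z'Z] / sigma2_e + blockdiag(0, K_t^{-1} / sigma2_t)`.
#' A term whose variance is exactly zero is absorbed (dropped; its effects
#' are fixed at zero).  Solving the system yields BLUEs/BLUPs identical to
#' generalized least squares on the marginal model.
#'
#' @param spec a [mixed_model_spec()].
#' @param sigma named numeric vector of variance components: one entry per
#'   random term label plus `"residual"` (strictly positive).
#' @return List with `C`, `rhs`, `solution` (`beta` then stacked `u`),
#'   `index` (block indices), and `labels`.
#' @export
build_mme <- function(spec, sigma) {
  labels <- vapply(spec$random, `[[`, "", "label")
  if (!all(c(labels, "residual") %in% names(sigma)))
    stop("sigma must be named with every term label plus 'residual'")
  if (sigma[["residual"]] <= 0) stop("residual variance must be > 0")
  drop <- labels[sigma[labels] == 0]
  if (length(drop))
    spec$random <- spec$random[!labels %in% drop]
  labels <- vapply(spec$random, `[[`, "", "label")
  prep <- prepare_mm(spec)
  sig <- c(unname(sigma[labels]), sigma[["residual"]])
  ev <- mme_eval(prep, sig)
  r <- prep$r
  C <- prep$M0 / sig[r + 1]
  for (t in seq_len(r)) {
    it <- prep$idx[[t]]
    C[it, it] <- C[it, it] + prep$terms[[t]]$Kinv / sig[t]
  }
  list(
    C = C, rhs = prep$rhs0 / sig[r + 1], solution = ev$sol,
    index = c(list(fixed = seq_len(prep$p)),
      stats::setNames(prep$idx, labels)),
    labels = labels, absorbed = drop
  )
}

#' Fit a mixed model by average-information REML
#'
#' Maximizes the restricted likelihood over the variance components of a
#' [mixed_model_spec()] using average-information (AI) updates with step
#' halving, falling back to an EM update whenever the AI step fails to
#' improve the restricted log-likelihood.  Components are clamped at a
#' small floor (`1e-8` times the phenotypic variance) and flagged as
#' boundary estimates.  The fit is deterministic given the data and
#' starting values.
#'
#' @param spec a [mixed_model_spec()].
#' @param init optional named starting values (term labels + `"residual"`);
#'   default splits the phenotypic variance equally over all components.
#' @param tol relative-change convergence tolerance on every component
#'   (default `1e-6`).
#' @param logl_tol absolute convergence tolerance on the restricted
#'   log-likelihood (default `1e-8`).
#' @param max_iter iteration cap (default 200); non-convergence returns the
#'   current estimates with `converged = FALSE` and a warning.
#' @param verbose print an iteration trace.
#' @return An object of class `gblup_fit`: variance components (`sigma2`,
#'   with boundary flags), `logLik`, `AIC`/`BIC` (k = number of variance
#'   parameters), fixed-effect estimates with standard errors, per-term
#'   BLUPs with prediction error variances (`blups`), fitted values,
#'   the AI-based covariance of the variance components (`vcov_sigma2`),
#'   and the iteration trace.
#' @export
fit_reml <- function(spec, init = NULL, tol = 1e-6, logl_tol = 1e-8,
                     max_iter = 200, verbose = FALSE) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  prep <- prepare_mm(spec)
  r <- prep$r
  k <- r + 1
  if (prep$n < prep$p + k + 1)
    stop("fewer observations than parameters to estimate")
  vp <- stats::var(prep$y)
  if (!is.finite(vp) || vp <= 0) vp <- max(mean(prep$y)^2, 1) * 1e-6
  floor_val <- 1e-8 * vp
  labels <- c(vapply(prep$terms, `[[`, "", "label"), "residual")
  sigma <- if (is.null(init)) rep(vp / k, k) else {
    if (!all(labels %in% names(init)))
      stop("init must name every term plus 'residual'")
    s0 <- pmax(as.numeric(init[labels]), floor_val)
    # warm starts may carry boundary values from a fit on slightly
    # different data; snap them to this data's floor
    s0[s0 < 100 * floor_val] <- floor_val
    s0
  }
  ev <- mme_eval(prep, sigma, want_inverse = TRUE)
  dv <- mme_derivs(prep, ev)
  trace <- data.frame(iter = 0, logLik = -ev$m2ll / 2, step = "init")
  converged <- FALSE
  iter <- 0
  n_stall <- 0L
  n_slow_em <- 0L
  while (iter < max_iter) {
    iter <- iter + 1
    step_used <- "none"
    cand <- NULL
    # AI step on the free components (those not pinned at the floor with a
    # negative score), with step halving
    at_floor <- sigma <= floor_val * 100
    free <- !(at_floor & dv$score < 0)
    delta <- NULL
    if (any(free)) {
      Af <- dv$AI[free, free, drop = FALSE]
      Af <- Af + diag(1e-10 * max(diag(Af), 1), nrow(Af))
      df_ <- tryCatch(solve(Af, dv$score[free]), error = function(e) NULL)
      if (!is.null(df_)) {
        delta <- rep(0, k)
        delta[free] <- df_
      }
    }
    if (!is.null(delta) && all(is.finite(delta)) && iter > 1) {
      # restrain each update to a bounded multiplicative change so a single
      # aggressive step cannot pin a component to the floor (a local trap)
      lo <- pmax(sigma * 0.1, floor_val)
      hi <- pmax(sigma * 10, 1e-3 * vp)
      step <- 1
      for (h in seq_len(8)) {
        prop <- pmin(pmax(sigma + step * delta, lo), hi)
        pe <- tryCatch(mme_eval(prep, prop), error = function(e) NULL)
        if (!is.null(pe) && is.finite(pe$m2ll) && pe$m2ll <= ev$m2ll + 1e-10) {
          cand <- list(sigma = prop, ev = pe); step_used <- "AI"
          break
        }
        step <- step / 2
      }
    }
    if (is.null(cand)) {
      prop <- pmax(dv$em, floor_val)
      pe <- tryCatch(mme_eval(prep, prop), error = function(e) NULL)
      if (!is.null(pe) && is.finite(pe$m2ll) && pe$m2ll <= ev$m2ll + 1e-6) {
        cand <- list(sigma = prop, ev = pe); step_used <- "EM"
      }
    }
    if (is.null(cand)) { converged <- TRUE; break }  # numerical limit
    rel_change <- max(abs(cand$sigma - sigma) / pmax(sigma, floor_val))
    dll <- abs(cand$ev$m2ll - ev$m2ll) / 2
    sigma <- cand$sigma
    ev <- cand$ev
    ev$Tinv <- chol2inv(ev$chol)
    dv <- mme_derivs(prep, ev)
    trace <- rbind(trace,
      data.frame(iter = iter, logLik = -ev$m2ll / 2, step = step_used))
    if (verbose)
      message(sprintf("it %3d [%s] logL = %.6f  sigma = %s", iter, step_used,
        -ev$m2ll / 2, paste(signif(sigma, 4), collapse = " ")))
    n_stall <- if (dll < 1e-7) n_stall + 1L else 0L
    n_slow_em <- if (step_used == "EM" && dll < 1e-5) n_slow_em + 1L else 0L
    if ((rel_change < tol && dll < logl_tol) ||
        (dll < logl_tol && rel_change < 1e-3 && step_used == "EM") ||
        n_stall >= 3L ||     # likelihood flat to 1e-7 for 3 iterations
        n_slow_em >= 10L) {  # EM crawling below 1e-5 gain per iteration
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  boundary <- sigma <= floor_val * (1 + 1e-12)
  names(sigma) <- names(boundary) <- labels
  vcov_sigma2 <- tryCatch(solve(dv$AI), error = function(e) NULL)
  if (!is.null(vcov_sigma2)) dimnames(vcov_sigma2) <- list(labels, labels)
  Tinv <- ev$Tinv
  beta <- stats::setNames(ev$sol[seq_len(prep$p)], colnames(prep$X))
  se_beta <- sqrt(pmax(diag(Tinv)[seq_len(prep$p)], 0))
  blups <- stats::setNames(vector("list", r), utils::head(labels, -1))
  for (t in seq_len(r)) {
    it <- prep$idx[[t]]
    term <- prep$terms[[t]]
    blups[[t]] <- data.frame(
      level = term$levels,
      blup = ev$sol[it],
      pev = pmax(diag(Tinv)[it], 0),
      n_obs = term$n_obs_level,
      stringsAsFactors = FALSE
    )
  }
  logLik <- -ev$m2ll / 2
  structure(list(
    sigma2 = sigma, boundary = boundary, logLik = logLik,
    AIC = ev$m2ll + 2 * k, BIC = ev$m2ll + k * log(prep$n),
    n = prep$n, k = k, converged = converged, iterations = iter,
    beta = beta, se_beta = se_beta, blups = blups,
    fitted = as.numeric(prep$W %*% ev$sol),
    residuals = prep$y - as.numeric(prep$W %*% ev$sol),
    vcov_sigma2 = vcov_sigma2, trace = trace, spec = spec
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> %s ~ %d random term(s), n = %d\n  logLik %.3f  AIC %.2f  BIC %.2f  (%s, %d it)\n",
    x$spec$response, length(x$blups), x$n, x$logLik, x$AIC, x$BIC,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  cat("  sigma2:",
    paste(sprintf("%s=%.4g%s", names(x$sigma2), x$sigma2,
      ifelse(x$boundary, "*", "")), collapse = "  "), "\n")
  if (any(x$boundary)) cat("  (* at boundary floor)\n")
  invisible(x)
}

#' Extract per-level BLUPs and prediction error variances
#'
#' @param fit a [fit_reml()] result.
#' @param term random term label; omit to get the full named list.
#' @return Data frame with columns `level`, `blup`, `pev`, `n_obs` (or a
#'   list thereof).
#' @export
extract_blups <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (is.null(term)) return(fit$blups)
  if (!term %in% names(fit$blups))
    stop("no random term '", term, "' in this fit")
  fit$blups[[term]]
}
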