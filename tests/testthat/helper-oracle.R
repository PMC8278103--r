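# Independent generalized-least-squares oracle on the explicit marginal
# covariance V = sum_t sigma2_t Z_t K_t Z_t' + sigma2_e I.  Dense, O(n^3);
# only for small instances.  Kept deliberately independent of the MME code
# path it checks.
gls_oracle <- function(spec, sigma) {
  data <- spec$data
  y <- data[[spec$response]]
  n <- length(y)
  X <- model.matrix(spec$fixed, data)
  V <- diag(sigma[["residual"]], n)
  Zs <- list(); Gs <- list()
  for (tm in spec$random) {
    obs <- if (length(tm$factors) == 1) as.character(data[[tm$factors]]) else
      do.call(paste, c(data[tm$factors], sep = ":"))
    levels <- if (is.null(tm$kernel)) sort(unique(obs)) else rownames(tm$kernel)
    Z <- matrix(0, n, length(levels))
    Z[cbind(seq_len(n), match(obs, levels))] <- 1
    K <- if (is.null(tm$kernel)) diag(length(levels)) else as.matrix(tm$kernel)
    G <- K * sigma[[tm$label]]
    V <- V + Z %*% G %*% t(Z)
    Zs[[tm$label]] <- Z; Gs[[tm$label]] <- G
  }
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  P <- Vi - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  res <- y - X %*% beta
  out <- list(beta = as.numeric(beta))
  for (lb in names(Zs)) {
    G <- Gs[[lb]]; Z <- Zs[[lb]]
    out[[paste0("u_", lb)]] <- as.numeric(G %*% t(Z) %*% Vi %*% res)
    out[[paste0("pev_", lb)]] <- diag(G - G %*% t(Z) %*% P %*% Z %*% G)
  }
  out$m2ll <- as.numeric(
    determinant(V)$modulus +
      determinant(t(X) %*% Vi %*% X)$modulus +
      t(res) %*% Vi %*% res + (n - ncol(X)) * log(2 * pi)
  )
  out
}

# Random small mixed-model instance: <= `max_n` observations, 1-4 random
# terms, a mix of identity and dense PSD kernels.
random_instance <- function(seed, max_n = 40) {
  set.seed(seed)
  n <- sample(12:max_n, 1)
  n_terms <- sample(1:4, 1)
  data <- data.frame(y = rnorm(n, 10, 2))
  random <- list()
  sigma <- c()
  for (t in seq_len(n_terms)) {
    q <- sample(3:6, 1)
    col <- paste0("g", t)
    data[[col]] <- sample(paste0("L", seq_len(q)), n, replace = TRUE)
    kernel <- NULL
    if (runif(1) < 0.5) {
      A <- matrix(rnorm(q * q), q)
      K <- crossprod(A) / q + diag(q) * 0.3
      dimnames(K) <- list(paste0("L", seq_len(q)), paste0("L", seq_len(q)))
      kernel <- K
    }
    random[[t]] <- rand_term(paste0("T", t), col, kernel)
    sigma[paste0("T", t)] <- runif(1, 0.3, 3)
  }
  sigma["residual"] <- runif(1, 0.3, 2)
  # add a genuine signal so estimates are not degenerate
  data$y <- data$y + rnorm(n)
  list(
    spec = mixed_model_spec("y", data, ~1, random),
    sigma = sigma
  )
}

# Solve the MME at fixed variance components through the package internals
# and return beta, per-term BLUPs and PEVs in oracle-compatible layout.
mme_solution <- function(spec, sigma) {
  prep <- gcablup:::prepare_mm(spec)
  labels <- vapply(prep$terms, `[[`, "", "label")
  sig <- c(unname(sigma[labels]), sigma[["residual"]])
  ev <- gcablup:::mme_eval(prep, sig, want_inverse = TRUE)
  out <- list(beta = ev$sol[seq_len(prep$p)], m2ll = ev$m2ll)
  for (t in seq_along(prep$terms)) {
    it <- prep$idx[[t]]
    out[[paste0("u_", labels[t])]] <- ev$sol[it]
    out[[paste0("pev_", labels[t])]] <- diag(ev$Tinv)[it]
  }
  out
}
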