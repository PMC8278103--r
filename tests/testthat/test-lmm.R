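test_that("MME solutions match the marginal GLS oracle on random instances", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    got <- mme_solution(inst$spec, inst$sigma)
    want <- gls_oracle(inst$spec, inst$sigma)
    expect_equal(got$beta, want$beta, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(got$m2ll, want$m2ll, tolerance = 1e-8)
    for (tm in inst$spec$random) {
      lb <- tm$label
      expect_equal(got[[paste0("u_", lb)]], want[[paste0("u_", lb)]],
        tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(got[[paste0("pev_", lb)]], want[[paste0("pev_", lb)]],
        tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("REML on balanced one-way designs equals the ANOVA estimators", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- rep(paste0("g", 1:5), each = 4)
    y <- rnorm(20, 5) + rep(rnorm(5, 0, 2), each = 4)
    a <- anova(stats::aov(y ~ g))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    if (msb <= msw) next  # interior solutions only
    fit <- fit_reml(mixed_model_spec("y", data.frame(g = g, y = y),
      random = list(rand_term("G", "g"))))
    expect_equal(unname(fit$sigma2[["G"]]), (msb - msw) / 4, tolerance = 1e-6)
    expect_equal(unname(fit$sigma2[["residual"]]), msw, tolerance = 1e-6)
  }
})

test_that("REML agrees with lme4 on an identity-kernel two-term model", {
  skip_if_not_installed("lme4")
  set.seed(10)
  d <- expand.grid(g = paste0("g", 1:8), b = paste0("b", 1:3),
    stringsAsFactors = FALSE)
  d <- d[rep(seq_len(nrow(d)), 2), ]
  d$y <- rnorm(nrow(d), 4) + rep(rnorm(8, 0, 1.4), 6) +
    rnorm(nrow(d), 0, 0.3)[as.integer(factor(d$b))]
  fit <- fit_reml(mixed_model_spec("y", d, random = list(
    rand_term("G", "g"), rand_term("B", "b"))))
  lf <- lme4::lmer(y ~ 1 + (1 | g) + (1 | b), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  lme4_sig <- setNames(vc$vcov, sub("^$", "residual", vc$grp))
  expect_equal(unname(fit$sigma2[["G"]]),
    unname(lme4_sig[["g"]]), tolerance = 1e-4)
  expect_equal(unname(fit$sigma2[["residual"]]),
    unname(lme4_sig[["Residual"]]), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("BLUPs shrink as theory dictates at fixed variance components", {
  # balanced 2-level random effect: BLUP = shrink * (group mean - grand mean)
  set.seed(2)
  d <- data.frame(
    g = rep(c("a", "b"), each = 6),
    y = rnorm(12, 10) + rep(c(-1.5, 1.5), each = 6)
  )
  spec <- mixed_model_spec("y", d, random = list(rand_term("G", "g")))
  sg <- 1.7; se <- 0.9
  got <- mme_solution(spec, c(G = sg, residual = se))
  shrink <- 6 * sg / (6 * sg + se)
  gm <- mean(d$y)
  grp <- tapply(d$y, d$g, mean)
  expect_equal(got$u_G, as.numeric(shrink * (grp - gm)), tolerance = 1e-8)
  # total shrinkage as the variance ratio collapses
  tiny <- mme_solution(spec, c(G = 1e-10, residual = 1))
  expect_lt(max(abs(tiny$u_G)), 1e-8)
  # identity-kernel balanced BLUPs sum to zero
  expect_equal(sum(got$u_G), 0, tolerance = 1e-8)
})

test_that("unobserved kernel levels borrow information; identity levels do not", {
  set.seed(3)
  ids <- paste0("L", 1:6)
  A <- matrix(rnorm(36), 6)
  K <- crossprod(A) / 6 + diag(6) * 0.2
  dimnames(K) <- list(ids, ids)
  d <- data.frame(
    g = rep(ids[1:5], each = 4),
    y = rnorm(20, 0, 1) + rep(rnorm(5, 0, 2), each = 4)
  )
  spec <- mixed_model_spec("y", d,
    random = list(rand_term("G", "g", kernel = K)))
  sig <- c(G = 2, residual = 1)
  got <- mme_solution(spec, sig)
  want <- gls_oracle(spec, sig)
  expect_equal(got$u_G, want$u_G, tolerance = 1e-8)
  # level 6 has no data: its PEV is below sigma2 * K_66 because its
  # relatives carry information, and its BLUP need not be zero
  expect_lt(got$pev_G[6], sig[["G"]] * K[6, 6])
  # identity kernel over declared levels: a no-data level keeps BLUP 0 and
  # full prior PEV
  I6 <- identity_kernel(ids)
  spec_i <- mixed_model_spec("y", d,
    random = list(rand_term("G", "g", kernel = I6)))
  got_i <- mme_solution(spec_i, sig)
  expect_equal(got_i$u_G[6], 0, tolerance = 1e-10)
  expect_equal(got_i$pev_G[6], sig[["G"]], tolerance = 1e-10)
})

test_that("fits are deterministic, permutation-invariant, and monotone in logL", {
  st <- tiny_study()
  spec1 <- model_catalog("yield", "gca", st$phenotypes)
  f1 <- fit_reml(spec1)
  f2 <- fit_reml(spec1)
  expect_identical(f1$sigma2, f2$sigma2)
  perm <- sample(nrow(st$phenotypes))
  spec_p <- model_catalog("yield", "gca", st$phenotypes[perm, ])
  f3 <- fit_reml(spec_p)
  expect_equal(f1$sigma2, f3$sigma2, tolerance = 1e-8)
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-8)
  bm1 <- extract_blups(f1, "M"); bm3 <- extract_blups(f3, "M")
  expect_equal(bm1$blup[order(bm1$level)], bm3$blup[order(bm3$level)],
    tolerance = 1e-8)
  # accepted iterations never decrease the restricted log-likelihood
  expect_true(all(diff(f1$trace$logLik) > -1e-6))
  # information criteria are recomputable from logL and k
  expect_equal(f1$AIC, -2 * f1$logLik + 2 * f1$k)
  expect_equal(f1$BIC, -2 * f1$logLik + f1$k * log(f1$n))
})

test_that("degenerate inputs are handled: zero variance, rank, data checks", {
  d <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = 5)
  fit <- suppressWarnings(fit_reml(
    mixed_model_spec("y", d, random = list(rand_term("G", "g")))
  ))
  expect_true(all(fit$boundary | fit$sigma2 < 1e-6))
  # singular fixed-effect design
  d2 <- data.frame(g = rep(c("a", "b"), 6), x = 1, y = rnorm(12))
  expect_error(
    fit_reml(mixed_model_spec("y", d2, fixed = ~x + I(2 * x),
      random = list(rand_term("G", "g")))),
    "singular"
  )
  # kernel must cover observed levels
  K <- identity_kernel(c("a", "b"))
  d3 <- data.frame(g = c("a", "b", "c", "a", "b", "c"), y = rnorm(6))
  expect_error(
    fit_reml(mixed_model_spec("y", d3,
      random = list(rand_term("G", "g", kernel = K)))),
    "lacks observed level"
  )
  # too few observations
  d4 <- data.frame(g = c("a", "b"), y = rnorm(2))
  expect_error(
    fit_reml(mixed_model_spec("y", d4, random = list(rand_term("G", "g")))),
    "fewer observations"
  )
  expect_error(
    mixed_model_spec("y", data.frame(y = rep(NA_real_, 4))),
    "no non-missing"
  )
})

test_that("build_mme absorbs zero-variance terms and validates sigma", {
  set.seed(5)
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 4),
    h = rep(c("u", "v"), 6), y = rnorm(12)
  )
  spec <- mixed_model_spec("y", d, random = list(
    rand_term("G", "g"), rand_term("H", "h")))
  mme <- build_mme(spec, c(G = 1, H = 0, residual = 1))
  expect_identical(mme$absorbed, "H")
  expect_false("H" %in% names(mme$index))
  expect_error(build_mme(spec, c(G = 1, H = 1, residual = 0)), "residual")
  expect_error(build_mme(spec, c(G = 1, residual = 1)), "named")
})

test_that("the SCA term is detected by model comparison when present", {
  # data carrying real female-by-male interaction variance: the GCA + SCA
  # model should win on AIC in most replicates
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed * 7)
    nf <- 4; nm <- 12
    d <- expand.grid(
      female = paste0("f", 1:nf), male = paste0("m", 1:nm),
      rep = 1:3, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    fe <- rnorm(nf, 0, 1.5); me <- rnorm(nm, 0, 1.5)
    sca <- matrix(rnorm(nf * nm, 0, 2), nf, nm)
    idx <- cbind(as.integer(factor(d$female)), as.integer(factor(d$male)))
    d$y <- 10 + fe[idx[, 1]] + me[idx[, 2]] + sca[idx] + rnorm(nrow(d), 0, 1)
    d$fm <- paste(d$female, d$male, sep = "/")
    base <- list(rand_term("F", "female"), rand_term("M", "male"))
    f_gca <- fit_reml(mixed_model_spec("y", d, random = base))
    f_sca <- fit_reml(mixed_model_spec("y", d,
      random = c(base, list(rand_term("FM", "fm")))))
    if (f_sca$AIC < f_gca$AIC) wins <- wins + 1L
  }
  expect_gt(wins, 10)
})
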