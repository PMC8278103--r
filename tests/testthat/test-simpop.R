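test_that("parent simulation is seed-stable and degenerates correctly", {
  cfg <- tiny_cfg(seed = 7)
  p1 <- simulate_parents(cfg)
  p2 <- simulate_parents(cfg)
  expect_identical(p1$males$dosages, p2$males$dosages)
  expect_identical(p1$females$dosages, p2$females$dosages)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$phenotypes, st2$phenotypes)
  expect_identical(st1$true_values, st2$true_values)
  # recurrent fraction 1: every male is the recurrent parent, no het
  cfg_r <- tiny_cfg(seed = 3)
  cfg_r$recurrent_genome_fraction <- 1
  pr <- simulate_parents(cfg_r)
  expect_true(all(pr$males$dosages %in% c(0, 2)))
  expect_equal(
    max(apply(pr$males$dosages, 2, function(x) length(unique(x)))), 1
  )
  cfg_bad <- tiny_cfg()
  cfg_bad$n_donor_families <- 1000
  expect_error(simulate_parents(cfg_bad), "families")
})

test_that("male genomes carry the configured recurrent-parent fraction", {
  # Monte Carlo at the default population scale over 20 seeds
  fracs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 1000 + s)
    mean(attr(simulate_parents(cfg)$males, "recurrent_fraction"))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.75), 0.03)
  # females and males form distinct clusters: cross-pool SDAF far above
  # within-pool SDAF
  cfg <- tiny_cfg(seed = 5)
  p <- simulate_parents(cfg)
  ff <- allele_frequencies(p$females)$per_individual
  fm <- allele_frequencies(p$males)$per_individual
  cross <- sdaf(ff[1, ], fm[1, ])
  within_f <- sdaf(ff[1, ], ff[2, ])
  expect_gt(cross, 2 * within_f)
})

test_that("the default crossing design reproduces the study histogram", {
  cfg <- sim_config(seed = 2)
  des <- simulate_crossing_design(
    cfg, sprintf("F%02d", 1:13), sprintf("M%03d", 1:564)
  )
  tested <- des[des$tested, ]
  expect_equal(nrow(tested), 938)
  counts <- table(tested$male)
  expect_equal(length(counts), 382)          # histogram totals 382 males
  expect_equal(max(counts), 5)               # no male crossed to all 6
  expect_equal(as.vector(table(factor(as.vector(counts), levels = 1:5))),
    c(85, 108, 124, 60, 5))
  # tested and untested partition the full grid
  expect_equal(nrow(des), 13 * 564)
  expect_false(any(duplicated(des$hybrid)))
  # every pair of used females overlaps in some male
  fu <- attr(des, "females_used")
  sets <- split(tested$female, tested$male)
  for (pr in utils::combn(fu, 2, simplify = FALSE)) {
    expect_true(any(vapply(sets, function(s) all(pr %in% s), logical(1))))
  }
})

test_that("crossing edge cases behave: one female, infeasible requests", {
  cfg1 <- tiny_cfg()
  cfg1$crossing <- crossing_config(1, 10, 10, female_count_dist = NULL)
  des <- simulate_crossing_design(cfg1, paste0("F0", 1:5), sprintf("M%03d", 1:36))
  tested <- des[des$tested, ]
  expect_equal(length(unique(tested$female)), 1L)
  cfg2 <- tiny_cfg()
  cfg2$crossing <- crossing_config(3, 10, 25, female_count_dist = NULL)
  expect_error(
    simulate_crossing_design(cfg2, paste0("F0", 1:5), sprintf("M%03d", 1:36)),
    "infeasible"
  )
  expect_error(crossing_config(4, 10, 50, NULL), "n_training")
})

test_that("phenotypes collapse to the grand mean when variances vanish", {
  cfg <- tiny_cfg(seed = 9, traits = list(
    flat = trait_sim(50, c(F = 0, M = 0, FM = 0, E = 0, FE = 0, ME = 0,
      B = 0, e = 1e-12), mph_shift = 0)
  ))
  cfg$missing_rep_rate <- 0
  st <- simulate_study(cfg)
  expect_lt(max(abs(st$phenotypes$flat - 50)), 1e-4)
  expect_equal(max(abs(st$true_values$flat$sca)), 0)
})

test_that("realized effect variances converge to the configured components", {
  # 200 males, sigma2_M = 4, other genetic variances 0
  vars <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_females = 4, n_cms = 3, n_males = 200, n_donor_families = 8,
      n_sites = 500,
      crossing = crossing_config(3, 200, 400, female_count_dist = NULL),
      traits = list(t1 = trait_sim(10, c(F = 0, M = 4, FM = 0, E = 0,
        FE = 0, ME = 0, B = 0, e = 1))),
      seed = 3000 + s
    )
    st <- simulate_study(cfg)
    var(st$true_values$t1$male_gca)
  }, numeric(1))
  expect_lt(abs(mean(vars) - 4), 0.8)
})

test_that("the simulated study satisfies downstream preconditions", {
  st <- tiny_study()
  phen <- st$phenotypes
  # every phenotyped hybrid appears in the design as tested
  hyb <- unique(phen$genotype[phen$type == "hybrid"])
  expect_true(all(hyb %in% st$design$hybrid[st$design$tested]))
  # truth covers every parent and designed hybrid
  tv <- st$true_values[[1]]
  expect_setequal(names(tv$female_gca), rownames(st$female_genotypes$dosages))
  expect_setequal(names(tv$male_gca), rownames(st$male_genotypes$dosages))
  expect_setequal(names(tv$hybrid_value), st$design$hybrid)
  # single-environment traits observed only in environment 1
  pe <- phen$env[!is.na(phen$potential_yield)]
  expect_identical(unique(pe), "E1")
  # parents panels imputed/complete and polymorphic
  expect_false(anyNA(st$female_genotypes$dosages))
  expect_false(anyNA(st$male_genotypes$dosages))
  # kernels are PSD and cover the parents
  for (K in st$kernels) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  # and every catalog stage accepts the study
  GH <- suppressMessages(hybrid_kernel(st))
  kern <- c(st$kernels, list(G_H = GH))
  for (stg in c("hybrid_value", "hybrid_value_genomic", "gca", "gca_sca",
                "gca_genomic", "gca_sca_genomic", "heterosis")) {
    expect_s3_class(
      model_catalog("yield", stg, phen, kern), "mixed_model_spec"
    )
  }
})

test_that("hybrid mean shift and maintainer mapping feed heterosis analysis", {
  st <- tiny_study()
  tv <- st$true_values$yield
  expect_equal(tv$mph_shift, 0.32 * 36)
  # CMS females phenotyped through maintainer ids, TGMS through its own
  expect_identical(unname(st$maintainer_map[["F01"]]), "B_F01")
  expect_identical(unname(st$maintainer_map[["F05"]]), "F05")
  expect_true(all(unname(st$maintainer_map[st$cms]) %in% st$phenotypes$genotype))
})
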