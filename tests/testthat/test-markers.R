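test_that("site filters apply the het, site-count and MAC rules", {
  # 10 individuals; site A has 6/10 heterozygotes (0.6 > 0.5)
  dA <- c(1, 1, 1, 1, 1, 1, 0, 0, 2, 2)
  # site B: minor allele count 1 (< 3); site C: minor allele count 3
  dB <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 1)
  dC <- c(2, 2, 2, 2, 2, 2, 2, 1, 1, 1)
  # site D: only 2 non-missing calls
  dD <- c(2, 0, rep(NA, 8))
  g <- mm_of(cbind(A = dA, B = dB, C = dC, D = dD))
  spec <- site_filter_spec(
    max_het_fraction = 0.5, min_site_count = 5, min_minor_allele_count = 3
  )
  out <- filter_sites(g, spec)
  expect_identical(colnames(out$dosages), "C")
  rep <- attr(out, "filter_report")
  expect_equal(rep$dropped[rep$rule == "max_het_fraction"], 1)
  expect_equal(rep$dropped[rep$rule == "min_minor_allele_count"], 2)
})

test_that("filtering passes clean data unchanged and is idempotent", {
  set.seed(1)
  g <- mm_of(matrix(sample(c(0, 2), 60, replace = TRUE), 10))
  spec <- site_filter_spec(0.5, 5, 2)
  f1 <- filter_sites(g, spec)
  f2 <- filter_sites(f1, spec)
  expect_identical(f1$dosages, f2$dosages)
  clean <- mm_of(matrix(rep(c(0, 2), 10), nrow = 4, ncol = 5, byrow = TRUE))
  expect_identical(filter_sites(clean, site_filter_spec())$dosages, clean$dosages)
  empty <- marker_matrix(matrix(0, 3, 0,
    dimnames = list(paste0("i", 1:3), character(0))))
  expect_error(filter_sites(empty), "empty")
})

test_that("naive imputation fills per-site with documented tie rules", {
  g <- mm_of(cbind(a = c(0, 2, NA), b = c(2, 2, NA), c = c(0, 1, 2)))
  maj <- impute_naive(g, "major")
  expect_equal(unname(maj$dosages[3, "a"]), 0)  # tie 0 vs 2 -> lower
  expect_equal(unname(maj$dosages[3, "b"]), 2)
  mean_ <- impute_naive(g, "mean")
  expect_equal(unname(mean_$dosages[3, "b"]), 2)
  expect_identical(impute_naive(g, "mean")$dosages[, "c"], g$dosages[, "c"])
  full <- mm_of(matrix(c(0, 1, 2, 2), 2))
  expect_identical(impute_naive(full, "mean")$dosages, full$dosages)
  allna <- mm_of(cbind(x = c(NA, NA)))
  expect_error(impute_naive(allna), "fully missing")
})

test_that("hybrid genotypes are expected F1 dosages and parent-symmetric", {
  f <- mm_of(matrix(c(2, 2, 0, 1), 1, dimnames = list("f1", paste0("s", 1:4))))
  m <- mm_of(matrix(c(0, 2, 0, 0), 1, dimnames = list("m1", paste0("s", 1:4))))
  h <- infer_hybrid_genotypes(f, m, data.frame(female = "f1", male = "m1"))
  expect_equal(unname(h$dosages[1, ]), c(1, 2, 0, 0.5))
  expect_identical(rownames(h$dosages), "f1/m1")
  h_rev <- infer_hybrid_genotypes(m, f, data.frame(female = "m1", male = "f1"))
  expect_equal(unname(h_rev$dosages[1, ]), unname(h$dosages[1, ]))
  # allele mismatch at a shared site id must be named
  m_bad <- m
  m_bad$sites$alt[2] <- "C"
  expect_error(
    infer_hybrid_genotypes(f, m_bad, data.frame("f1", "m1")), "s2"
  )
})

test_that("allele frequencies are dosage/2 per individual and panel means", {
  g <- mm_of(matrix(c(2, 1, 0, 0), 4, 1))
  af <- allele_frequencies(g)
  expect_equal(unname(af$per_individual[, 1]), c(1, 0.5, 0, 0))
  expect_equal(unname(af$panel), 0.375)
  g2 <- mm_of(matrix(c(2, 0), 2, 1))
  expect_equal(unname(allele_frequencies(g2)$panel), 0.5)
  gna <- mm_of(matrix(c(2, NA), 2, 1))
  expect_error(allele_frequencies(gna), "missing")
})

test_that("SDAF matches its definition and invariances", {
  expect_equal(sdaf(c(1, 0.5, 0), c(0.5, 0.5, 0.5)), 0.5 / 3)
  expect_equal(sdaf(c(0.3, 0.8), c(0.3, 0.8)), 0)
  expect_equal(sdaf(c(1, 1), c(0, 0)), 1)
  expect_error(sdaf(1, c(0, 1)), "length")
  set.seed(4)
  for (i in 1:10) {
    p <- runif(50); q <- runif(50)
    expect_identical(sdaf(p, q), sdaf(q, p))
    expect_gte(sdaf(p, q), 0)
    # invariant to which allele is counted per site (flip both parents)
    flip <- runif(50) < 0.5
    pf <- ifelse(flip, 1 - p, p); qf <- ifelse(flip, 1 - q, q)
    expect_equal(sdaf(pf, qf), sdaf(p, q))
  }
})

test_that("the GRM matches the VanRaden formula on a hand example", {
  g <- mm_of(matrix(c(2, 0, 0, 2), 2, dimnames = list(c("a", "b"), c("s1", "s2"))))
  G <- grm(g)
  expect_equal(unclass(G)[1:2, 1:2], matrix(c(2, -2, -2, 2), 2,
    dimnames = list(c("a", "b"), c("a", "b"))), ignore_attr = TRUE)
  # duplicated individual: identical rows, off-diagonal equals diagonal
  g3 <- mm_of(matrix(c(2, 0, 2, 0, 2, 0, 1, 2, 1), 3, byrow = FALSE,
    dimnames = list(c("a", "b", "a2"), c("s1", "s2", "s3"))))
  g3$dosages["a2", ] <- g3$dosages["a", ]
  G3 <- suppressMessages(grm(g3, stabilize_epsilon = 0))
  expect_equal(G3["a", "a2"], G3["a", "a"], tolerance = 1e-10)
  expect_error(grm(mm_of(matrix(2, 3, 4))), "monomorphic")
})

test_that("GRM properties hold over random panels", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- matrix(rbinom(20 * 200, 2, rep(runif(200, 0.1, 0.9), each = 20)),
      20, 200)
    rownames(d) <- paste0("i", 1:20); colnames(d) <- paste0("s", 1:200)
    G <- suppressMessages(grm(marker_matrix(d), stabilize_epsilon = 0))
    expect_lt(max(abs(G - t(G))), 1e-10)
    expect_gt(mean(diag(G)), 0.5)
    expect_lt(mean(diag(G)), 2)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    # invariance to site and individual order (up to relabeling)
    perm_s <- sample(ncol(d)); perm_i <- sample(nrow(d))
    G2 <- suppressMessages(grm(marker_matrix(d[perm_i, perm_s]),
      stabilize_epsilon = 0))
    ids <- rownames(G)
    expect_equal(unclass(G2)[ids, ids], unclass(G)[ids, ids],
      tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("the Kronecker SCA kernel has the right structure and spectrum", {
  I2 <- identity_kernel(c("f1", "f2")); I3 <- identity_kernel(c("m1", "m2", "m3"))
  K <- sca_kernel(I2, I3)
  expect_equal(unclass(K), diag(6), ignore_attr = TRUE)
  expect_identical(rownames(K)[1:3], c("f1/m1", "f1/m2", "f1/m3"))
  GF <- relationship_matrix(matrix(c(1, .5, .5, 1), 2,
    dimnames = list(c("f1", "f2"), c("f1", "f2"))))
  K2 <- sca_kernel(GF, I3)
  expect_equal(K2["f1/m1", "f2/m1"], 0.5)
  GM <- relationship_matrix(matrix(c(1.2, .3, .3, .8), 2,
    dimnames = list(c("m1", "m2"), c("m1", "m2"))))
  K3 <- sca_kernel(GF, GM)
  ev <- sort(eigen(K3, only.values = TRUE)$values)
  ev_expect <- sort(as.vector(outer(
    eigen(GF, only.values = TRUE)$values,
    eigen(GM, only.values = TRUE)$values
  )))
  expect_equal(ev, ev_expect, tolerance = 1e-10)
  expect_gte(min(ev), 0)
  # pair-restricted version equals the matching Kronecker submatrix
  pairs <- data.frame(female = c("f1", "f2"), male = c("m2", "m1"))
  Kp <- sca_kernel_pairs(GF, GM, pairs)
  expect_equal(unclass(Kp),
    unclass(K3)[c("f1/m2", "f2/m1"), c("f1/m2", "f2/m1")],
    tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dosage TSV round-trips and VCF parsing collapses multiallelics", {
  g <- tiny_study()$female_genotypes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- read_dosage_tsv(path)
  expect_equal(g2$dosages, g$dosages)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\t.\tG\tC,T\t.\t.\t.\tGT\t0/0\t0/2\t0/0\t1/1"
  ), vcf)
  mm <- read_vcf_dosages(vcf)
  expect_equal(dim(mm$dosages), c(4L, 2L))
  expect_equal(unname(mm$dosages[, 1]), c(0, 1, 2, NA))
  # site 2 allele counts: G x5, T(index 2) x1, C(index 1) x2; the two most
  # frequent are G and C, the 0/2 call carries the dropped allele T and is
  # set missing, and the dosage counts the rarer retained allele C
  expect_equal(unname(mm$dosages[, 2]), c(0, NA, 0, 2))
})
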