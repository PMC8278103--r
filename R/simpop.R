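#' Crossing-design parameters for the simulator
#'
#' The default emulates the study design the package targets: six female
#' testers crossed to a subset of the male panel to give 938 training
#' hybrids, with the number of females per male following the observed
#' histogram (85 males crossed to 1 female, 108 to 2, 124 to 3, 60 to 4,
#' and 5 to 5 — 382 males in total), no male crossed to every female, and
#' every pair of used females sharing at least one male.
#'
#' @param n_females_used,n_males_used number of parents entering crosses.
#' @param n_training_hybrids number of tested (phenotyped) hybrids.
#' @param female_count_dist optional named integer vector: names are
#'   females-per-male counts, values are how many males get that count.
#'   Must sum to `n_males_used` with total crosses `n_training_hybrids`.
#'   `NULL` allocates counts randomly between 1 and
#'   `n_females_used - 1`.
#' @return A `crossing_config` list.
#' @export
crossing_config <- function(n_females_used = 6, n_males_used = 382,
                            n_training_hybrids = 938,
                            female_count_dist = c(
                              "1" = 85, "2" = 108, "3" = 124, "4" = 60, "5" = 5
                            )) {
  stopifnot(
    n_females_used >= 1, n_males_used >= 1,
    n_training_hybrids >= n_males_used,
    n_training_hybrids <= n_females_used * n_males_used
  )
  if (!is.null(female_count_dist)) {
    stopifnot(
      sum(female_count_dist) == n_males_used,
      sum(as.integer(names(female_count_dist)) * female_count_dist) ==
        n_training_hybrids,
      all(as.integer(names(female_count_dist)) <= n_females_used)
    )
  }
  structure(list(
    n_females_used = n_females_used, n_males_used = n_males_used,
    n_training_hybrids = n_training_hybrids,
    female_count_dist = female_count_dist
  ), class = "crossing_config")
}

#' Per-trait simulation settings
#'
#' @param mean trait grand mean (trait units).
#' @param sigma2 named variances: `F`, `M`, `FM` (genetic), `E`, `FE`,
#'   `ME`, `B` (design), `e` (plot error); all in squared trait units.
#' @param mph_shift hybrid mean shift as a proportion of the trait mean;
#'   hybrids receive `mph_shift * mean` on top of their genetic value, so
#'   simulated mid-parent heterosis is tunable.
#' @param single_env observe the trait in environment 1 only.
#' @return A `trait_sim` list.
#' @export
trait_sim <- function(mean, sigma2, mph_shift = 0, single_env = FALSE) {
  needed <- c("F", "M", "FM", "E", "FE", "ME", "B", "e")
  stopifnot(all(needed %in% names(sigma2)), all(sigma2 >= 0), sigma2[["e"]] > 0)
  structure(list(
    mean = mean, sigma2 = sigma2[needed], mph_shift = mph_shift,
    single_env = single_env
  ), class = "trait_sim")
}

#' Default trait settings for the simulator
#'
#' Six yield-related traits (plant height, tiller number, panicle length,
#' proportion of spikelets filled, yield per plant, potential yield per
#' plant) with means on their field scales and variance ratios chosen so
#' entry-mean heritabilities land in the 0.3-0.9 band typical of hybrid
#' rice trials; spikelet filling and potential yield are observed in one
#' environment only.  The hybrid mean shifts give mid-parent heterosis
#' levels from slightly negative (height) to about a third of the mean
#' (yield).
#'
#' @return Named list of [trait_sim()] settings.
#' @export
default_traits <- function() {
  list(
    height = trait_sim(85, c(
      F = 40, M = 30, FM = 10, E = 60, FE = 5, ME = 5, B = 4, e = 30
    ), mph_shift = -0.02),
    tillers = trait_sim(14, c(
      F = 2, M = 1.5, FM = 0.5, E = 6, FE = 1, ME = 1, B = 0.5, e = 10
    ), mph_shift = 0.29),
    panicle_length = trait_sim(226, c(
      F = 150, M = 100, FM = 50, E = 80, FE = 20, ME = 20, B = 10, e = 250
    ), mph_shift = 0.02),
    spikelets_filled = trait_sim(0.757, c(
      F = 0.006, M = 0.005, FM = 0.002, E = 0, FE = 0, ME = 0,
      B = 0.001, e = 0.010
    ), mph_shift = -0.03, single_env = TRUE),
    yield = trait_sim(36, c(
      F = 30, M = 25, FM = 15, E = 150, FE = 15, ME = 15, B = 5, e = 250
    ), mph_shift = 0.32),
    potential_yield = trait_sim(54, c(
      F = 25, M = 20, FM = 15, E = 0, FE = 0, ME = 0, B = 5, e = 260
    ), mph_shift = 0.33, single_env = TRUE)
  )
}

#' Simulation configuration for a two-pool hybrid breeding study
#'
#' Defaults emulate the population the package models: 13 female testers
#' (12 CMS whose seed-bearing phenotypes come from maintainer lines, 1
#' TGMS phenotyped directly) forming one tight cluster, and 564 BC1F5
#' backcross introgression male lines in 11 donor-parent families sharing
#' a recurrent parent (expected 75% recurrent genome, residual
#' heterozygosity 1/32 per segregating site), phenotyped in an unbalanced
#' RCBD over 2 environments x 2 blocks with occasional missing plots.
#' Sites are exchangeable draws (no genetic map): genome-wide relationship
#' estimates, the only marker summaries the analysis uses, do not depend
#' on linkage, and 2,000 sites already estimate them stably.
#'
#' @param n_females,n_cms,n_males,n_donor_families population sizes.
#' @param n_sites number of biallelic marker sites.
#' @param recurrent_genome_fraction expected fraction of each male genome
#'   from the recurrent parent.
#' @param residual_het heterozygosity probability at donor-origin sites
#'   where donor and recurrent alleles differ (BC1F5: `1/2^5`).
#' @param female_pool_divergence per-site probability that the female-pool
#'   founder haplotype differs from the recurrent parent; together with
#'   the male mosaic structure this sets the female-male SDAF level
#'   (default 0.15 puts it in the 0.20-0.28 window typical of elite
#'   two-pool rice germplasm).
#' @param female_divergence per-site mutation probability separating each
#'   female from the female-pool founder haplotype.
#' @param crossing a [crossing_config()].
#' @param traits named list of [trait_sim()] settings.
#' @param n_environments,n_blocks_per_env trial dimensions.
#' @param missing_rep_rate probability a plot record is missing.
#' @param n_checks number of inbred commercial checks.
#' @param seed integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_females = 13, n_cms = 12, n_males = 564,
                       n_donor_families = 11, n_sites = 2000,
                       recurrent_genome_fraction = 0.75,
                       residual_het = 1 / 32,
                       female_pool_divergence = 0.15,
                       female_divergence = 0.05,
                       crossing = crossing_config(),
                       traits = default_traits(),
                       n_environments = 2, n_blocks_per_env = 2,
                       missing_rep_rate = 0.05, n_checks = 6, seed = 1) {
  stopifnot(
    n_females >= 1, n_cms <= n_females, n_males >= 1,
    n_donor_families >= 1, n_sites >= 1,
    recurrent_genome_fraction >= 0, recurrent_genome_fraction <= 1,
    residual_het >= 0, residual_het <= 1,
    n_environments >= 1, n_blocks_per_env >= 1,
    missing_rep_rate >= 0, missing_rep_rate < 1
  )
  cr <- crossing
  stopifnot(
    cr$n_females_used <= n_females, cr$n_males_used <= n_males,
    cr$n_training_hybrids <= cr$n_females_used * cr$n_males_used
  )
  structure(list(
    n_females = n_females, n_cms = n_cms, n_males = n_males,
    n_donor_families = n_donor_families, n_sites = n_sites,
    recurrent_genome_fraction = recurrent_genome_fraction,
    residual_het = residual_het,
    female_pool_divergence = female_pool_divergence,
    female_divergence = female_divergence,
    crossing = cr, traits = traits, n_environments = n_environments,
    n_blocks_per_env = n_blocks_per_env,
    missing_rep_rate = missing_rep_rate, n_checks = n_checks,
    seed = as.integer(seed)
  ), class = "sim_config")
}

female_ids <- function(config) sprintf("F%02d", seq_len(config$n_females))
male_ids <- function(config) sprintf("M%03d", seq_len(config$n_males))

#' Simulate female and male parental genotypes
#'
#' Males are per-site i.i.d. mosaics of a recurrent-parent haplotype and
#' one of the donor-family haplotypes (donor probability
#' `1 - recurrent_genome_fraction`), nearly fully homozygous with residual
#' heterozygosity `residual_het` at donor-origin sites where the donor and
#' recurrent alleles differ.  Females are homozygous perturbations of a
#' separate founder haplotype, so they form a distinct cluster.  Both
#' panels share the same site list.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `females` and `males` ([marker_matrix()] objects);
#'   the male matrix carries `family` (donor family per male) and
#'   `recurrent_fraction` (true origin fraction per male) attributes.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_donor_families > config$n_males)
    stop("more donor families than males: cannot assign families")
  set.seed(config$seed)
  ns <- config$n_sites
  site_id <- sprintf("S%05d", seq_len(ns))
  sites <- data.frame(
    site_id = site_id,
    chrom = as.character(rep_len(1:12, ns)),
    pos = seq_len(ns) * 1000L, ref = "A", alt = "B",
    stringsAsFactors = FALSE
  )
  recurrent <- stats::rbinom(ns, 1, 0.5)
  donors <- matrix(
    stats::rbinom(config$n_donor_families * ns, 1, 0.5),
    nrow = config$n_donor_families
  )
  fam <- sort(rep_len(seq_len(config$n_donor_families), config$n_males))
  p_donor <- 1 - config$recurrent_genome_fraction
  md <- matrix(0, config$n_males, ns,
    dimnames = list(male_ids(config), site_id))
  origin_frac <- numeric(config$n_males)
  for (i in seq_len(config$n_males)) {
    donor <- donors[fam[i], ]
    origin <- stats::rbinom(ns, 1, p_donor)
    allele <- ifelse(origin == 1, donor, recurrent)
    dos <- 2 * allele
    het <- origin == 1 & donor != recurrent &
      stats::runif(ns) < config$residual_het
    dos[het] <- 1
    md[i, ] <- dos
    origin_frac[i] <- 1 - mean(origin)
  }
  flip_f <- stats::runif(ns) < config$female_pool_divergence
  founder_f <- ifelse(flip_f, 1 - recurrent, recurrent)
  fd <- matrix(0, config$n_females, ns,
    dimnames = list(female_ids(config), site_id))
  # females descend along a random genealogy: each line branches off a
  # previously generated one, giving the nested (differential)
  # relatedness of a real tester panel rather than a star phylogeny
  haps <- vector("list", config$n_females)
  for (i in seq_len(config$n_females)) {
    base_hap <- if (i == 1) founder_f else
      haps[[sample.int(i - 1, 1)]]
    mut <- stats::runif(ns) < config$female_divergence
    haps[[i]] <- ifelse(mut, 1 - base_hap, base_hap)
    fd[i, ] <- 2 * haps[[i]]
  }
  females <- marker_matrix(fd, sites)
  males <- marker_matrix(md, sites)
  attr(males, "family") <- stats::setNames(fam, rownames(md))
  attr(males, "recurrent_fraction") <- stats::setNames(origin_frac, rownames(md))
  list(females = females, males = males)
}

#' Simulate an unbalanced incomplete crossing design
#'
#' Flags `n_training_hybrids` of the full female-by-male grid as tested,
#' allocating females-per-male counts from `female_count_dist` (or
#' randomly between 1 and `n_females_used - 1`), never crossing a male to
#' every used female (when more than one female is used), and repairing
#' the assignment until every pair of used females shares at least one
#' male.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param females,males character vectors of parent ids (the full panels).
#' @return A `crossing_design` data frame with columns `female`, `male`,
#'   `hybrid`, `tested`, and attributes `females_used`, `males_used`.
#' @export
simulate_crossing_design <- function(config, females, males) {
  stopifnot(inherits(config, "sim_config"))
  cr <- config$crossing
  if (cr$n_females_used > length(females) || cr$n_males_used > length(males))
    stop("crossing config exceeds panel sizes")
  set.seed(config$seed + 1L)
  fu <- sort(sample(females, cr$n_females_used))
  mu <- sort(sample(males, cr$n_males_used))
  nf <- cr$n_females_used
  cap <- if (nf > 1) nf - 1 else 1
  if (cr$n_training_hybrids > cr$n_males_used * cap)
    stop("infeasible design: too many training hybrids for the no-complete-crossing constraint")
  counts <- if (!is.null(cr$female_count_dist)) {
    cnt <- rep(as.integer(names(cr$female_count_dist)), cr$female_count_dist)
    sample(cnt)
  } else {
    cnt <- rep(1L, cr$n_males_used)
    extra <- cr$n_training_hybrids - cr$n_males_used
    while (extra > 0) {
      open <- which(cnt < cap)
      take <- sample(open, min(extra, length(open)))
      cnt[take] <- cnt[take] + 1L
      extra <- extra - length(take)
    }
    cnt
  }
  if (any(counts >= nf) && nf > 1)
    stop("female count distribution violates the no-complete-crossing constraint")
  assign_females <- function() {
    lapply(counts, function(k) sample(fu, k))
  }
  ok_overlap <- function(sets) {
    if (nf < 2) return(TRUE)
    prs <- utils::combn(fu, 2)
    for (j in seq_len(ncol(prs))) {
      covered <- any(vapply(
        sets, function(s) all(prs[, j] %in% s), logical(1)
      ))
      if (!covered) return(FALSE)
    }
    TRUE
  }
  sets <- assign_females()
  for (try in 1:100) {
    # every used female must appear
    missing_f <- setdiff(fu, unique(unlist(sets)))
    for (f in missing_f) {
      i <- sample(seq_along(sets), 1)
      sets[[i]][1] <- f
      sets[[i]] <- unique(sets[[i]])
    }
    if (nf >= 2) {
      prs <- utils::combn(fu, 2)
      fixed_all <- TRUE
      for (j in seq_len(ncol(prs))) {
        covered <- any(vapply(
          sets, function(s) all(prs[, j] %in% s), logical(1)
        ))
        if (!covered) {
          cand <- which(counts >= 2)
          if (!length(cand)) stop("infeasible overlap constraint")
          i <- sample(cand, 1)
          keep <- setdiff(sets[[i]], prs[, j])
          sets[[i]] <- c(prs[, j], utils::head(keep, counts[i] - 2))
          fixed_all <- FALSE
        }
      }
      if (fixed_all && !length(missing_f)) break
    } else break
  }
  if (!ok_overlap(sets)) stop("infeasible overlap constraint")
  tested <- data.frame(
    female = unlist(sets),
    male = rep(mu, vapply(sets, length, 0L)),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(
    male = males, female = females,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("female", "male")]
  grid$hybrid <- paste(grid$female, grid$male, sep = "/")
  grid$tested <- grid$hybrid %in% paste(tested$female, tested$male, sep = "/")
  stopifnot(sum(grid$tested) == cr$n_training_hybrids)
  structure(grid,
    class = c("crossing_design", "data.frame"),
    females_used = fu, males_used = mu
  )
}

#' Simulate plot-level phenotypes from the GCA + SCA model
#'
#' Draws female and male GCA effects with covariances
#' `sigma2_F * G_F` and `sigma2_M * G_M` (marker-driven, so genomically
#' related parents have correlated effects), SCA with the Kronecker
#' covariance `sigma2_FM * (G_F x G_M)`, and independent environment,
#' block-in-environment, female-by-environment, male-by-environment, and
#' plot-error effects.  Kernels are rescaled ([scale_kernel()]) so each
#' configured variance is the expected realized variance of its effects
#' across levels; the rescaled kernels are returned for use in downstream
#' fits on the simulated data.  Tested hybrids get one plot per block per
#' environment with `missing_rep_rate` dropout; single-environment traits
#' are recorded in environment 1 only.  Inbred phenotypes (used male
#' parents, maintainer lines standing in for the CMS females, the TGMS
#' female itself, and the commercial checks) are also emitted, with
#' hybrids receiving the trait's configured mean shift so mid-parent
#' heterosis is tunable.  The true inbred genetic value of a parent is
#' twice its GCA (the GCA being the effect transmitted to progeny); check
#' values are independent draws on the total-GCA scale.
#'
#' @param config a [sim_config()].
#' @param females,males parental [marker_matrix()] panels.
#' @param design a `crossing_design` from [simulate_crossing_design()].
#' @return A `sim_study` list: `config`, `female_genotypes`,
#'   `male_genotypes`, `design`, `phenotypes` (plot table), `true_values`
#'   (per trait: `female_gca`, `male_gca`, `sca`, `hybrid_value`,
#'   `inbred_value`, `mph_shift`), `kernels` (`G_F`, `G_M` scaled),
#'   `maintainer_map`, `checks`, `cms`.
#' @export
simulate_phenotypes <- function(config, females, males, design) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "crossing_design"))
  fid <- rownames(females$dosages); mid <- rownames(males$dosages)
  bad <- setdiff(c(design$female, design$male), c(fid, mid))
  if (length(bad))
    stop("design references unknown parent id(s): ",
      paste(utils::head(bad, 5), collapse = ", "))
  set.seed(config$seed + 2L)
  G_F <- scale_kernel(grm(females, kind = "G_F"))
  G_M <- scale_kernel(grm(males, kind = "G_M"))
  Lf <- chol_with_jitter(G_F)$chol          # upper: t(Lf) %*% Lf = G_F
  Lm <- t(chol_with_jitter(G_M)$chol)       # lower
  nf <- length(fid); nm <- length(mid)
  n_env <- config$n_environments; n_blk <- config$n_blocks_per_env
  cms <- stats::setNames(
    seq_len(config$n_females) <= config$n_cms, fid
  )
  maintainer_map <- stats::setNames(
    ifelse(cms, paste0("B_", fid), fid), fid
  )
  checks <- sprintf("CHK%d", seq_len(config$n_checks))
  tested <- design[design$tested, , drop = FALSE]
  inbred_males <- sort(unique(tested$male))
  inbred_geno <- c(unname(maintainer_map), checks)
  inbred_parent_of <- c(stats::setNames(fid, unname(maintainer_map)))

  env_lv <- sprintf("E%d", seq_len(n_env))
  blk_lv <- sprintf("B%d", seq_len(n_blk))
  plot_geno <- c(tested$hybrid, inbred_males, inbred_geno)
  plot_type <- c(
    rep("hybrid", nrow(tested)),
    rep("inbred", length(inbred_males) + length(inbred_geno))
  )
  plot_f <- c(tested$female, rep(NA, length(inbred_males) + length(inbred_geno)))
  plot_m <- c(tested$male, rep(NA, length(inbred_males) + length(inbred_geno)))
  base <- expand.grid(
    i = seq_along(plot_geno), env = env_lv, block = blk_lv,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  keep <- stats::runif(nrow(base)) >= config$missing_rep_rate
  base <- base[keep, , drop = FALSE]
  phen <- data.frame(
    genotype = plot_geno[base$i], female = plot_f[base$i],
    male = plot_m[base$i], type = plot_type[base$i],
    env = base$env, block = base$block, rep = 1L,
    stringsAsFactors = FALSE
  )
  # conditional (exact-variance) sampling: the MVN draw sets the direction,
  # then the vector is rescaled so its realized sample variance equals the
  # configured component exactly.  With few levels (6 females) the
  # chi-square magnitude noise of an unconditional draw would otherwise
  # dominate any parameter-recovery comparison.
  exact_var <- function(x, s2) {
    if (s2 == 0) return(x * 0)
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v <= 0) return(x)
    x * sqrt(s2 / v)
  }
  true_values <- list()
  for (tn in names(config$traits)) {
    tc <- config$traits[[tn]]
    s <- tc$sigma2
    Fe <- exact_var(as.numeric(t(Lf) %*% stats::rnorm(nf)), s[["F"]])
    Me <- exact_var(as.numeric(Lm %*% stats::rnorm(nm)), s[["M"]])
    names(Fe) <- fid; names(Me) <- mid
    Smat <- exact_var(
      Lm %*% matrix(stats::rnorm(nm * nf), nm, nf) %*% Lf, s[["FM"]]
    )
    dimnames(Smat) <- list(mid, fid)
    # environment and block effects are centered across their realized
    # levels (and environments variance-standardized): the trait mean is
    # then the realized trial mean, which is the scale heterosis
    # percentages refer to
    Eef <- stats::rnorm(n_env, 0, sqrt(s[["E"]]))
    Eef <- if (n_env > 1) exact_var(Eef - mean(Eef), s[["E"]]) else Eef * 0
    names(Eef) <- env_lv
    Bef <- matrix(stats::rnorm(n_env * n_blk, 0, sqrt(s[["B"]])),
      n_env, n_blk, dimnames = list(env_lv, blk_lv))
    if (n_blk > 1) Bef <- Bef - rowMeans(Bef)
    FEef <- matrix(stats::rnorm(nf * n_env, 0, sqrt(s[["FE"]])),
      nf, n_env, dimnames = list(fid, env_lv))
    MEef <- matrix(stats::rnorm(nm * n_env, 0, sqrt(s[["ME"]])),
      nm, n_env, dimnames = list(mid, env_lv))
    shift <- tc$mph_shift * tc$mean
    sca_all <- stats::setNames(
      Smat[cbind(design$male, design$female)], design$hybrid
    )
    hybrid_value <- stats::setNames(
      Fe[design$female] + Me[design$male] + sca_all, design$hybrid
    )
    inbred_value <- c(
      stats::setNames(2 * Fe[fid], unname(maintainer_map)),
      stats::setNames(2 * Me, mid),
      stats::setNames(
        stats::rnorm(length(checks), 0, sqrt(s[["F"]] + s[["M"]])), checks
      )
    )
    g <- ifelse(phen$type == "hybrid",
      hybrid_value[phen$genotype] + shift,
      inbred_value[phen$genotype]
    )
    val <- tc$mean + g + Eef[phen$env] +
      Bef[cbind(phen$env, phen$block)] +
      ifelse(is.na(phen$female), 0, FEef[cbind(phen$female, phen$env)]) +
      ifelse(is.na(phen$male), 0, MEef[cbind(phen$male, phen$env)]) +
      stats::rnorm(nrow(phen), 0, sqrt(s[["e"]]))
    if (tc$single_env) val[phen$env != env_lv[1]] <- NA
    phen[[tn]] <- as.numeric(val)
    true_values[[tn]] <- list(
      female_gca = Fe, male_gca = Me, sca = sca_all,
      hybrid_value = hybrid_value, inbred_value = inbred_value,
      mph_shift = shift
    )
  }
  structure(list(
    config = config, female_genotypes = females, male_genotypes = males,
    design = design, phenotypes = phen, true_values = true_values,
    kernels = list(G_F = G_F, G_M = G_M),
    maintainer_map = maintainer_map, inbred_parent_of = inbred_parent_of,
    checks = checks, cms = cms
  ), class = "sim_study")
}

#' Simulate a complete study (parents, design, phenotypes)
#'
#' @param config a [sim_config()].
#' @return A `sim_study`; see [simulate_phenotypes()].
#' @export
simulate_study <- function(config = sim_config()) {
  par <- simulate_parents(config)
  design <- simulate_crossing_design(
    config, rownames(par$females$dosages), rownames(par$males$dosages)
  )
  simulate_phenotypes(config, par$females, par$males, design)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d females x %d males, %d tested hybrids, %d plots, %d trait(s)\n",
    nrow(x$female_genotypes$dosages), nrow(x$male_genotypes$dosages),
    sum(x$design$tested), nrow(x$phenotypes), length(x$true_values)
  ))
  invisible(x)
}

#' Hybrid genomic kernel for a simulated (or real) study
#'
#' Infers expected F1 genotypes for the given hybrids from the parental
#' panels and returns their VanRaden relationship matrix, rescaled with
#' [scale_kernel()] for consistency with the study's parental kernels.
#'
#' @param study a `sim_study` (or any list with `female_genotypes`,
#'   `male_genotypes`, `design`).
#' @param hybrids hybrid ids; default all tested hybrids.
#' @return A `relationship_matrix` of kind `"G_H_scaled"`.
#' @export
hybrid_kernel <- function(study, hybrids = NULL) {
  design <- study$design
  if (is.null(hybrids)) hybrids <- design$hybrid[design$tested]
  rows <- design[match(hybrids, design$hybrid), ]
  if (anyNA(rows$female)) stop("unknown hybrid id(s)")
  hg <- infer_hybrid_genotypes(
    study$female_genotypes, study$male_genotypes,
    rows[c("female", "male")]
  )
  scale_kernel(grm(hg, kind = "G_H"))
}
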