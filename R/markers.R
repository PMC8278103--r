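#' Marker dosage matrix
#'
#' Container for a panel of individuals genotyped at biallelic SNPs, coded as
#' counts of the alternate allele (0, 1, 2, or `NA` for missing).  Expected F1
#' dosages produced by [infer_hybrid_genotypes()] may be fractional.
#'
#' @param dosages numeric matrix, individuals in rows, sites in columns.
#'   Row names are individual ids and column names site ids; both required
#'   and unique.
#' @param sites optional data frame of site metadata with columns `site_id`,
#'   `chrom`, `pos`, `ref`, `alt`.  Defaults to a skeleton built from the
#'   column names of `dosages`.
#' @return An object of class `marker_matrix`: a list with elements
#'   `dosages` and `sites`.
#' @export
marker_matrix <- function(dosages, sites = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) && is.null(rownames(dosages)))
    stop("dosage matrix must have individual (row) names")
  if (ncol(dosages) && is.null(colnames(dosages)))
    stop("dosage matrix must have site (column) names")
  if (ncol(dosages) == 0 && is.null(colnames(dosages)))
    colnames(dosages) <- character(0)
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate individual ids")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate site ids")
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2]")
  }
  if (is.null(sites)) {
    nsite <- ncol(dosages)
    sites <- data.frame(
      site_id = colnames(dosages), chrom = rep(NA_character_, nsite),
      pos = rep(NA_integer_, nsite), ref = rep("A", nsite),
      alt = rep("B", nsite), stringsAsFactors = FALSE
    )
  }
  stopifnot(identical(sites$site_id, colnames(dosages)))
  structure(list(dosages = dosages, sites = sites), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf(
    "<marker_matrix> %d individuals x %d sites (%.1f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

#' Site filter specification
#'
#' Thresholds for marker site quality control, mirroring TASSEL-style site
#' filters: a cap on the fraction of heterozygous calls, a minimum number of
#' non-missing calls (site count), and a minimum minor allele count.
#' Multiallelic variants are reduced to their two most frequent alleles at
#' parse time (see [read_vcf_dosages()]), so dosage matrices entering
#' [filter_sites()] are already biallelic.
#'
#' @param max_het_fraction maximum fraction of non-missing calls that may be
#'   heterozygous (default 0.5).
#' @param min_site_count minimum number of individuals with a non-missing
#'   call.
#' @param min_minor_allele_count minimum count of the rarer allele.
#' @return A `site_filter_spec` list.
#' @export
site_filter_spec <- function(max_het_fraction = 0.5, min_site_count = 1,
                             min_minor_allele_count = 0) {
  stopifnot(
    max_het_fraction >= 0, min_site_count >= 0,
    min_minor_allele_count >= 0
  )
  structure(
    list(
      max_het_fraction = max_het_fraction,
      min_site_count = min_site_count,
      min_minor_allele_count = min_minor_allele_count
    ),
    class = "site_filter_spec"
  )
}

#' Filter marker sites on quality thresholds
#'
#' Retains sites with at least `min_site_count` non-missing calls, a minor
#' allele count of at least `min_minor_allele_count`, and a heterozygote
#' fraction (among non-missing calls) of at most `max_het_fraction`.  The
#' operation is idempotent.  Per-rule drop counts are attached as the
#' `"filter_report"` attribute; a site failing several rules is counted once
#' per rule it fails.
#'
#' @param geno a [marker_matrix()].
#' @param spec a [site_filter_spec()].
#' @return Filtered `marker_matrix`.
#' @export
filter_sites <- function(geno, spec = site_filter_spec()) {
  stopifnot(inherits(geno, "marker_matrix"), inherits(spec, "site_filter_spec"))
  d <- geno$dosages
  if (ncol(d) == 0 || nrow(d) == 0) stop("empty marker matrix")
  n_obs <- colSums(!is.na(d))
  alt_count <- colSums(d, na.rm = TRUE)
  minor_count <- pmin(alt_count, 2 * n_obs - alt_count)
  het_frac <- ifelse(n_obs > 0, colSums(d == 1, na.rm = TRUE) / n_obs, 1)
  pass_count <- n_obs >= spec$min_site_count
  pass_mac <- minor_count >= spec$min_minor_allele_count
  pass_het <- het_frac <= spec$max_het_fraction
  keep <- pass_count & pass_mac & pass_het
  out <- marker_matrix(
    d[, keep, drop = FALSE],
    geno$sites[keep, , drop = FALSE]
  )
  attr(out, "filter_report") <- data.frame(
    rule = c("min_site_count", "min_minor_allele_count", "max_het_fraction"),
    dropped = c(sum(!pass_count), sum(!pass_mac), sum(!pass_het)),
    retained = sum(keep)
  )
  out
}

#' Naive per-site imputation of missing dosages
#'
#' Replaces missing dosages site by site with either the rounded mean
#' (`mode = "mean"`, ties at .5 round to the even dosage, i.e. `round()`)
#' or the most frequent (`mode = "major"`, ties broken toward the lower
#' dosage) observed dosage.  A population-level haplotype imputer is a
#' deliberate non-goal; downstream relationship matrices are insensitive to
#' the difference on the panels this package targets.
#'
#' @param geno a [marker_matrix()]; every site needs at least one
#'   non-missing call (filter first).
#' @param mode `"mean"` or `"major"`.
#' @return A `marker_matrix` with no missing values.
#' @export
impute_naive <- function(geno, mode = c("mean", "major")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "marker_matrix"))
  d <- geno$dosages
  miss_sites <- which(colSums(!is.na(d)) == 0)
  if (length(miss_sites))
    stop(
      "fully missing site(s): ",
      paste(colnames(d)[utils::head(miss_sites, 5)], collapse = ", ")
    )
  na_cols <- which(colSums(is.na(d)) > 0)
  for (j in na_cols) {
    obs <- d[!is.na(d[, j]), j]
    fill <- if (mode == "mean") {
      round(mean(obs))
    } else {
      tab <- table(obs)
      # which.max on a table keeps the first maximum; names sort ascending
      as.numeric(names(tab)[which.max(tab)])
    }
    d[is.na(d[, j]), j] <- fill
  }
  marker_matrix(d, geno$sites)
}

#' Expected F1 hybrid genotypes from parental dosages
#'
#' For each requested cross the hybrid dosage at a site is the expectation
#' over parental gametes, `(female + male) / 2`; fractional dosages are kept
#' because the result feeds covariance estimation, not genotype calling.
#' Parent panels are intersected on site id and the ref/alt alleles must
#' agree at every shared site.
#'
#' @param females,males imputed [marker_matrix()] objects.
#' @param pairs data frame (or 2-column matrix) of female and male ids.
#' @param sep separator used to build hybrid ids as `"female/male"`.
#' @return A `marker_matrix` of hybrids on the shared site panel.
#' @export
infer_hybrid_genotypes <- function(females, males, pairs, sep = "/") {
  stopifnot(inherits(females, "marker_matrix"), inherits(males, "marker_matrix"))
  pairs <- as.data.frame(pairs)
  fid <- as.character(pairs[[1]]); mid <- as.character(pairs[[2]])
  if (anyNA(females$dosages) || anyNA(males$dosages))
    stop("parent panels must be imputed before hybrid inference")
  shared <- intersect(females$sites$site_id, males$sites$site_id)
  if (!length(shared)) stop("no shared sites between parent panels")
  fs <- females$sites[match(shared, females$sites$site_id), ]
  ms <- males$sites[match(shared, males$sites$site_id), ]
  bad <- which(fs$ref != ms$ref | fs$alt != ms$alt)
  if (length(bad))
    stop(
      "ref/alt allele mismatch at shared site(s): ",
      paste(shared[utils::head(bad, 5)], collapse = ", ")
    )
  miss_f <- setdiff(fid, rownames(females$dosages))
  miss_m <- setdiff(mid, rownames(males$dosages))
  if (length(miss_f) || length(miss_m))
    stop(
      "unknown parent id(s): ",
      paste(utils::head(c(miss_f, miss_m), 5), collapse = ", ")
    )
  fd <- females$dosages[fid, shared, drop = FALSE]
  md <- males$dosages[mid, shared, drop = FALSE]
  h <- (fd + md) / 2
  rownames(h) <- paste(fid, mid, sep = sep)
  if (anyDuplicated(rownames(h))) stop("duplicate crosses in `pairs`")
  marker_matrix(h, fs)
}

#' Allele frequencies from dosages
#'
#' Per-individual frequency of the counted (alternate) allele is dosage / 2;
#' the panel frequency is its mean over individuals.
#'
#' @param geno an imputed [marker_matrix()].
#' @return List with `per_individual` (matrix, individuals x sites) and
#'   `panel` (named numeric vector over sites).
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "marker_matrix"))
  if (anyNA(geno$dosages)) stop("missing dosages: impute before computing frequencies")
  per_ind <- geno$dosages / 2
  list(per_individual = per_ind, panel = colMeans(per_ind))
}

#' Squared difference in allele frequency (SDAF)
#'
#' Mean over sites of the squared difference between two parents' allele
#' frequencies, `mean((p_i - p_j)^2)`.  A genetic-distance measure in
#' [0, 1]; invariant to which allele is counted at a site because the
#' difference is squared, and symmetric in its arguments.
#'
#' @param p_i,p_j numeric frequency vectors of equal length (values in
#'   [0, 1]).
#' @return Scalar SDAF.
#' @export
sdaf <- function(p_i, p_j) {
  if (length(p_i) != length(p_j)) stop("frequency vectors differ in length")
  if (length(p_i) < 1) stop("empty frequency vectors")
  mean((p_i - p_j)^2)
}
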