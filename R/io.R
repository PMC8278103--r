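#' Read a dosage TSV into a marker matrix
#'
#' Expects a tab-separated file with individuals in rows and sites in
#' columns; the first column holds individual ids and the header row site
#' ids.  Missing dosages may be empty, `NA`, or `.`.
#'
#' @param path file path.
#' @return A [marker_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path,
    check.names = FALSE, na.strings = c("NA", "", "."),
    stringsAsFactors = FALSE
  )
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  marker_matrix(d)
}

#' Write a marker matrix as a dosage TSV
#'
#' @param geno a [marker_matrix()].
#' @param path output file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "marker_matrix"))
  tab <- data.frame(
    individual = rownames(geno$dosages), geno$dosages,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read biallelic SNP dosages from a VCF
#'
#' Parses the GT field of a VCF (via the vcfR package) into alternate-allele
#' dosages.  Multiallelic records are reduced to their two most frequent
#' alleles: calls carrying any other allele are set missing, and the two
#' retained alleles are recoded so the dosage counts the less frequent of
#' the two.  Requires the suggested package vcfR.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [marker_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages() requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  site_id <- ifelse(
    is.na(fix[, "ID"]) | fix[, "ID"] == ".",
    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]
  )
  n_site <- nrow(gt)
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = n_site,
    dimnames = list(colnames(gt), site_id))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt1 <- character(n_site)
  for (k in seq_len(n_site)) {
    calls <- gt[k, ]
    alleles <- strsplit(gsub("\\|", "/", calls), "/", fixed = FALSE)
    flat <- suppressWarnings(as.integer(unlist(alleles)))
    tab <- sort(table(flat[!is.na(flat)]), decreasing = TRUE)
    if (length(tab) == 0) next
    top2 <- as.integer(names(tab))[seq_len(min(2, length(tab)))]
    if (length(top2) == 1) top2 <- c(top2, setdiff(0:1, top2)[1])
    # count the rarer of the two retained alleles
    counted <- top2[2]
    dos <- vapply(alleles, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (length(a) != 2 || anyNA(a) || !all(a %in% top2)) return(NA_real_)
      sum(a == counted)
    }, numeric(1))
    d[, k] <- dos
    allele_seq <- function(i) {
      if (i == 0) ref[k] else strsplit(alt[k], ",")[[1]][i]
    }
    alt1[k] <- allele_seq(counted)
    ref[k] <- allele_seq(top2[1])
  }
  sites <- data.frame(
    site_id = site_id, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = ref, alt = alt1,
    stringsAsFactors = FALSE
  )
  marker_matrix(d, sites)
}

#' Write a relationship matrix as a labeled TSV
#'
#' @param G a [relationship_matrix()].
#' @param path output file path.
#' @export
write_kernel_tsv <- function(G, path) {
  tab <- data.frame(id = rownames(G), as.matrix(G),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
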