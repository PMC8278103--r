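#' Restrict an SCA kernel to a list of female/male pairs
#'
#' Entry for pairs (f, m) and (f', m') is `G_F[f, f'] * G_M[m, m']`, i.e.
#' the corresponding principal submatrix of the full Kronecker product,
#' computed without forming it.
#'
#' @param G_F,G_M parental kernels.
#' @param pairs data frame (or 2-column matrix) of female and male ids.
#' @param sep pair-label separator.
#' @return A `relationship_matrix` over the pairs.
#' @export
sca_kernel_pairs <- function(G_F, G_M, pairs, sep = "/") {
  pairs <- as.data.frame(pairs)
  fi <- match(as.character(pairs[[1]]), rownames(G_F))
  mi <- match(as.character(pairs[[2]]), rownames(G_M))
  if (anyNA(fi) || anyNA(mi)) stop("pair parent missing from kernel")
  K <- as.matrix(G_F)[fi, fi, drop = FALSE] * as.matrix(G_M)[mi, mi, drop = FALSE]
  ids <- paste(pairs[[1]], pairs[[2]], sep = sep)
  dimnames(K) <- list(ids, ids)
  relationship_matrix(K, kind = "G_FM")
}

catalog_stages <- c(
  "hybrid_value", "hybrid_value_genomic", "gca", "gca_sca",
  "gca_genomic", "gca_sca_genomic", "heterosis"
)

#' Build the standard hybrid-trial model for an analysis stage
#'
#' Returns the [mixed_model_spec()] used at each stage of the analysis:
#'
#' * `hybrid_value` / `hybrid_value_genomic`: hybrid genetic value model
#'   `y = mu + H + E + HE + B(E) + e`; the genomic variant puts the hybrid
#'   kernel `G_H` on `H`.
#' * `gca` / `gca_genomic`: combining-ability model
#'   `y = mu + F + M + E + B(E) + FE + ME + e`, with parental kernels
#'   `G_F`/`G_M` on the GCA terms in the genomic variant.
#' * `gca_sca` / `gca_sca_genomic`: adds the female-by-male SCA term `FM`,
#'   with the Kronecker kernel `G_FM` in the genomic variant.
#' * `heterosis`: genotype-value model over hybrids *and* inbreds,
#'   `y = mu + F(class) + G + E + GE + B(E) + e`, where `F(class)` is a
#'   fixed inbred-vs-hybrid indicator absorbing the heterotic mean shift.
#'
#' When the trait is observed in a single environment the environment term
#' and its interactions are dropped automatically.  Environments (2 levels)
#' are random by default, as in the source design; `env_fixed = TRUE` moves
#' the environment main effect to the fixed part (interactions stay
#' random).
#'
#' Non-heterosis stages are fit on hybrid plots only (`type == "hybrid"`).
#' Kernels are subset to observed levels unless `keep_all_levels = TRUE`
#' (needed when predicting untested parents or hybrids).
#'
#' @param trait response column name.
#' @param stage one of `r paste(catalog_stages, collapse = ", ")`.
#' @param data plot-level phenotype table with columns `genotype`,
#'   `female`, `male`, `type`, `env`, `block`, and the trait.
#' @param kernels named list with the elements the stage needs: `G_F`,
#'   `G_M`, `G_H`, and/or `G_FM` (the latter may be omitted if `G_F` and
#'   `G_M` are present; it is then built for the observed pairs).
#' @param env_fixed treat environment as fixed.
#' @param keep_all_levels keep every kernel level in the model even if
#'   unobserved.
#' @return A `mixed_model_spec` with `stage` and `genomic` fields set.
#' @export
model_catalog <- function(trait, stage, data, kernels = list(),
                          env_fixed = FALSE, keep_all_levels = FALSE) {
  stage <- match.arg(stage, catalog_stages)
  stopifnot(trait %in% names(data))
  genomic <- grepl("genomic", stage)
  if (stage != "heterosis") {
    data <- data[data$type == "hybrid", , drop = FALSE]
  }
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (!nrow(data)) stop("no observations of trait ", trait)
  multi_env <- length(unique(data$env)) > 1
  data$block_in_env <- paste(data$env, data$block, sep = ":")
  data$fm <- paste(data$female, data$male, sep = "/")
  data$HE <- paste(data$genotype, data$env, sep = ":")
  data$GE <- data$HE
  data$FE <- paste(data$female, data$env, sep = ":")
  data$ME <- paste(data$male, data$env, sep = ":")

  need <- function(nm) {
    if (is.null(kernels[[nm]])) stop("stage ", stage, " needs kernel ", nm)
    kernels[[nm]]
  }
  sub_kernel <- function(K, observed) {
    if (keep_all_levels) return(K)
    ids <- intersect(rownames(K), unique(observed))
    if (!length(ids)) stop("kernel shares no levels with the data")
    relationship_matrix(as.matrix(K)[ids, ids, drop = FALSE],
      kind = attr(K, "kind") %||% "G")
  }

  rt <- list()
  fixed <- ~1
  if (stage %in% c("hybrid_value", "hybrid_value_genomic")) {
    H_kernel <- if (genomic) sub_kernel(need("G_H"), data$genotype) else NULL
    rt <- c(rt, list(rand_term("H", "genotype", H_kernel)))
    if (multi_env && !env_fixed) rt <- c(rt, list(rand_term("E", "env")))
    if (multi_env && env_fixed) fixed <- ~env
    if (multi_env) rt <- c(rt, list(rand_term("HE", "HE")))
    rt <- c(rt, list(rand_term("B", "block_in_env")))
  } else if (stage %in% c("gca", "gca_genomic", "gca_sca", "gca_sca_genomic")) {
    F_kernel <- if (genomic) sub_kernel(need("G_F"), data$female) else NULL
    M_kernel <- if (genomic) sub_kernel(need("G_M"), data$male) else NULL
    rt <- c(rt, list(
      rand_term("F", "female", F_kernel),
      rand_term("M", "male", M_kernel)
    ))
    if (grepl("sca", stage)) {
      FM_kernel <- NULL
      if (genomic) {
        # the auto-built Kronecker kernel is variance-standardized
        # (scale_kernel) so sigma2_FM is reported on the same realized-
        # variance scale as the parental components; a user-supplied G_FM
        # is used as-is.  Predictions and the likelihood are invariant to
        # this scalar.
        FM_kernel <- if (!is.null(kernels$G_FM)) {
          sub_kernel(kernels$G_FM, data$fm)
        } else if (keep_all_levels) {
          scale_kernel(sca_kernel(need("G_F"), need("G_M")))
        } else {
          up <- unique(data[c("female", "male")])
          scale_kernel(sca_kernel_pairs(need("G_F"), need("G_M"), up))
        }
      }
      rt <- c(rt, list(rand_term("FM", "fm", FM_kernel)))
    }
    if (multi_env && !env_fixed) rt <- c(rt, list(rand_term("E", "env")))
    if (multi_env && env_fixed) fixed <- ~env
    rt <- c(rt, list(rand_term("B", "block_in_env")))
    if (multi_env) rt <- c(rt, list(
      rand_term("FE", "FE"), rand_term("ME", "ME")
    ))
  } else { # heterosis
    if (!any(data$type == "inbred"))
      stop("heterosis stage needs inbred records (indicator inestimable)")
    data$type <- factor(data$type, levels = c("inbred", "hybrid"))
    fixed <- ~type
    rt <- c(rt, list(rand_term("G", "genotype")))
    if (multi_env && !env_fixed) rt <- c(rt, list(rand_term("E", "env")))
    if (multi_env) rt <- c(rt, list(rand_term("GE", "GE")))
    rt <- c(rt, list(rand_term("B", "block_in_env")))
  }
  spec <- mixed_model_spec(trait, data, fixed = fixed, random = rt)
  spec$stage <- stage
  spec$genomic <- genomic
  spec$multi_env <- multi_env
  spec
}
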