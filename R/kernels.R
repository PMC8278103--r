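#' Genomic relationship matrix (VanRaden / Endelman-Jannink method)
#'
#' Centers dosages by twice the panel allele frequency and scales by the sum
#' of expected site variances: `G = W W' / (2 * sum(p * (1 - p)))` with
#' `W[i, k] = dosage[i, k] - 2 * p_k`.  Monomorphic sites contribute nothing
#' to either numerator or denominator.  If the smallest eigenvalue is below
#' zero (numerically), `stabilize_epsilon` is added to the diagonal and a
#' message logged, so the result is always positive semidefinite.
#'
#' @param geno an imputed [marker_matrix()] with at least two individuals
#'   and one polymorphic site.
#' @param stabilize_epsilon ridge added to the diagonal when needed
#'   (default 1e-6).
#' @param kind label stored on the result (e.g. `"G_F"`, `"G_M"`, `"G_H"`).
#' @return A symmetric matrix with individual ids as dimnames, class
#'   `relationship_matrix`, and attributes `kind` and `stabilized`.
#' @export
grm <- function(geno, stabilize_epsilon = 1e-6, kind = "G") {
  stopifnot(inherits(geno, "marker_matrix"))
  d <- geno$dosages
  if (anyNA(d)) stop("missing dosages: impute before computing the GRM")
  if (nrow(d) < 2) stop("need at least two individuals")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic: zero denominator")
  W <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  stabilized <- FALSE
  if (ev_min < 0) {
    G <- G + diag(stabilize_epsilon, nrow(G))
    stabilized <- TRUE
    message(sprintf(
      "grm: min eigenvalue %.3g < 0; added %.1e * I", ev_min, stabilize_epsilon
    ))
  }
  relationship_matrix(G, kind = kind, stabilized = stabilized)
}

#' Label a symmetric kernel as a relationship matrix
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param kind free-text label (`"G_F"`, `"G_M"`, `"G_H"`, `"G_FM"`,
#'   `"identity"`, ...).
#' @param stabilized whether a diagonal ridge was applied.
#' @return The matrix with class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, kind = "G", stabilized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("kernel needs dimnames (level ids)")
  if (max(abs(values - t(values))) > 1e-10) stop("kernel is not symmetric")
  structure(values,
    class = c("relationship_matrix", "matrix", "array"),
    kind = kind, stabilized = stabilized
  )
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf(
    "<relationship_matrix %s> %d x %d, mean diag %.3f\n",
    attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))
  ))
  invisible(x)
}

#' Kronecker-product SCA kernel
#'
#' Covariance kernel for female-by-male specific combining ability:
#' `G_FM = G_F %x% G_M`, with row/column labels the `"female/male"` pairs in
#' female-major order.  The Kronecker product of positive semidefinite
#' inputs is positive semidefinite (its eigenvalues are the pairwise
#' products of the input eigenvalues).
#'
#' @param G_F,G_M relationship matrices (or plain labeled symmetric
#'   matrices) for the female and male panels.
#' @param sep separator for pair labels (default `"/"`, matching
#'   [infer_hybrid_genotypes()]).
#' @return A `relationship_matrix` of dimension `n_F * n_M`.
#' @export
sca_kernel <- function(G_F, G_M, sep = "/") {
  G_F <- as.matrix(G_F); G_M <- as.matrix(G_M)
  ids <- as.vector(t(outer(rownames(G_F), rownames(G_M), paste, sep = sep)))
  K <- G_F %x% G_M
  dimnames(K) <- list(ids, ids)
  relationship_matrix(K, kind = "G_FM")
}

#' Identity kernel over a set of levels
#'
#' @param ids character vector of level ids.
#' @return A `relationship_matrix` of kind `"identity"`.
#' @export
identity_kernel <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  relationship_matrix(K, kind = "identity")
}

#' Rescale a kernel so random effects have unit expected sample variance
#'
#' Divides a kernel by `(tr(G) - sum(G)/q) / (q - 1)`, the expected sample
#' variance of one MVN(0, G) draw across its q levels.  Effects drawn with
#' covariance `sigma2 * scale_kernel(G)` then have realized variance across
#' levels converging to `sigma2`, which makes simulated variance components
#' directly interpretable and recoverable.  Used by the population
#' simulator; analysis kernels are left on the VanRaden scale.
#'
#' @param G a relationship matrix.
#' @return Rescaled `relationship_matrix` (same kind, `"_scaled"` suffix).
#' @export
scale_kernel <- function(G) {
  q <- nrow(G)
  psi <- (sum(diag(G)) - sum(G) / q) / (q - 1)
  if (psi <= 0) stop("degenerate kernel: non-positive expected sample variance")
  relationship_matrix(as.matrix(G) / psi,
    kind = paste0(attr(G, "kind") %||% "G", "_scaled"),
    stabilized = isTRUE(attr(G, "stabilized"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
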