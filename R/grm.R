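#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' Centers the dosage matrix by twice the allele frequency and scales the
#' cross-product by `2 * sum(p * (1 - p))` over polymorphic markers
#' (monomorphic markers are excluded from the scaling; after centering they
#' contribute nothing to the numerator). For fully inbred panels the raw
#' VanRaden diagonal averages ~2 (inbred lines carry double the
#' Hardy-Weinberg dosage variance), so by default the matrix is
#' additionally normalized to mean diagonal 1; this keeps the REML
#' heritability `sigma_g^2 / (sigma_g^2 + sigma_e^2)` interpretable as the
#' fraction of phenotypic variance that is genetic on the line basis.
#'
#' @param panel a `GenotypePanel` or a plain dosage matrix (varieties in
#'   rows).
#' @param normalize rescale to mean diagonal 1 (default `TRUE`).
#' @return symmetric n x n matrix of class `GRM` with variety dimnames and
#'   attribute `"n_polymorphic"`.
#' @export
compute_grm <- function(panel, normalize = TRUE) {
  geno <- if (inherits(panel, "GenotypePanel")) panel$geno else as.matrix(panel)
  if (nrow(geno) < 2) stop("need at least 2 varieties")
  if (any(is.na(geno))) stop("no missing dosages allowed; filter markers first")
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic")
  w <- sweep(geno, 2, 2 * p)
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  g <- tcrossprod(w) / denom
  if (normalize) g <- g / mean(diag(g))
  dimnames(g) <- list(rownames(geno), rownames(geno))
  attr(g, "n_polymorphic") <- sum(poly)
  class(g) <- c("GRM", class(g))
  g
}

# Symmetric eigendecomposition of a GRM with PSD jitter: small negative
# eigenvalues from numerical error are lifted to a tiny positive floor.
grm_eigen <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values)) {
    message("GRM not numerically PSD; eigenvalue floor applied")
  }
  e$values <- pmax(e$values, 1e-9)
  e
}
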