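# Small builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk unless a test writes it first.

small_panel <- function(n_spring = 40, n_winter = 30, n_alternative = 0,
                        n_markers = 300, founder_count = 12, seed = 7, ...) {
  simulate_panel(panel_config(n_spring = n_spring, n_winter = n_winter,
                              n_alternative = n_alternative,
                              n_markers = n_markers,
                              founder_count = founder_count, seed = seed, ...))
}

# tiny deterministic panel built by hand (no simulation)
toy_panel <- function(geno) {
  m <- ncol(geno)
  map <- data.frame(marker = colnames(geno), chrom = "chr1",
                    cM = seq_len(m) * 10, bp = seq_len(m) * 1000)
  info <- data.frame(variety_id = rownames(geno),
                     seasonal_type = "spring",
                     listing_year = 2000 + seq_len(nrow(geno)),
                     afp_order = seq_len(nrow(geno)))
  genotype_panel(geno, map, info)
}

toy_traits <- function(scores, scale = NULL) {
  if (is.null(scale)) {
    scale <- stats::setNames(rep(list(1:9), ncol(scores)), colnames(scores))
  }
  trait_table(scores, scale)
}

named_matrix <- function(vals, ids, markers) {
  matrix(vals, length(ids), length(markers), byrow = TRUE,
         dimnames = list(ids, markers))
}

# map with unlinked markers (one per chromosome)
unlinked_map <- function(k) {
  data.frame(marker = paste0("u", seq_len(k)),
             chrom = paste0("chr", seq_len(k)),
             cM = rep(0, k), bp = rep(1L, k))
}

# brute-force REML log-likelihood for the single-kernel model, by direct
# dense-matrix evaluation (independent of the eigendecomposition path)
brute_reml_loglik <- function(sg2, se2, y, X, A) {
  V <- sg2 * A + se2 * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus +
                      determinant(XtViX, logarithm = TRUE)$modulus +
                      drop(t(r) %*% Vi %*% r))
}

# selfing-chain enumeration: genotype distribution (AA, AB, BB) of one
# locus after k selfing generations starting from a heterozygote
selfing_dist <- function(k) {
  v <- c(0, 1, 0)  # P(AA), P(AB), P(BB)
  for (i in seq_len(k)) {
    v <- c(v[1] + v[2] / 4, v[2] / 2, v[3] + v[2] / 4)
  }
  v
}
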