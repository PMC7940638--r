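#' Mixed-linear-model association scan of a DUS trait
#'
#' Per-marker Wald test of the marker effect in
#' `y = X beta + m_i k_i + g + e` with the polygenic term `g ~ N(0,
#' sigma_g^2 A)`. Variance components are estimated once on the null model
#' (no marker) and reused for every marker — the standard
#' population-parameters-previously-determined (P3D) approximation — so the
#' scan reduces to a generalized-least-squares regression in the whitened
#' eigenbasis of `A`. With `exact = TRUE` the variance components are
#' instead re-estimated by REML for every marker (slow; intended for small
#' fixtures). Markers monomorphic in the analysis set get `NA` p-values;
#' q-values are computed within the scan by [fdr_qvalues()].
#'
#' @param y named numeric trait vector (missing values dropped).
#' @param X fixed-effect design matrix.
#' @param panel a `GenotypePanel` (or dosage matrix with marker columns).
#' @param A relationship matrix from [compute_grm()]; computed from the
#'   panel when `NULL`.
#' @param exact per-marker REML instead of P3D.
#' @param population label stored in the result metadata.
#' @return a data.frame of class `GwasResult` with one row per tested
#'   marker: `marker`, `chrom`, `cM`, `bp`, `effect`, `se`, `p`,
#'   `neglog10p`, `q`; attributes `null_fit` (the [reml_univariate()]
#'   result), `population`, `conditioning` (character vector of markers in
#'   the fixed effects).
#' @export
run_gwas <- function(y, X, panel, A = NULL, exact = FALSE,
                     population = "combined") {
  geno <- if (inherits(panel, "GenotypePanel")) panel$geno else as.matrix(panel)
  map <- if (inherits(panel, "GenotypePanel")) panel$map else NULL
  if (is.null(A)) A <- compute_grm(geno)
  keep <- !is.na(y)
  ids <- if (!is.null(names(y))) names(y)[keep] else which(keep)
  y <- y[keep]
  X <- X[ids, , drop = FALSE]
  geno <- geno[ids, , drop = FALSE]
  A <- A[ids, ids]
  n <- length(y)
  p <- ncol(X)
  eig <- grm_eigen(unclass(A))
  null_fit <- reml_univariate(y, X, A, eig = eig)
  mono <- apply(geno, 2, function(v) length(unique(v)) == 1)
  if (exact) {
    res <- t(vapply(seq_len(ncol(geno)), function(j) {
      if (mono[j]) return(c(NA_real_, NA_real_, NA_real_))
      xj <- cbind(X, marker = geno[, j])
      fit <- reml_univariate(y, xj, A, eig = eig)
      gls_wald(y, xj, eig, fit$lambda, which = ncol(xj))
    }, numeric(3)))
  } else {
    lam <- null_fit$lambda
    w <- 1 / (lam * eig$values + 1)
    s <- sqrt(w)
    ys <- s * drop(crossprod(eig$vectors, y))
    xs <- s * crossprod(eig$vectors, X)
    ms <- s * crossprod(eig$vectors, geno)
    qx <- qr(xs)
    yt <- qr.resid(qx, ys)
    mt <- qr.resid(qx, ms)
    mm <- colSums(mt^2)
    my <- colSums(mt * yt)
    ok <- !mono & mm > 1e-10
    eff <- my / mm
    rss <- sum(yt^2) - my^2 / mm
    df <- n - p - 1
    sig2 <- rss / df
    se <- sqrt(sig2 / mm)
    tval <- eff / se
    pv <- 2 * stats::pt(-abs(tval), df)
    eff[!ok] <- se[!ok] <- pv[!ok] <- NA_real_
    res <- cbind(eff, se, pv)
  }
  out <- data.frame(marker = colnames(geno),
                    effect = res[, 1], se = res[, 2], p = res[, 3])
  if (!is.null(map)) {
    out <- cbind(out[, "marker", drop = FALSE],
                 map[match(out$marker, map$marker), c("chrom", "cM", "bp")],
                 out[, c("effect", "se", "p")])
  }
  out$neglog10p <- -log10(out$p)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  # exact zero p from extreme tests: floor at the smallest double
  out$p[ok & out$p == 0] <- .Machine$double.xmin
  out$q[ok] <- fdr_qvalues(out$p[ok])
  rownames(out) <- NULL
  class(out) <- c("GwasResult", class(out))
  attr(out, "null_fit") <- null_fit
  attr(out, "population") <- population
  attr(out, "conditioning") <- character(0)
  out
}

gls_wald <- function(y, X, eig, lam, which) {
  w <- 1 / (lam * eig$values + 1)
  s <- sqrt(w)
  ys <- s * drop(crossprod(eig$vectors, y))
  xs <- s * crossprod(eig$vectors, X)
  fit <- stats::lm.fit(xs, ys)
  cf <- fit$coefficients[which]
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  xtx_inv <- chol2inv(chol(crossprod(xs)))
  se <- sqrt(rss / df * xtx_inv[which, which])
  c(cf, se, 2 * stats::pt(-abs(cf / se), df))
}

#' Conditional re-scan on the top marker
#'
#' Linkage disequilibrium around a major locus can lift markers elsewhere
#' in the genome above the significance threshold. Whenever the strongest
#' signal of a scan exceeds the trigger (default -log10 p of 10), the scan
#' is repeated once with the top marker added to the fixed effects (and
#' excluded from the tested set); markers that were significant only
#' through LD with that locus drop out of the second scan.
#'
#' @param result a `GwasResult` from [run_gwas()].
#' @param y,X,panel,A the inputs of the original scan.
#' @param trigger -log10 p threshold for triggering the re-scan.
#' @return the input `result` unchanged when no marker reaches the
#'   trigger; otherwise a list of class `GwasScanPair` with elements
#'   `initial`, `conditional` and `conditioning_marker`.
#' @export
conditional_rescan <- function(result, y, X, panel, A = NULL, trigger = 10) {
  stopifnot(inherits(result, "GwasResult"))
  ok <- !is.na(result$neglog10p)
  if (!any(ok) || max(result$neglog10p[ok]) <= trigger) {
    return(result)
  }
  top <- result$marker[ok][which.max(result$neglog10p[ok])]
  geno <- if (inherits(panel, "GenotypePanel")) panel$geno else as.matrix(panel)
  mcol <- geno[rownames(X), top]
  x2 <- cbind(X, mcol)
  colnames(x2)[ncol(x2)] <- top
  if (qr(x2)$rank < ncol(x2)) {
    stop("conditioning marker ", top, " is collinear with the fixed effects")
  }
  keep <- setdiff(colnames(geno), top)
  panel2 <- if (inherits(panel, "GenotypePanel")) {
    structure(list(geno = geno[, keep, drop = FALSE],
                   map = panel$map[panel$map$marker %in% keep, , drop = FALSE],
                   info = panel$info),
              class = "GenotypePanel")
  } else {
    geno[, keep, drop = FALSE]
  }
  res2 <- run_gwas(y, x2, panel2, A = A,
                   population = attr(result, "population"))
  attr(res2, "conditioning") <- top
  structure(list(initial = result, conditional = res2,
                 conditioning_marker = top),
            class = "GwasScanPair")
}

#' @export
print.GwasResult <- function(x, ...) {
  ok <- !is.na(x$p)
  cat(sprintf("GwasResult (%s): %d markers tested, %d NA\n",
              attr(x, "population"), sum(ok), sum(!ok)))
  hits <- x[ok & x$q < 0.05, , drop = FALSE]
  cat(sprintf("  FDR<0.05 hits: %d; top -log10 p = %.2f\n",
              nrow(hits), max(x$neglog10p[ok])))
  invisible(x)
}
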