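#' Fixed-effect design matrix for DUS trait analyses
#'
#' Intercept, year of entry into the national listing (continuous) and,
#' when more than one seasonal type is present, the seasonal type factor
#' (dropped automatically in spring-only or winter-only analyses).
#'
#' @param info a panel `info` data.frame (see [genotype_panel()]).
#' @param include_type include the seasonal-type factor when possible.
#' @return numeric design matrix with variety row names.
#' @export
dus_fixed_design <- function(info, include_type = TRUE) {
  year <- info$listing_year
  if (all(is.na(year))) year <- rep(0, nrow(info))
  year <- year - mean(year, na.rm = TRUE)
  x <- cbind(intercept = 1, year = year)
  if (include_type && length(unique(info$seasonal_type)) > 1) {
    mm <- stats::model.matrix(~ seasonal_type, data = info)[, -1, drop = FALSE]
    x <- cbind(x, mm)
  }
  rownames(x) <- info$variety_id
  x
}

# Full REML log-likelihood (constant -(n-p)/2*log(2*pi) omitted) for the
# single-kernel model V = sg2*A + se2*I, evaluated in the eigenbasis of A.
reml_loglik_uni <- function(sg2, se2, ystar, xstar, d) {
  v <- sg2 * d + se2
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  xtvx <- crossprod(xstar * w, xstar)
  ch <- tryCatch(chol(xtvx), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(xstar, w * ystar)))
  r <- ystar - xstar %*% beta
  ypy <- sum(w * r^2)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + ypy)
}

#' Univariate REML for a genomic mixed model
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigma_g^2 A)` and
#' `e ~ N(0, sigma_e^2 I)` by exact profile REML over the variance ratio,
#' using the spectral decomposition of the relationship matrix (a single
#' random effect makes the profiled restricted likelihood one-dimensional,
#' so the fit is deterministic and exact up to the 1-D optimizer
#' tolerance). Heritability is `sigma_g^2 / (sigma_g^2 + sigma_e^2)`; its
#' standard error comes from the observed information of the variance
#' components via the delta method.
#'
#' @param y named numeric response (ordinal DUS scores are analysed as
#'   numeric); missing values are dropped together with their rows of `X`
#'   and `A`.
#' @param X fixed-effect design matrix (see [dus_fixed_design()]).
#' @param A relationship matrix from [compute_grm()].
#' @param eig optional precomputed `grm_eigen(A)` (used by the GWAS driver
#'   to avoid repeated decompositions); must match `A` after missing-data
#'   alignment, so only supply it when `y` is complete.
#' @return object of class `VarCompResult`: variance components `sigma_g2`,
#'   `sigma_e2`, `sigma_y2` (= their sum), `h2`, `se_h2`, `beta`,
#'   `loglik`, `lambda`, `n`, and a `status` string (`"converged"`,
#'   `"boundary"`, or `"degenerate"`).
#' @export
reml_univariate <- function(y, X, A, eig = NULL) {
  keep <- !is.na(y)
  if (!is.null(names(y))) {
    ids <- names(y)[keep]
    y <- y[keep]
    X <- X[ids, , drop = FALSE]
    A <- A[ids, ids]
    if (!is.null(eig) && any(!keep)) eig <- NULL
  } else {
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
    A <- A[keep, keep]
    if (!is.null(eig) && any(!keep)) eig <- NULL
  }
  n <- length(y)
  p <- qr(X)$rank
  if (p < ncol(X)) {
    X <- X[, qr(X)$pivot[seq_len(p)], drop = FALSE]
  }
  if (n <= p + 1) stop("too few observations for REML")
  if (stats::sd(y) == 0) {
    stop("response has zero variance")
  }
  if (is.null(eig)) eig <- grm_eigen(unclass(A))
  d <- eig$values
  ystar <- drop(crossprod(eig$vectors, y))
  xstar <- crossprod(eig$vectors, X)
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    xtvx <- crossprod(xstar * w, xstar)
    ch <- tryCatch(chol(xtvx), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(xstar, w * ystar)))
    r <- ystar - xstar %*% beta
    rss <- sum(w * r^2)
    se2 <- rss / (n - p)
    ll <- reml_loglik_uni(lam * se2, se2, ystar, xstar, d)
    list(ll = ll, se2 = se2, beta = beta)
  }
  grid <- seq(-15, 15, length.out = 61)
  lls <- vapply(grid, function(g) prof(g)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(g) prof(g)$ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  fit <- prof(opt$maximum)
  lam <- exp(opt$maximum)
  se2 <- fit$se2
  sg2 <- lam * se2
  status <- "converged"
  if (opt$maximum <= grid[1] + 1 || opt$maximum >= grid[length(grid)] - 1) {
    status <- "boundary"
  }
  if (se2 < 1e-10 * stats::var(y)) status <- "degenerate"
  h2 <- sg2 / (sg2 + se2)
  se_h2 <- h2_se_delta(sg2, se2, ystar, xstar, d)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, sigma_y2 = sg2 + se2,
                 h2 = h2, se_h2 = se_h2, beta = beta,
                 loglik = fit$ll, lambda = lam, n = n, status = status),
            class = "VarCompResult")
}

h2_se_delta <- function(sg2, se2, ystar, xstar, d) {
  f <- function(th) reml_loglik_uni(th[1], th[2], ystar, xstar, d)
  h <- tryCatch(num_hessian(f, c(sg2, se2)), error = function(e) NULL)
  if (is.null(h)) return(NA_real_)
  info <- -h
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) return(NA_real_)
  tot <- sg2 + se2
  grad <- c(se2, -sg2) / tot^2
  v <- drop(t(grad) %*% vc %*% grad)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

num_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel, 1e-8)
  out <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        out[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        out[i, j] <- out[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  out
}

#' @export
print.VarCompResult <- function(x, ...) {
  cat(sprintf("VarCompResult (n = %d, %s): h2 = %.3f (SE %.3f)\n",
              x$n, x$status, x$h2, x$se_h2))
  cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f\n", x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' Bivariate REML for genetic and phenotypic correlations
#'
#' Fits the two-trait genomic mixed model with unstructured 2x2 genetic and
#' residual covariance matrices, each Kronecker-multiplied with the
#' relationship matrix and the identity respectively. Both traits must be
#' observed on the analysis set. The fit works in the eigenbasis of `A`,
#' where the restricted likelihood factorizes over 2x2 blocks; variance
#' components are parameterized as log-variances and `atanh` correlations
#' so constraints hold automatically, warm-started from the two univariate
#' fits, and maximized by quasi-Newton (BFGS). The phenotypic correlation
#' is computed exactly from the estimated components:
#' `rho_y = (rho_g*sg1*sg2 + rho_e*se1*se2) / sqrt((sg1^2+se1^2)*(sg2^2+se2^2))`.
#'
#' @param y1,y2 named numeric responses (varieties missing either trait are
#'   dropped).
#' @param X fixed-effect design matrix (same convention for both traits).
#' @param A relationship matrix.
#' @param fix_rho optionally fix both correlations at a value (e.g.
#'   `fix_rho = 0` constrains the model to two independent traits, which
#'   must then agree with the univariate fits).
#' @return object of class `BivarResult` with the four variance components,
#'   `rho_g`, `rho_e`, `rho_y`, delta-method `se_rho_g` and `se_rho_y`,
#'   `loglik`, `n` and `status` (`"converged"` or `"boundary"` when a
#'   correlation is at +/-1).
#' @export
reml_bivariate <- function(y1, y2, X, A, fix_rho = NULL) {
  if (!is.null(names(y1)) && !is.null(names(y2))) {
    ids <- intersect(names(y1)[!is.na(y1)], names(y2)[!is.na(y2)])
    y1 <- y1[ids]; y2 <- y2[ids]
    X <- X[ids, , drop = FALSE]
    A <- A[ids, ids]
  } else {
    keep <- !is.na(y1) & !is.na(y2)
    y1 <- y1[keep]; y2 <- y2[keep]
    X <- X[keep, , drop = FALSE]
    A <- A[keep, keep]
  }
  n <- length(y1)
  p <- qr(X)$rank
  if (p < ncol(X)) X <- X[, qr(X)$pivot[seq_len(p)], drop = FALSE]
  eig <- grm_eigen(unclass(A))
  d <- eig$values
  u <- eig$vectors
  z1 <- drop(crossprod(u, y1))
  z2 <- drop(crossprod(u, y2))
  xs <- crossprod(u, X)
  negll <- function(th) {
    g1 <- exp(th[1]); g2 <- exp(th[2]); rg <- tanh(th[3])
    e1 <- exp(th[4]); e2 <- exp(th[5]); re <- tanh(th[6])
    if (any(!is.finite(c(g1, g2, rg, e1, e2, re)))) return(1e10)
    m11 <- d * g1 + e1
    m22 <- d * g2 + e2
    m12 <- d * rg * sqrt(g1 * g2) + re * sqrt(e1 * e2)
    det <- m11 * m22 - m12^2
    if (any(!is.finite(det)) || any(det <= 0) || any(m11 <= 0)) return(1e10)
    ai <- m22 / det; bi <- -m12 / det; ci <- m11 / det
    k11 <- crossprod(xs * ai, xs)
    k12 <- crossprod(xs * bi, xs)
    k22 <- crossprod(xs * ci, xs)
    kmat <- rbind(cbind(k11, k12), cbind(k12, k22))
    rhs <- c(crossprod(xs, ai * z1 + bi * z2),
             crossprod(xs, bi * z1 + ci * z2))
    ch <- tryCatch(chol(kmat), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), rhs))
    r1 <- z1 - xs %*% beta[seq_len(p)]
    r2 <- z2 - xs %*% beta[p + seq_len(p)]
    ypy <- sum(ai * r1^2 + 2 * bi * r1 * r2 + ci * r2^2)
    0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) + ypy)
  }
  # warm start: univariate components, residual-correlation moment estimate
  f1 <- reml_univariate(y1, X, A, eig = eig)
  f2 <- reml_univariate(y2, X, A, eig = eig)
  r0 <- stats::cor(stats::resid(stats::lm(y1 ~ X - 1)),
                   stats::resid(stats::lm(y2 ~ X - 1)))
  r0 <- max(min(r0, 0.9), -0.9)
  start <- c(log(max(f1$sigma_g2, 1e-4)), log(max(f2$sigma_g2, 1e-4)),
             atanh(r0), log(max(f1$sigma_e2, 1e-4)),
             log(max(f2$sigma_e2, 1e-4)), atanh(r0))
  if (!is.null(fix_rho)) {
    zfix <- atanh(max(min(fix_rho, 0.999999), -0.999999))
    negll_fixed <- function(th4) negll(c(th4[1:2], zfix, th4[3:4], zfix))
    opt <- stats::optim(start[c(1, 2, 4, 5)], negll_fixed, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    th <- c(opt$par[1:2], zfix, opt$par[3:4], zfix)
  } else {
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  }
  g1 <- exp(th[1]); g2 <- exp(th[2]); rg <- tanh(th[3])
  e1 <- exp(th[4]); e2 <- exp(th[5]); re <- tanh(th[6])
  ry <- rho_y_from_components(g1, g2, rg, e1, e2, re)
  status <- if (abs(rg) > 0.999 || abs(re) > 0.999) "boundary"
            else if (opt$convergence == 0) "converged" else "not converged"
  ses <- if (is.null(fix_rho)) bivar_se_delta(negll, th) else
    c(rho_g = NA_real_, rho_y = NA_real_)
  structure(list(sigma_g1_2 = g1, sigma_g2_2 = g2,
                 sigma_e1_2 = e1, sigma_e2_2 = e2,
                 rho_g = rg, rho_e = re, rho_y = ry,
                 se_rho_g = ses["rho_g"], se_rho_y = ses["rho_y"],
                 loglik = -opt$value, n = n, status = status),
            class = "BivarResult")
}

#' Phenotypic correlation from bivariate variance components
#'
#' @param g1,g2 genetic variances of traits 1 and 2.
#' @param rg genetic correlation.
#' @param e1,e2 residual variances.
#' @param re residual correlation.
#' @return the phenotypic correlation implied by the components.
#' @export
rho_y_from_components <- function(g1, g2, rg, e1, e2, re) {
  (rg * sqrt(g1 * g2) + re * sqrt(e1 * e2)) /
    sqrt((g1 + e1) * (g2 + e2))
}

bivar_se_delta <- function(negll, th) {
  out <- c(rho_g = NA_real_, rho_y = NA_real_)
  h <- tryCatch(num_hessian(function(x) -negll(x), th), error = function(e) NULL)
  if (is.null(h)) return(out)
  vc <- tryCatch(solve(-h), error = function(e) NULL)
  if (is.null(vc)) return(out)
  rg <- tanh(th[3])
  v_rg <- (1 - rg^2)^2 * vc[3, 3]
  if (is.finite(v_rg) && v_rg >= 0) out["rho_g"] <- sqrt(v_rg)
  ry_of <- function(x) {
    rho_y_from_components(exp(x[1]), exp(x[2]), tanh(x[3]),
                          exp(x[4]), exp(x[5]), tanh(x[6]))
  }
  grad <- vapply(seq_along(th), function(i) {
    e <- numeric(length(th)); e[i] <- 1e-5
    (ry_of(th + e) - ry_of(th - e)) / 2e-5
  }, numeric(1))
  v_ry <- drop(t(grad) %*% vc %*% grad)
  if (is.finite(v_ry) && v_ry >= 0) out["rho_y"] <- sqrt(v_ry)
  out
}

#' @export
print.BivarResult <- function(x, ...) {
  cat(sprintf("BivarResult (n = %d, %s):\n", x$n, x$status))
  cat(sprintf("  rho_g = %.3f (SE %.3f), rho_e = %.3f, rho_y = %.3f (SE %.3f)\n",
              x$rho_g, x$se_rho_g, x$rho_e, x$rho_y, x$se_rho_y))
  invisible(x)
}
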