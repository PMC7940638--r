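test_that("with an identity kinship the scan reproduces the OLS F-test", {
  set.seed(41)
  n <- 60
  geno <- matrix(sample(c(0, 2), n * 30, replace = TRUE), n, 30,
                 dimnames = list(paste0("v", 1:n), paste0("m", 1:30)))
  y <- setNames(rnorm(n), rownames(geno))
  X <- cbind(intercept = rep(1, n))
  rownames(X) <- rownames(geno)
  A <- diag(n)
  dimnames(A) <- list(rownames(geno), rownames(geno))
  res <- run_gwas(y, X, geno, A = A)
  # OLS oracle per marker
  for (j in c(1, 7, 20)) {
    ols <- summary(lm(y ~ geno[, j]))$coefficients
    expect_equal(res$p[j], ols[2, 4], tolerance = 1e-6)
    expect_equal(res$effect[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("a large-effect QTL is localized and monomorphic markers yield NA", {
  sim <- small_panel(n_spring = 80, n_winter = 80, n_markers = 600, seed = 43)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.8, n_qtl = 1)),
                        seed = 3)
  y <- setNames(tr$latent[, 1], rownames(sim$panel$geno))
  res <- run_gwas(y, X, sim$panel, A = A)
  map <- sim$panel$map
  top <- res$marker[which.max(res$neglog10p)]
  qtl <- tr$qtl$t1
  expect_equal(map$chrom[map$marker == top], map$chrom[map$marker == qtl])
  expect_lt(abs(map$cM[map$marker == top] - map$cM[map$marker == qtl]), 5)
  # monomorphic marker: NA result
  geno2 <- sim$panel$geno
  geno2[, 1] <- 2
  res2 <- run_gwas(y, X, geno2, A = A)
  expect_true(is.na(res2$p[1]))
  # every NA marker is unestimable: monomorphic or confounded with the
  # fixed effects (e.g. fixed between seasonal types)
  for (j in which(is.na(res2$p))) {
    r2 <- suppressWarnings(summary(lm(geno2[, j] ~ X - 1))$r.squared)
    expect_true(var(geno2[, j]) == 0 || r2 > 0.999)
  }
})

test_that("scan statistics are invariant to a consistent variety permutation", {
  sim <- small_panel(n_spring = 40, n_winter = 0, n_markers = 200, seed = 47)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.5)), seed = 2)
  y <- setNames(tr$latent[, 1], rownames(sim$panel$geno))
  res <- run_gwas(y, X, sim$panel, A = A)
  perm <- sample(names(y))
  res2 <- run_gwas(y[perm], X[perm, , drop = FALSE],
                   sim$panel$geno[perm, ], A = A[perm, perm])
  expect_equal(res2$p, res$p, tolerance = 1e-5)
  expect_equal(res2$effect, res$effect, tolerance = 1e-5)
})

test_that("exact per-marker REML agrees with P3D on a small fixture", {
  sim <- small_panel(n_spring = 30, n_winter = 0, n_markers = 60, seed = 53)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.4)), seed = 8)
  y <- setNames(tr$latent[, 1], rownames(sim$panel$geno))
  p3d <- run_gwas(y, X, sim$panel, A = A)
  ex <- run_gwas(y, X, sim$panel, A = A, exact = TRUE)
  ok <- !is.na(p3d$p) & !is.na(ex$p)
  expect_gt(cor(-log10(p3d$p[ok]), -log10(ex$p[ok])), 0.97)
})

test_that("q-values reproduce the BH oracle at pi0 = 1 and behave at the edges", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  q <- fdr_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), c(0.004, 0.02, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(fdr_qvalues(rep(1, 10)) == 1))
  # monotone in sorted p and never above 1
  set.seed(5)
  p2 <- runif(500)^0.7
  q2 <- fdr_qvalues(p2)
  expect_true(all(q2 <= 1))
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_true(attr(q2, "pi0") <= 1 && attr(q2, "pi0") > 0)
  expect_error(fdr_qvalues(numeric(0)), "empty")
  expect_error(fdr_qvalues(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("null scans are calibrated: uniform p and few FDR discoveries", {
  # unrelated lines (no pedigree LD) so markers are independent
  hits <- integer(10)
  ksp <- numeric(10)
  for (r in 1:10) {
    sim <- simulate_panel(panel_config(n_spring = 60, n_winter = 60,
                                       n_alternative = 0, n_markers = 300,
                                       founder_count = 60, pedigree_depth = 0,
                                       seed = 100 + r))
    A <- compute_grm(sim$panel)
    X <- dus_fixed_design(sim$panel$info)
    set.seed(200 + r)
    y <- setNames(rnorm(120), rownames(sim$panel$geno))
    res <- run_gwas(y, X, sim$panel, A = A)
    ok <- !is.na(res$p)
    hits[r] <- sum(res$q[ok] < 0.05)
    ksp[r] <- suppressWarnings(ks.test(res$p[ok], "punif")$p.value)
  }
  expect_lt(mean(hits), 0.05 * 300)
  expect_gt(median(ksp), 0.05)
})

test_that("the conditional re-scan removes LD-shadow peaks and is a no-op otherwise", {
  sim <- small_panel(n_spring = 100, n_winter = 0, n_markers = 300,
                     founder_count = 40, seed = 59)
  geno <- sim$panel$geno
  map <- sim$panel$map
  # plant a QTL on chr1 and a near-copy shadow marker on chr5; the QTL must
  # segregate at intermediate frequency
  freq <- colMeans(geno) / 2
  qtl <- map$marker[map$chrom == "chr1" & freq > 0.3 & freq < 0.7][1]
  shadow <- map$marker[map$chrom == "chr5"][5]
  geno[, shadow] <- geno[, qtl]
  flip <- sample(nrow(geno), 4)
  geno[flip, shadow] <- 2 - geno[flip, shadow]
  panel <- genotype_panel(geno, map, sim$panel$info)
  A <- compute_grm(panel)
  X <- dus_fixed_design(panel$info)
  set.seed(7)
  y <- setNames(2 * geno[, qtl] + rnorm(nrow(geno), 0, 1.5), rownames(geno))
  res <- run_gwas(y, X, panel, A = A)
  expect_gt(max(res$neglog10p, na.rm = TRUE), 10)
  expect_lt(res$q[res$marker == shadow], 0.05)  # shadow significant in scan 1
  pair <- conditional_rescan(res, y, X, panel, A = A, trigger = 10)
  expect_s3_class(pair, "GwasScanPair")
  expect_equal(pair$conditioning_marker,
               res$marker[which.max(res$neglog10p)])
  # conditioning marker excluded from the second scan
  expect_false(pair$conditioning_marker %in% pair$conditional$marker)
  # the shadow peak collapses once the top marker is conditioned on
  sh2 <- pair$conditional[pair$conditional$marker == shadow, ]
  expect_gt(sh2$q, 0.05)
  # no marker above the trigger: identical output
  set.seed(8)
  y0 <- setNames(rnorm(nrow(geno)), rownames(geno))
  res0 <- run_gwas(y0, X, panel, A = A)
  expect_identical(conditional_rescan(res0, y0, X, panel, A = A), res0)
})
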