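test_that("GRM matches the hand-computed VanRaden oracle on a toy matrix", {
  geno <- named_matrix(c(0, 2,
                         2, 2,
                         0, 0), c("a", "b", "c"), c("m1", "m2"))
  g <- compute_grm(geno, normalize = FALSE)
  # oracle: center by 2p, cross-product, scale by 2*sum(p(1-p))
  p <- colMeans(geno) / 2
  w <- sweep(geno, 2, 2 * p)
  oracle <- tcrossprod(w) / (2 * sum(p * (1 - p)))
  expect_equal(unclass(g), oracle, ignore_attr = TRUE)
  gn <- compute_grm(geno)
  expect_equal(mean(diag(gn)), 1)
})

test_that("GRM is symmetric under allele-label swaps and identical lines coincide", {
  sim <- small_panel(n_markers = 120, seed = 9)
  geno <- sim$panel$geno
  g1 <- compute_grm(geno)
  flip <- sample(ncol(geno), 30)
  geno2 <- geno
  geno2[, flip] <- 2 - geno2[, flip]
  expect_equal(compute_grm(geno2), g1, tolerance = 1e-12)
  # duplicated line: off-diagonal equals both diagonals
  dup <- rbind(geno[1:5, ], twin = geno[1, ])
  rownames(dup)[6] <- "twin"
  gd <- compute_grm(dup)
  expect_equal(gd["twin", rownames(geno)[1]], gd["twin", "twin"])
  expect_equal(gd[1, 1], gd["twin", "twin"])
  expect_error(compute_grm(matrix(2, 3, 4,
                                  dimnames = list(letters[1:3], LETTERS[1:4]))),
               "monomorphic")
})

test_that("eigendecomposition REML agrees with a brute-force likelihood grid", {
  sim <- small_panel(n_spring = 40, n_winter = 0, n_markers = 200, seed = 13)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.6, n_qtl = 5)),
                        seed = 4)
  y <- setNames(tr$latent[, 1], rownames(sim$panel$geno))
  fit <- reml_univariate(y, X, A)
  # brute-force search over h2 of the profiled restricted likelihood
  Au <- unclass(A)
  class(Au) <- "matrix"
  grid <- seq(0.01, 0.99, 0.01)
  lls <- vapply(grid, function(h) {
    sy <- fit$sigma_y2
    brute_reml_loglik(h * sy, (1 - h) * sy, y, X, Au)
  }, numeric(1))
  expect_lt(abs(grid[which.max(lls)] - fit$h2), 0.015)
  # the solver's likelihood value matches the dense-matrix evaluation
  ll_dense <- brute_reml_loglik(fit$sigma_g2, fit$sigma_e2, y, X, Au)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-4)
  expect_lte(max(lls), fit$loglik + 1e-4)  # grid never beats the solver
})

test_that("heritability estimates are invariant to affine rescaling of y", {
  sim <- small_panel(n_spring = 35, n_winter = 0, n_markers = 150, seed = 17)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.5)), seed = 6)
  y <- setNames(tr$latent[, 1], rownames(sim$panel$geno))
  f1 <- reml_univariate(y, X, A)
  f2 <- reml_univariate(5 * y - 3, X, A)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$se_h2, f2$se_h2, tolerance = 1e-4)
})

test_that("degenerate and missing-data inputs are handled explicitly", {
  sim <- small_panel(n_spring = 30, n_winter = 0, n_markers = 100, seed = 19)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  # y exactly in the column span of X: zero residual flagged
  y <- setNames(drop(X %*% c(2, 0.1)), rownames(X))
  fit <- reml_univariate(y, X, A)
  expect_true(fit$status %in% c("degenerate", "boundary"))
  # missing values dropped pairwise
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.4)), seed = 2)
  y2 <- setNames(tr$latent[, 1], rownames(X))
  y2[1:5] <- NA
  fit2 <- reml_univariate(y2, X, A)
  expect_equal(fit2$n, 25)
  expect_error(reml_univariate(setNames(rep(1, 30), rownames(X)), X, A),
               "zero variance")
})

test_that("phenotypic correlation identity holds and self-correlation hits the boundary", {
  # direct substitution: unit variances, rho_g = 0.5, rho_e = 0
  expect_equal(rho_y_from_components(1, 1, 0.5, 1, 1, 0), 0.25)
  sim <- small_panel(n_spring = 60, n_winter = 0, n_markers = 200, seed = 23)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.5)), seed = 3)
  y <- setNames(tr$latent[, 1], rownames(X))
  fit <- reml_bivariate(y, y, X, A)
  expect_gt(fit$rho_g, 0.99)
  expect_gt(fit$rho_y, 0.99)
  expect_equal(fit$status, "boundary")
})

test_that("bivariate fit with correlations fixed at zero degenerates to univariate", {
  sim <- small_panel(n_spring = 80, n_winter = 0, n_markers = 300, seed = 29)
  A <- compute_grm(sim$panel)
  X <- dus_fixed_design(sim$panel$info)
  tr <- simulate_traits(sim$panel, list(trait_spec(1, target_h2 = 0.6, n_qtl = 10),
                                        trait_spec(2, target_h2 = 0.3, n_qtl = 10)),
                        seed = 7)
  y1 <- setNames(tr$latent[, 1], rownames(X))
  y2 <- setNames(tr$latent[, 2], rownames(X))
  bi <- reml_bivariate(y1, y2, X, A, fix_rho = 0)
  u1 <- reml_univariate(y1, X, A)
  u2 <- reml_univariate(y2, X, A)
  expect_equal(bi$sigma_g1_2, u1$sigma_g2, tolerance = 1e-3)
  expect_equal(bi$sigma_e1_2, u1$sigma_e2, tolerance = 1e-3)
  expect_equal(bi$sigma_g2_2, u2$sigma_g2, tolerance = 1e-3)
  expect_equal(bi$sigma_e2_2, u2$sigma_e2, tolerance = 1e-3)
})

test_that("yield BLUEs recover true variety values", {
  sim <- small_panel(n_spring = 25, n_winter = 0, n_markers = 100, seed = 31)
  tr <- simulate_traits(sim$panel, list(trait_spec(1)), seed = 1)
  # noise-free balanced trials: BLUEs equal truth exactly
  tc0 <- trial_config(years = 2001:2002, locations_per_year = 2, error_sd = 0,
                      sd_management = 0, sd_my = 0, sd_myv = 0, sd_myl = 0)
  rec0 <- simulate_vcu_trials(sim$panel, tc0, tr$true_yield)
  b0 <- suppressMessages(yield_blues(rec0))
  expect_equal(setNames(b0$blues$blue, b0$blues$variety_id)[names(tr$true_yield)],
               tr$true_yield, tolerance = 1e-8)
  # noisy trials: rank correlation above 0.95
  tc <- trial_config(years = 2001:2004, locations_per_year = 3, error_sd = 0.3,
                     seed = 5)
  rec <- simulate_vcu_trials(sim$panel, tc, tr$true_yield)
  b <- suppressMessages(yield_blues(rec))
  est <- setNames(b$blues$blue, b$blues$variety_id)
  expect_gt(cor(est[names(tr$true_yield)], tr$true_yield,
                method = "spearman"), 0.95)
  # record order invariance
  b2 <- suppressMessages(yield_blues(rec[sample(nrow(rec)), ]))
  expect_equal(sort(b2$blues$blue), sort(b$blues$blue), tolerance = 1e-8)
  expect_error(yield_blues(rec[0, ]), "empty")
})
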