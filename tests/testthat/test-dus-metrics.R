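test_that("normalized distance equals 2*(1 - similarity) on inbred panels", {
  sim <- small_panel(n_spring = 20, n_winter = 15, n_markers = 200, seed = 3)
  d <- genomic_distance_matrix(sim$panel)$d
  geno <- sim$panel$geno
  # direct match-count oracle, all pairs, exact
  for (i in 1:10) {
    for (j in (i + 1):11) {
      sim_ij <- mean(geno[i, ] == geno[j, ])
      expect_equal(d[i, j], 2 * (1 - sim_ij), tolerance = 1e-12)
    }
  }
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  expect_identical(d, t(d))
})

test_that("toy distances match hand arithmetic", {
  geno <- named_matrix(c(0, 0, 0, 0,
                         2, 0, 0, 0), c("x", "y"), paste0("m", 1:4))
  d <- genomic_distance_matrix(toy_panel(geno))$d
  expect_equal(d["x", "y"], 0.5)  # one mismatch in four markers: 2 * 1/4
  # 2% mismatching markers -> distance 0.04 (the EDV-range example)
  g2 <- named_matrix(rep(0, 200), "x", paste0("m", 1:100))
  g2 <- rbind(x = rep(0, 100), y = c(rep(2, 2), rep(0, 98)))
  colnames(g2) <- paste0("m", 1:100)
  d2 <- genomic_distance_matrix(toy_panel(g2))$d
  expect_equal(d2["x", "y"], 0.04)
})

test_that("distinctness screening flags candidates below the threshold", {
  sim <- small_panel(n_spring = 25, n_winter = 0, n_markers = 100, seed = 5)
  ref <- sim$panel$geno
  # candidate identical to a reference variety
  cand <- ref[3, , drop = FALSE]
  rownames(cand) <- "copycat"
  scr <- distinctness_screen(cand, sim$panel)
  expect_equal(scr$min_distance, 0)
  expect_true(scr$edv_flag)
  expect_equal(scr$nearest, rownames(ref)[3])
  # candidate at distance 0.04: not distinct at the 0.05 default
  cand2 <- ref[3, , drop = FALSE]
  cand2[1, 1:2] <- 2 - cand2[1, 1:2]
  rownames(cand2) <- "near"
  scr2 <- distinctness_screen(cand2, sim$panel)
  expect_equal(scr2$min_distance, 0.04)
  expect_false(scr2$distinct)
  # threshold 0: every non-identical candidate is distinct
  scr3 <- distinctness_screen(cand2, sim$panel, threshold = 0)
  expect_true(scr3$distinct)
  # invariant decisions under reference permutation (up to tie-breaking)
  perm <- sample(nrow(ref))
  scr4 <- distinctness_screen(cand2, ref[perm, ])
  expect_equal(scr4$min_distance, scr2$min_distance)
  expect_equal(scr4$distinct, scr2$distinct)
  # differing marker sets are an error
  expect_error(distinctness_screen(cand2[, 1:50], sim$panel),
               "marker sets differ")
})

test_that("uniformity decisions compare within-lot spread to the ceiling", {
  m <- paste0("m", 1:100)
  clone <- named_matrix(rep(rep(0, 100), 5), paste0("s", 1:5), m)
  u0 <- uniformity_metric(clone, ceiling = 0.05)
  expect_equal(u0$max_within, 0)
  expect_true(u0$pass)
  # one off-type seed at distance 0.3 dominates the maximum
  off <- clone
  off[5, 1:15] <- 2
  u1 <- uniformity_metric(off, ceiling = 0.25)
  expect_equal(u1$max_within, 0.3)
  expect_false(u1$pass)
  expect_equal(unname(u1$het_per_seed), rep(0, 5))
  expect_error(uniformity_metric(clone[1, , drop = FALSE]), "at least 2")
  # ceiling derived from a reference panel
  sim <- small_panel(n_spring = 10, n_winter = 0, n_markers = 100, seed = 9)
  u2 <- uniformity_metric(off, reference = sim$panel)
  expect_false(is.null(u2$ceiling))
})

test_that("stability statistic is calibrated under pure drift and detects shifts", {
  set.seed(17)
  n_seed <- 60
  n_mark <- 400
  ne <- 80
  p0 <- runif(n_mark, 0.2, 0.8)
  draw_lot <- function(p) {
    g <- rbinom(n_seed * n_mark, 2, rep(p, each = n_seed))
    matrix(g, n_seed, n_mark,
           dimnames = list(paste0("s", 1:n_seed), paste0("m", 1:n_mark)))
  }
  lot1 <- draw_lot(p0)
  # identical lots: all shifts zero
  s0 <- stability_metric(lot1, lot1, effective_size = ne)
  expect_true(all(s0$per_marker$shift == 0))
  expect_equal(s0$n_flagged, 0)
  # pure Wright-Fisher drift for one generation, then resample seeds
  p_drift <- rbinom(n_mark, 2 * ne, p0) / (2 * ne)
  lot2 <- draw_lot(p_drift)
  s1 <- stability_metric(lot1, lot2, effective_size = ne, generations = 1)
  expect_gte(mean(abs(s1$per_marker$z) <= qnorm(0.975)), 0.93)
  # a deliberate frequency shift at one marker is flagged, others mostly not
  p_shift <- p0
  p_shift[1] <- min(p_shift[1] + 0.35, 0.99)
  lot3 <- draw_lot(p_shift)
  s2 <- stability_metric(lot1, lot3, effective_size = ne)
  expect_true(s2$per_marker$flag[1])
  expect_lt(mean(s2$per_marker$flag[-1]), 0.10)
  expect_error(stability_metric(lot1[0, ], lot1), "zero-depth")
})

test_that("marker subsampling correlation rises to 1 for marker-determined traits", {
  sim <- small_panel(n_spring = 30, n_winter = 25, n_markers = 300, seed = 21)
  geno <- sim$panel$geno
  # traits as (scaled) linear functions of the genome: at the full marker
  # set the two distance matrices measure the same thing
  set.seed(4)
  sc <- vapply(1:30, function(k) {
    v <- geno %*% rnorm(ncol(geno))
    as.numeric(cut(v, 9))
  }, numeric(nrow(geno)))
  dimnames(sc) <- list(rownames(geno), paste0("t", 1:30))
  tt <- toy_traits(sc)
  curve <- marker_subsample_curve(tt, sim$panel, seed = 2)
  full <- curve[curve$n_markers == ncol(geno) & curve$group == "all", ]
  expect_gt(full$correlation, 0.6)
  one <- curve[curve$n_markers == 1 & curve$group == "all", ]
  expect_lt(one$correlation, full$correlation)
  # grid follows the log10(0.1) rule up to the full marker count
  expect_equal(curve$n_markers[curve$group == "all"],
               unique(c(pmin(300, round(10^seq(0, log10(300), by = 0.1))), 300)))
})

test_that("high-heritability traits track marker distances more closely", {
  sim <- small_panel(n_spring = 40, n_winter = 35, n_markers = 300, seed = 23)
  specs <- list(trait_spec(1, target_h2 = 0.95, n_qtl = 20),
                trait_spec(2, target_h2 = 0.9, n_qtl = 20),
                trait_spec(3, target_h2 = 0.1, n_qtl = 20),
                trait_spec(4, target_h2 = 0.05, n_qtl = 20))
  tr <- simulate_traits(sim$panel, specs, seed = 11)
  h2 <- c(t1 = 0.95, t2 = 0.9, t3 = 0.1, t4 = 0.05)
  curve <- marker_subsample_curve(tr$traits, sim$panel, h2 = h2, seed = 3,
                                  replicates = 3)
  top <- curve[curve$n_markers == max(curve$n_markers), ]
  expect_gt(top$correlation[top$group == "high_h2"],
            top$correlation[top$group == "low_h2"])
})
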