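test_that("gametes of a fully homozygous parent copy its haplotype", {
  map <- make_genetic_map(50, 2, 80, seed = 1)
  p <- setNames(sample(c(0, 2), 50, replace = TRUE), map$marker)
  g <- simulate_gamete(p, map)
  expect_equal(g, unname(p) / 2, ignore_attr = TRUE)
  expect_error(simulate_gamete(p[-1], map), "different marker sets")
})

test_that("recombination fractions match the Haldane closed form", {
  # two markers 0 cM apart never recombine; 10 cM apart ~ 9.06%;
  # different chromosomes ~ 50%
  map <- data.frame(marker = c("a", "b", "c", "d"),
                    chrom = c("chr1", "chr1", "chr1", "chr2"),
                    cM = c(5, 5, 15, 0), bp = 1:4)
  r <- genomicDUS:::interval_switch_prob(map)
  expect_equal(r, c(0.5, 0, 0.5 * (1 - exp(-0.2)), 0.5))
  n <- 10000
  h1 <- matrix(0, n, 4)
  h2 <- matrix(1, n, 4)
  set.seed(2)
  g <- genomicDUS:::meiosis_cohort(h1, h2, r)
  expect_equal(mean(g[, 1] != g[, 2]), 0, tolerance = 1e-12)
  expect_equal(mean(g[, 2] != g[, 3]), (1 - exp(-0.2)) / 2, tolerance = 0.01)
  expect_equal(mean(g[, 3] != g[, 4]), 0.5, tolerance = 0.02)
})

test_that("crossing schemes reproduce the inbreeding recursions", {
  map <- make_genetic_map(150, 3, 100, seed = 5)
  p1 <- setNames(rep(0, 150), map$marker)
  p2 <- setNames(rep(2, 150), map$marker)
  f6 <- simulate_cross(p1, p2, "F6", n = 4000, map = map, seed = 3)
  # residual heterozygosity after 5 selfings: (1/2)^5 (absolute tolerance)
  expect_lt(abs(mean(f6$geno == 1) - 2^-5), 0.008)
  # allele frequency stays 1/2 under selfing
  expect_lt(abs(mean(f6$geno) / 2 - 0.5), 0.02)
  bc <- simulate_cross(p1, p2, "BC1S4", n = 4000, map = map, seed = 3)
  # donor (non-recurrent parent 2) allele frequency: 1/4
  expect_lt(abs(mean(bc$geno) / 2 - 0.25), 0.02)
  # determinism
  f6b <- simulate_cross(p1, p2, "F6", n = 4000, map = map, seed = 3)
  expect_identical(f6$geno, f6b$geno)
  # recurrent parent choice
  bc2 <- simulate_cross(p1, p2, cross_scheme("BC1S4", recurrent_parent = "second"),
                        n = 2000, map = map, seed = 4)
  expect_lt(abs(mean(bc2$geno) / 2 - 0.75), 0.02)
})

test_that("heterozygosity halves per extra selfing generation", {
  map <- make_genetic_map(100, 2, 100, seed = 8)
  p1 <- setNames(rep(0, 100), map$marker)
  p2 <- setNames(rep(2, 100), map$marker)
  ks <- 1:5
  het <- vapply(ks, function(k) {
    pr <- simulate_cross(p1, p2, cross_scheme("generic", n_self = k),
                         n = 3000, map = map, seed = 10 + k)
    mean(pr$geno == 1)
  }, numeric(1))
  slope <- coef(lm(log(het) ~ ks))[2]
  expect_equal(unname(slope), -log(2), tolerance = 0.05)
})

test_that("identical parents give a warning and trivially matching progeny", {
  map <- make_genetic_map(30, 1, 50, seed = 2)
  p <- setNames(rep(c(0, 2), 15), map$marker)
  expect_warning(pr <- simulate_cross(p, p, "F6", n = 50, map = map, seed = 1),
                 "identical parents")
  rep_ <- match_report(pr, list(p1 = p, p2 = p), n_bootstrap = 50, seed = 1)
  expect_true(all(rep_$per_target$match_pct == 100))
})

test_that("exact-match percentages agree with the selfing-chain enumeration oracle", {
  # k unlinked markers segregating between the parents; F6 progeny match a
  # parent iff fixed for that parent's allele at every such marker
  for (k in c(2, 4)) {
    map <- unlinked_map(k)
    p1 <- setNames(rep(0, k), map$marker)
    p2 <- setNames(rep(2, k), map$marker)
    pr <- simulate_cross(p1, p2, "F6", n = 8000, map = map, seed = 20 + k)
    rep_ <- match_report(pr, list(parent1 = p1), n_bootstrap = 100, seed = 1)
    p_fix <- selfing_dist(5)[1]  # P(fixed to one parent's allele)
    expect_lt(abs(rep_$per_target$match_pct / 100 - p_fix^k), 0.02)
    # bootstrap mean tracks the point estimate
    expect_equal(rep_$per_target$boot_mean_pct, rep_$per_target$match_pct,
                 tolerance = 1)
  }
})

test_that("match percentage is non-increasing in segregating subset size and uniqueness sums to n", {
  map <- make_genetic_map(60, 3, 100, seed = 31)
  set.seed(6)
  p1 <- setNames(sample(c(0, 2), 60, replace = TRUE), map$marker)
  p2 <- p1
  seg <- sample(60, 20)
  p2[seg] <- 2 - p2[seg]
  pr <- simulate_cross(p1, p2, "F6", n = 2000, map = map, seed = 9)
  nested <- list(map$marker[seg[1:2]], map$marker[seg[1:8]], map$marker[seg])
  pcts <- vapply(nested, function(sub) {
    match_report(pr, list(p = p1), marker_subset = sub,
                 n_bootstrap = 10, seed = 1)$per_target$match_pct
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
  # markers monomorphic between parents match both parents trivially
  mono <- setdiff(map$marker, map$marker[seg])[1:5]
  rep_m <- match_report(pr, list(p1 = p1, p2 = p2), marker_subset = mono,
                        n_bootstrap = 10, seed = 1)
  expect_true(all(rep_m$per_target$match_pct == 100))
  full <- match_report(pr, list(p1 = p1), n_bootstrap = 10, seed = 2)
  expect_equal(sum(full$uniqueness), 2000)
  expect_error(match_report(pr, list(p1 = p1), marker_subset = character(0)),
               "non-empty")
})

test_that("few segregating markers cannot separate progeny but many can", {
  map <- make_genetic_map(600, 7, 150, seed = 37)
  set.seed(12)
  p1 <- setNames(sample(c(0, 2), 600, replace = TRUE), map$marker)
  p2 <- p1
  seg <- sample(600, 180)
  p2[seg] <- 2 - p2[seg]
  pr <- simulate_cross(p1, p2, "F6", n = 500, map = map, seed = 13)
  # a small panel (8 segregating markers): many progeny collide with a
  # parent or with each other
  small <- map$marker[seg[1:8]]
  rep_s <- match_report(pr, list(p1 = p1, p2 = p2), marker_subset = small,
                        n_bootstrap = 50, seed = 2)
  expect_gt(max(rep_s$per_target$match_pct), 0)
  expect_lt(length(rep_s$uniqueness), 500)      # haplotype collisions
  # 500 genome-wide markers: essentially everyone is unique
  big <- sample(map$marker, 500)
  rep_b <- match_report(pr, list(p1 = p1, p2 = p2), marker_subset = big,
                        n_bootstrap = 50, seed = 2)
  expect_true(all(rep_b$per_target$match_pct == 0))
  expect_equal(length(rep_b$uniqueness), 500)   # all distinct
})
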