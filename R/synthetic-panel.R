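#' Configuration for the synthetic variety panel
#'
#' Defaults emulate the structure of the UK barley national-list collection
#' analysed throughout the package: 432 spring, 372 winter and 5 alternative
#' inbred varieties genotyped at ~40k biallelic SNPs on 7 chromosomes, with
#' the two seasonal subpopulations clearly diverged. Founder lines of each
#' seasonal type are drawn from type-specific allele frequencies under a
#' Balding-Nichols (F-model) divergence around a common ancestral frequency;
#' later varieties are F6 inbred lines bred by crossing earlier varieties of
#' the same type through the package's meiosis engine, which creates
#' realistic relatedness and linkage disequilibrium.
#'
#' @param n_spring,n_winter,n_alternative variety counts per seasonal type.
#' @param n_markers total SNP count.
#' @param n_chromosomes chromosome count (default 7, as in barley).
#' @param chrom_length_cM chromosome length(s) in cM (recycled).
#' @param founder_count founder lines per seasonal type.
#' @param pedigree_depth breeding generations after the founders.
#' @param between_type_divergence F-model divergence between seasonal types,
#'   strictly in (0, 1).
#' @param year_range calendar years over which listing dates are spread.
#' @param seed integer seed.
#' @return a list of class `PanelConfig`.
#' @export
panel_config <- function(n_spring = 432, n_winter = 372, n_alternative = 5,
                         n_markers = 40000, n_chromosomes = 7,
                         chrom_length_cM = 150,
                         founder_count = 40, pedigree_depth = 3,
                         between_type_divergence = 0.35,
                         year_range = c(1960, 2020), seed = 1) {
  stopifnot(n_spring >= 0, n_winter >= 0, n_alternative >= 0,
            n_markers >= n_chromosomes, founder_count >= 1,
            pedigree_depth >= 0)
  if (between_type_divergence < 0 || between_type_divergence >= 1) {
    stop("between_type_divergence must be in [0, 1); 0 collapses the types into one population")
  }
  structure(as.list(environment()), class = "PanelConfig")
}

#' Simulate an inbred two-season variety panel
#'
#' See [panel_config()] for the population model. The output dosage matrix
#' contains only \{0, 2\} (fully inbred lines); the pedigree records parent
#' pairs for every non-founder variety; listing years and AFP-like
#' submission order follow breeding generation.
#'
#' @param config a [panel_config()].
#' @return list with elements `panel` (a [genotype_panel()]), `pedigree`
#'   (data.frame `variety_id`, `parent1_id`, `parent2_id`) and `map`.
#' @export
simulate_panel <- function(config = panel_config()) {
  n_total <- config$n_spring + config$n_winter + config$n_alternative
  if (n_total == 0) stop("degenerate config: no varieties requested")
  if (config$n_markers == 0) stop("degenerate config: no markers requested")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  map <- make_genetic_map(config$n_markers, config$n_chromosomes,
                          config$chrom_length_cM)
  m <- nrow(map)
  f <- config$between_type_divergence
  p0 <- stats::runif(m, 0.1, 0.9)
  type_freq <- function() {
    if (f <= 0) return(p0)  # degenerate: one population
    a <- p0 * (1 - f) / f
    b <- (1 - p0) * (1 - f) / f
    stats::rbeta(m, a, b)
  }
  counts <- c(spring = config$n_spring, winter = config$n_winter,
              alternative = config$n_alternative)
  r <- interval_switch_prob(map)
  hap_list <- list()
  info_list <- list()
  ped_list <- list()
  for (ty in names(counts)) {
    n_ty <- counts[[ty]]
    if (n_ty == 0) next
    p_ty <- type_freq()
    nf <- min(config$founder_count, n_ty)
    founders <- matrix(stats::runif(nf * m) < rep(p_ty, each = nf), nf, m) * 1
    ids <- sprintf("%s%04d", toupper(substr(ty, 1, 1)), seq_len(n_ty))
    rownames(founders) <- ids[seq_len(nf)]
    haps <- founders
    ped <- data.frame(variety_id = ids[seq_len(nf)],
                      parent1_id = NA_character_, parent2_id = NA_character_,
                      generation = 0L)
    n_rest <- n_ty - nf
    if (n_rest > 0 && config$pedigree_depth > 0) {
      per_gen <- diff(floor(seq(0, n_rest, length.out = config$pedigree_depth + 1)))
      done <- nf
      for (g in seq_len(config$pedigree_depth)) {
        k <- per_gen[g]
        if (k == 0) next
        i1 <- sample.int(done, k, replace = TRUE)
        i2 <- vapply(i1, function(i) {
          j <- sample.int(done, 1)
          while (j == i && done > 1) j <- sample.int(done, 1)
          j
        }, integer(1))
        # batched F6 single-seed descent from the F1 of each parent pair
        h1 <- haps[i1, , drop = FALSE]
        h2 <- haps[i2, , drop = FALSE]
        for (s in 1:5) {
          g1 <- meiosis_cohort(h1, h2, r)
          g2 <- meiosis_cohort(h1, h2, r)
          h1 <- g1; h2 <- g2
        }
        # derive the inbred line from one final selfing meiosis (doubled):
        # residual F6 heterozygosity is resolved to homozygosity so released
        # varieties are fully inbred
        newhap <- meiosis_cohort(h1, h2, r)
        new_ids <- ids[done + seq_len(k)]
        rownames(newhap) <- new_ids
        ped <- rbind(ped, data.frame(variety_id = new_ids,
                                     parent1_id = rownames(haps)[i1],
                                     parent2_id = rownames(haps)[i2],
                                     generation = g))
        haps <- rbind(haps, newhap)
        done <- done + k
      }
    } else if (n_rest > 0) {
      extra <- matrix(stats::runif(n_rest * m) < rep(p_ty, each = n_rest),
                      n_rest, m) * 1
      rownames(extra) <- ids[nf + seq_len(n_rest)]
      haps <- rbind(haps, extra)
      ped <- rbind(ped, data.frame(variety_id = rownames(extra),
                                   parent1_id = NA_character_,
                                   parent2_id = NA_character_,
                                   generation = 0L))
    }
    hap_list[[ty]] <- haps
    ped$seasonal_type <- ty
    ped_list[[ty]] <- ped
  }
  ped <- do.call(rbind, ped_list)
  haps <- do.call(rbind, hap_list)
  rownames(ped) <- NULL
  # AFP-like submission order: by breeding generation, randomized within,
  # types interleaved; listing years spread over the configured range
  ord <- order(ped$generation, stats::runif(nrow(ped)))
  ped <- ped[ord, ]
  haps <- haps[ped$variety_id, , drop = FALSE]
  yrs <- round(seq(config$year_range[1], config$year_range[2],
                   length.out = nrow(ped)))
  info <- data.frame(variety_id = ped$variety_id,
                     seasonal_type = ped$seasonal_type,
                     listing_year = yrs,
                     afp_order = seq_len(nrow(ped)))
  geno <- 2 * haps
  colnames(geno) <- as.character(map$marker)
  panel <- genotype_panel(geno, map, info)
  pedigree <- ped[, c("variety_id", "parent1_id", "parent2_id")]
  rownames(pedigree) <- NULL
  list(panel = panel, pedigree = pedigree, map = map)
}

#' Trait specification for the synthetic ordinal DUS traits
#'
#' @param trait_id integer 1..28.
#' @param scale admissible ordinal levels; binary traits use exactly
#'   \{1, 9\}.
#' @param target_h2 narrow-sense heritability of the latent liability.
#' @param n_qtl number of causal markers.
#' @param yield_rho_g target genetic correlation of this trait with yield.
#' @param missing_rate completely-at-random missingness rate.
#' @param segregating_in `"both"`, `"spring"` or `"winter"`; a trait
#'   segregating in only one seasonal type is constant in the other.
#' @return a list of class `TraitSpec`.
#' @export
trait_spec <- function(trait_id, scale = 1:9, target_h2 = 0.5, n_qtl = 3,
                       yield_rho_g = 0, missing_rate = 0,
                       segregating_in = c("both", "spring", "winter")) {
  segregating_in <- match.arg(segregating_in)
  stopifnot(target_h2 >= 0, target_h2 <= 1,
            yield_rho_g >= -1, yield_rho_g <= 1,
            missing_rate >= 0, missing_rate <= 1, n_qtl >= 1)
  if (length(scale) < 2) stop("trait scale needs at least two levels")
  if (!all(scale %in% 1:9)) stop("unknown trait scale: levels must be in 1..9")
  if (setequal(scale, c(1, 9)) && length(scale) != 2) {
    stop("binary traits use exactly levels {1, 9}")
  }
  structure(list(trait_id = as.integer(trait_id), scale = sort(scale),
                 target_h2 = target_h2, n_qtl = as.integer(n_qtl),
                 yield_rho_g = yield_rho_g, missing_rate = missing_rate,
                 segregating_in = segregating_in),
            class = "TraitSpec")
}

#' Default specifications for the 28 barley DUS traits
#'
#' Heritability targets follow the published combined-panel estimates for
#' the 28 UK barley DUS traits (e.g. ear row number ~1.00, flag-leaf
#' glaucosity ~0.12). Traits 3, 23 and 26 are binary (scored 1 or 9);
#' traits 3 and 12 segregate only in winter material and trait 27 only in
#' spring, giving two spring-invariant traits and one winter-invariant
#' trait. Twelve traits carry a non-zero genetic correlation with yield,
#' including negative correlations for ear attitude (10) and plant length
#' (11). Five traits have missingness above 10% (maximum 78%).
#'
#' @return list of 28 [trait_spec()] objects named `t1`..`t28`.
#' @export
default_trait_specs <- function() {
  h2 <- c(0.78, 0.25, 0.75, 0.74, 0.28, 0.12, 0.28, 0.67, 0.42, 0.25,
          0.17, 1.00, 0.10, 0.23, 0.18, 0.18, 0.34, 0.26, 1.00, 0.64,
          0.15, 1.00, 0.01, 0.69, 0.74, 0.96, 0.91, 1.00)
  binary <- c(3, 23, 26)
  seg <- rep("both", 28)
  seg[c(3, 12)] <- "winter"
  seg[27] <- "spring"
  rho <- numeric(28)
  rho[c(2, 7, 9, 14, 15, 17, 21, 25)] <- c(0.2, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2)
  rho[c(10, 11, 16, 18)] <- c(-0.3, -0.4, -0.2, -0.2)
  miss <- rep(0.02, 28)
  miss[5] <- 0.78
  miss[c(13, 16, 18, 21)] <- c(0.15, 0.12, 0.20, 0.30)
  lapply(1:28, function(i) {
    trait_spec(i,
               scale = if (i %in% binary) c(1, 9) else 1:9,
               target_h2 = h2[i],
               n_qtl = if (h2[i] >= 0.9) 1 else 3,
               yield_rho_g = rho[i],
               missing_rate = miss[i],
               segregating_in = seg[i])
  }) -> specs
  stats::setNames(specs, paste0("t", 1:28))
}

#' Simulate ordinal DUS trait scores on a panel
#'
#' Each trait's latent liability is `sqrt(h2) * g + sqrt(1 - h2) * e` where
#' `g` is a standardized genetic value from `n_qtl` causal markers and `e`
#' is standard normal noise, so the liability's narrow-sense heritability is
#' the target by construction. The liability is discretized onto the trait's
#' ordinal scale through fixed equal-probability normal quantile thresholds,
#' which preserves the heritability interpretation on the liability scale.
#' Missingness is injected completely at random.
#'
#' A synthetic yield breeding value is also returned, constructed as a
#' weighted sum of the trait genetic values (weights = `yield_rho_g`) plus
#' an independent polygenic component, so traits attain approximately their
#' target genetic correlation with yield.
#'
#' @param panel a `GenotypePanel`.
#' @param specs list of [trait_spec()]s with distinct `trait_id`s; default
#'   [default_trait_specs()].
#' @param seed integer seed.
#' @return list: `traits` (a [trait_table()]), `true_values` (matrix of
#'   latent genetic values, varieties x traits), `latent` (matrix of the
#'   continuous liabilities before discretization), `true_yield` (named
#'   vector of yield breeding values), `qtl` (list of causal marker ids per
#'   trait).
#' @export
simulate_traits <- function(panel, specs = default_trait_specs(), seed = 1) {
  ids <- vapply(specs, function(s) s$trait_id, integer(1))
  if (anyDuplicated(ids)) stop("specs cover duplicated trait_ids")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  geno <- panel$geno
  n <- nrow(geno)
  type <- panel$info$seasonal_type
  scores <- matrix(NA_real_, n, length(specs),
                   dimnames = list(rownames(geno), paste0("t", ids)))
  gvals <- matrix(0, n, length(specs), dimnames = dimnames(scores))
  latent <- matrix(0, n, length(specs), dimnames = dimnames(scores))
  scale_list <- list()
  qtl_list <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    tr <- paste0("t", sp$trait_id)
    scale_list[[tr]] <- sp$scale
    active <- switch(sp$segregating_in,
                     both = rep(TRUE, n),
                     spring = type == "spring",
                     winter = type == "winter")
    sub <- geno[active, , drop = FALSE]
    pseg <- colMeans(sub) / 2
    seg <- which(pseg > 0.05 & pseg < 0.95)
    if (length(seg) < sp$n_qtl) seg <- order(pmin(pseg, 1 - pseg),
                                             decreasing = TRUE)[seq_len(sp$n_qtl)]
    qtl <- sample(seg, sp$n_qtl)
    qtl_list[[tr]] <- colnames(geno)[qtl]
    eff <- stats::rnorm(sp$n_qtl)
    g <- drop(geno[, qtl, drop = FALSE] %*% eff)
    gs <- g[active]
    if (stats::sd(gs) > 0) {
      g <- (g - mean(gs)) / stats::sd(gs)
    } else {
      g <- g - mean(gs)
    }
    h2 <- sp$target_h2
    liab <- sqrt(h2) * g + sqrt(1 - h2) * stats::rnorm(n)
    gvals[, k] <- sqrt(h2) * g
    latent[, k] <- liab
    lv <- sp$scale
    if (h2 == 1 && length(unique(liab[active])) < length(lv)) {
      # fully genetic trait with few genotype classes: map classes to levels
      cls <- as.integer(factor(liab))
      scores[, k] <- lv[pmin(cls, length(lv))]
    } else {
      thr <- stats::qnorm(seq_len(length(lv) - 1) / length(lv))
      scores[, k] <- lv[findInterval(liab, thr) + 1L]
    }
    if (sp$segregating_in != "both") {
      scores[!active, k] <- lv[1]
      gvals[!active, k] <- 0
    }
    if (sp$missing_rate > 0) {
      drop_idx <- stats::runif(n) < sp$missing_rate
      scores[drop_idx, k] <- NA_real_
    }
  }
  # yield breeding values with target genetic correlations to the traits
  rho <- vapply(specs, function(s) s$yield_rho_g, numeric(1))
  gstd <- apply(gvals, 2, function(v) {
    if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
  })
  resid_var <- max(0, 1 - sum(rho^2))
  poly_qtl <- sample(ncol(geno), 50)
  poly <- drop(geno[, poly_qtl, drop = FALSE] %*% stats::rnorm(50))
  poly <- (poly - mean(poly)) / stats::sd(poly)
  true_yield <- drop(gstd %*% rho) + sqrt(resid_var) * poly
  names(true_yield) <- rownames(geno)
  list(traits = trait_table(scores, scale_list),
       true_values = gvals,
       latent = latent,
       true_yield = true_yield,
       qtl = qtl_list)
}

#' Simulate dual-site (two scoring organizations) trait scores
#'
#' Site A returns the input scores unchanged; site B adds a per-trait
#' systematic bias plus rounded Gaussian noise, clipped to each trait's
#' scale — emulating the same varieties being scored in two environments by
#' two organizations (e.g. one site scoring flag-leaf glaucosity about one
#' point higher than the other).
#'
#' @param traits a `TraitTable`.
#' @param site_bias numeric, per-trait bias added at site B (recycled).
#' @param noise_sd numeric, per-trait Gaussian noise SD at site B (recycled).
#' @param seed integer seed.
#' @return list with `site_a` and `site_b` trait tables over the same
#'   varieties.
#' @export
simulate_dual_site_scores <- function(traits, site_bias = 0, noise_sd = 0,
                                      seed = 1) {
  stopifnot(inherits(traits, "TraitTable"))
  if (!all(is.finite(site_bias)) || !all(is.finite(noise_sd))) {
    stop("bias and noise must be finite")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  sc <- traits$scores
  bias <- rep_len(site_bias, ncol(sc))
  nsd <- rep_len(noise_sd, ncol(sc))
  b <- sc
  for (k in seq_len(ncol(sc))) {
    lv <- traits$scale[[colnames(sc)[k]]]
    noise <- round(stats::rnorm(nrow(sc), 0, nsd[k]))
    v <- sc[, k] + bias[k] + noise
    # clip to the nearest admissible level
    v <- vapply(v, function(x) if (is.na(x)) NA_real_ else lv[which.min(abs(lv - x))],
                numeric(1))
    b[, k] <- v
  }
  list(site_a = trait_table(sc, traits$scale),
       site_b = trait_table(b, traits$scale))
}

#' Configuration for synthetic multi-environment yield trials
#'
#' @param years integer vector of trial years.
#' @param locations_per_year number of locations per year.
#' @param management_switch_year varieties listed in or after this year get
#'   management covariate 1, earlier varieties 0 (emulating the switch to
#'   fungicide-treated trials).
#' @param error_sd residual SD of a plot record.
#' @param sd_management,sd_my,sd_myv,sd_myl SDs of the random management,
#'   management:year, management:year:variety and management:year:location
#'   effects.
#' @param seed integer seed.
#' @return list of class `TrialConfig`.
#' @export
trial_config <- function(years = 2001:2006, locations_per_year = 4,
                         management_switch_year = 2004, error_sd = 0.5,
                         sd_management = 0.2, sd_my = 0.2, sd_myv = 0.1,
                         sd_myl = 0.2, seed = 1) {
  if (length(years) < 1 || locations_per_year < 1) {
    stop("empty trial design: need at least one year and one location")
  }
  structure(as.list(environment()), class = "TrialConfig")
}

#' Simulate multi-environment yield trial records
#'
#' Every variety is observed in every year x location cell (balanced
#' design). Yield = true variety value + management + management:year +
#' management:year:variety + management:year:location random effects +
#' residual, mirroring the random structure used to compute yield BLUEs.
#'
#' @param panel a `GenotypePanel` (supplies variety ids and listing years).
#' @param config a [trial_config()].
#' @param true_yield named vector of true variety yield values.
#' @return data.frame with columns `variety_id`, `year`, `location`,
#'   `management`, `yield`.
#' @export
simulate_vcu_trials <- function(panel, config = trial_config(), true_yield) {
  ids <- panel$info$variety_id
  if (!all(ids %in% names(true_yield))) {
    stop("true_yield must cover every panel variety")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  mgmt <- as.integer(panel$info$listing_year >= config$management_switch_year)
  names(mgmt) <- ids
  grid <- expand.grid(variety_id = ids, year = config$years,
                      location = paste0("loc", seq_len(config$locations_per_year)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$management <- mgmt[grid$variety_id]
  eff <- function(keys, sd) {
    u <- stats::rnorm(length(unique(keys)), 0, sd)
    names(u) <- unique(keys)
    u[keys]
  }
  e_m <- eff(as.character(grid$management), config$sd_management)
  e_my <- eff(paste(grid$management, grid$year), config$sd_my)
  e_myv <- eff(paste(grid$management, grid$year, grid$variety_id), config$sd_myv)
  e_myl <- eff(paste(grid$management, grid$year, grid$location), config$sd_myl)
  grid$yield <- true_yield[grid$variety_id] + e_m + e_my + e_myv + e_myl +
    stats::rnorm(nrow(grid), 0, config$error_sd)
  rownames(grid) <- NULL
  grid
}
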