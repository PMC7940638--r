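#' Configuration for a full synthetic-study pipeline run
#'
#' Bundles the study constants (distinctness threshold 0.05, FDR 0.05,
#' conditional re-scan trigger at -log10 p of 10, heritability split at
#' 0.5, 20-variety rolling window, 1000 bootstraps) with per-stage seeds
#' and the panel scale.
#'
#' @param panel a [panel_config()] describing the synthetic panel stage.
#' @param stages character vector of stages to run, in dependency order.
#' @param traits_for_reml trait columns analysed in the heritability stage
#'   (default: all simulated traits).
#' @param gwas_traits trait columns scanned in the gwas stage.
#' @param distinctness_threshold,fdr_level,rescan_trigger,h2_split,rolling_window,n_bootstrap,n_progeny study constants.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return a list of class `RunConfig`.
#' @export
pipeline_config <- function(panel = panel_config(n_spring = 120, n_winter = 100,
                                                 n_alternative = 2,
                                                 n_markers = 2000,
                                                 founder_count = 25,
                                                 seed = 101),
                            stages = c("simulate", "concordance",
                                       "heritability", "gwas", "progeny",
                                       "dus"),
                            traits_for_reml = NULL,
                            gwas_traits = c("t12", "t19"),
                            distinctness_threshold = 0.05,
                            fdr_level = 0.05,
                            rescan_trigger = 10,
                            h2_split = 0.5,
                            rolling_window = 20,
                            n_bootstrap = 1000,
                            n_progeny = 1000,
                            seed = 1) {
  stopifnot(distinctness_threshold > 0, fdr_level > 0, rescan_trigger > 0,
            rolling_window > 1, n_bootstrap > 0, n_progeny > 0)
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the synthetic genomic-DUS study end to end
#'
#' Executes the configured stages in dependency order, writing every stage
#' output as a delimited file under `out_dir` together with a manifest
#' (stage, seed, output file, row count, config hash) that suffices to
#' replay the run. A failed stage halts the pipeline with a stage-scoped
#' error; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest` (data.frame) and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("dusrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  manifest <- list()
  results <- list()
  cfg_hash <- config_hash(config)
  note <- function(stage, file, n) {
    manifest[[length(manifest) + 1]] <<-
      data.frame(stage = stage, file = file, rows = n,
                 seed = config$seed, config_hash = cfg_hash)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stage_seed <- function(k) (config$seed * 131L + k) %% .Machine$integer.max

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      pcfg <- config$panel
      pcfg$seed <- stage_seed(1)
      sim <- simulate_panel(pcfg)
      tr <- simulate_traits(sim$panel, seed = stage_seed(2))
      write_genotypes(sim$panel, file.path(out_dir, "panel.tsv"))
      write_trait_table(tr$traits, file.path(out_dir, "traits.tsv"))
      write_table_logged(sim$pedigree, file.path(out_dir, "pedigree.tsv"))
      results$sim <- sim
      results$traits <- tr
      note("simulate", "panel.tsv", n_varieties(sim$panel))
      note("simulate", "traits.tsv", nrow(tr$traits$scores))
    })
  }
  if ("concordance" %in% config$stages) {
    run_stage("concordance", {
      sites <- simulate_dual_site_scores(results$traits$traits,
                                         site_bias = c(rep(0, 5), 1, rep(0, 22)),
                                         noise_sd = 0.5, seed = stage_seed(3))
      a <- recode_binary_traits(sites$site_a)
      b <- recode_binary_traits(sites$site_b)
      disc <- per_variety_discrepancy(a, b)
      bias <- per_trait_bias(a, b)
      write_table_logged(disc$per_variety, file.path(out_dir, "discrepancy.tsv"))
      write_table_logged(bias, file.path(out_dir, "trait_bias.tsv"))
      spring <- results$sim$panel$info$seasonal_type == "spring"
      ssc <- a$scores[results$sim$panel$info$variety_id[spring], , drop = FALSE]
      roll <- rolling_trait_distance(
        trait_table(ssc, a$scale),
        order = stats::setNames(results$sim$panel$info$afp_order[spring],
                                rownames(ssc)),
        window = min(config$rolling_window, nrow(ssc) - 1))
      write_table_logged(roll, file.path(out_dir, "rolling_distance.tsv"))
      results$concordance <- disc
      note("concordance", "discrepancy.tsv", nrow(disc$per_variety))
      note("concordance", "rolling_distance.tsv", nrow(roll))
    })
  }
  if ("heritability" %in% config$stages) {
    run_stage("heritability", {
      panel <- results$sim$panel
      a <- compute_grm(panel)
      x <- dus_fixed_design(panel$info)
      trs <- config$traits_for_reml %||% colnames(results$traits$traits$scores)
      h2tab <- do.call(rbind, lapply(trs, function(tr) {
        y <- stats::setNames(results$traits$traits$scores[, tr],
                             rownames(results$traits$traits$scores))
        fit <- tryCatch(reml_univariate(y, x, a), error = function(e) NULL)
        if (is.null(fit)) return(data.frame(trait = tr, h2 = NA, se_h2 = NA,
                                            n = NA, status = "failed"))
        data.frame(trait = tr, h2 = fit$h2, se_h2 = fit$se_h2, n = fit$n,
                   status = fit$status)
      }))
      write_table_logged(h2tab, file.path(out_dir, "heritability.tsv"))
      results$h2 <- h2tab
      results$grm <- a
      note("heritability", "heritability.tsv", nrow(h2tab))
    })
  }
  if ("gwas" %in% config$stages) {
    run_stage("gwas", {
      panel <- results$sim$panel
      x <- dus_fixed_design(panel$info)
      for (tr in config$gwas_traits) {
        y <- stats::setNames(results$traits$traits$scores[, tr],
                             rownames(results$traits$traits$scores))
        res <- run_gwas(y, x, panel, A = results$grm)
        res2 <- conditional_rescan(res, y, x, panel, A = results$grm,
                                   trigger = config$rescan_trigger)
        fn <- paste0("gwas_", tr, ".tsv")
        write_table_logged(as.data.frame(res), file.path(out_dir, fn))
        results$gwas[[tr]] <- res2
        note("gwas", fn, nrow(res))
      }
    })
  }
  if ("progeny" %in% config$stages) {
    run_stage("progeny", {
      panel <- results$sim$panel
      ped <- results$sim$pedigree
      ok <- !is.na(ped$parent1_id) & !is.na(ped$parent2_id)
      pick <- ped[ok, ][1, ]
      p1 <- panel$geno[pick$parent1_id, ]
      p2 <- panel$geno[pick$parent2_id, ]
      prog <- simulate_cross(p1, p2, "F6", n = config$n_progeny,
                             map = panel$map, seed = stage_seed(4))
      rep_ <- match_report(prog,
                           list(parent1 = p1, parent2 = p2,
                                sibling = panel$geno[pick$variety_id, ]),
                           marker_subset = sample(colnames(panel$geno),
                                                  min(39, ncol(panel$geno))),
                           n_bootstrap = config$n_bootstrap,
                           seed = stage_seed(5))
      write_table_logged(rep_$per_target, file.path(out_dir, "match_report.tsv"))
      results$match <- rep_
      note("progeny", "match_report.tsv", nrow(rep_$per_target))
    })
  }
  if ("dus" %in% config$stages) {
    run_stage("dus", {
      panel <- results$sim$panel
      dr <- genomic_distance_matrix(panel)
      early <- panel$info$afp_order <= floor(n_varieties(panel) / 2)
      screen <- distinctness_screen(panel$geno[!early, , drop = FALSE],
                                    panel$geno[early, , drop = FALSE],
                                    threshold = config$distinctness_threshold)
      write_table_logged(as.data.frame(screen), file.path(out_dir, "distinctness.tsv"))
      write_table_logged(dr$partition, file.path(out_dir, "distance_partition.tsv"))
      h2v <- stats::setNames(results$h2$h2, results$h2$trait)
      curve <- marker_subsample_curve(results$traits$traits, panel, h2 = h2v,
                                      seed = stage_seed(6))
      write_table_logged(curve, file.path(out_dir, "marker_curve.tsv"))
      results$dus <- list(distance = dr, screen = screen, curve = curve)
      note("dus", "distinctness.tsv", nrow(screen))
      note("dus", "marker_curve.tsv", nrow(curve))
    })
  }
  manifest <- do.call(rbind, manifest)
  write_table_logged(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}

config_hash <- function(config) {
  flat <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small deterministic string hash (djb2); enough to fingerprint a config
  h <- 5381
  for (ch in utf8ToInt(flat)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
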