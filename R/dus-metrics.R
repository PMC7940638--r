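#' Normalized genomic distance matrix with seasonal-type partition summary
#'
#' The per-marker-normalized Manhattan distance: mean absolute dosage
#' difference over markers. For fully inbred \{0, 2\} panels every
#' mismatching marker contributes 2, so the distance equals
#' `2 * (1 - similarity)` where similarity is the proportion of exactly
#' matching markers; distances live in [0, 2]. Partition summaries report
#' the within-spring, within-winter and between-type distance ranges.
#'
#' @param panel a `GenotypePanel` (no missing dosages).
#' @param normalize divide by the marker count (default `TRUE`); with
#'   `FALSE` the raw Manhattan sum (as returned by `dist`) is reported.
#' @return object of class `DistanceReport`: `d` (symmetric matrix),
#'   `partition` data.frame of min/median/max per partition, `n_varieties`,
#'   `n_pairs`.
#' @export
genomic_distance_matrix <- function(panel, normalize = TRUE) {
  geno <- if (inherits(panel, "GenotypePanel")) panel$geno else as.matrix(panel)
  if (nrow(geno) < 2) stop("need at least 2 varieties")
  if (any(is.na(geno))) stop("no missing dosages allowed")
  d <- as.matrix(stats::dist(geno, method = "manhattan"))
  if (normalize) d <- d / ncol(geno)
  partition <- NULL
  if (inherits(panel, "GenotypePanel")) {
    ty <- panel$info$seasonal_type
    pick <- function(rows, cols, label) {
      sub <- d[rows, cols, drop = FALSE]
      vals <- if (identical(rows, cols)) sub[upper.tri(sub)] else as.vector(sub)
      if (!length(vals)) return(NULL)
      data.frame(partition = label, min = min(vals),
                 median = stats::median(vals), max = max(vals),
                 n_pairs = length(vals))
    }
    partition <- rbind(pick(ty == "spring", ty == "spring", "within_spring"),
                       pick(ty == "winter", ty == "winter", "within_winter"),
                       pick(ty == "spring", ty == "winter", "between_type"))
  }
  structure(list(d = d, partition = partition,
                 n_varieties = nrow(geno),
                 n_pairs = choose(nrow(geno), 2)),
            class = "DistanceReport")
}

#' @export
print.DistanceReport <- function(x, ...) {
  cat(sprintf("DistanceReport: %d varieties, %d pairwise comparisons\n",
              x$n_varieties, x$n_pairs))
  if (!is.null(x$partition)) print(x$partition, row.names = FALSE)
  invisible(x)
}

# normalized Manhattan distances of candidate rows against reference rows
cross_distance <- function(cand, ref) {
  m <- ncol(ref)
  out <- matrix(0, nrow(cand), nrow(ref),
                dimnames = list(rownames(cand), rownames(ref)))
  for (i in seq_len(nrow(cand))) {
    out[i, ] <- colMeans(abs(t(ref) - cand[i, ]))
  }
  out
}

#' Distinctness / EDV screen of candidate varieties
#'
#' Computes each candidate's minimum normalized genomic distance to the
#' common-knowledge reference panel. A candidate is distinct iff that
#' minimum is at least the threshold; otherwise it is flagged as a
#' potential essentially derived variety (EDV). Nearest-neighbour ties are
#' broken by reference panel order (first listed wins) and reported.
#'
#' @param candidates dosage matrix (rows = candidates) or `ProgenySet`,
#'   sharing the reference marker set.
#' @param reference a `GenotypePanel` or dosage matrix.
#' @param threshold minimum distance for distinctness (default 0.05).
#' @return data.frame of class `DusDecision`: `candidate`, `min_distance`,
#'   `nearest`, `tie`, `distinct`, `edv_flag`, `threshold`.
#' @export
distinctness_screen <- function(candidates, reference, threshold = 0.05) {
  cand <- if (inherits(candidates, "ProgenySet")) candidates$geno else as.matrix(candidates)
  ref <- if (inherits(reference, "GenotypePanel")) reference$geno else as.matrix(reference)
  if (is.null(colnames(cand)) || is.null(colnames(ref)) ||
      !identical(colnames(cand), colnames(ref))) {
    miss <- union(setdiff(colnames(cand), colnames(ref)),
                  setdiff(colnames(ref), colnames(cand)))
    stop("candidate and reference marker sets differ",
         if (length(miss)) paste0(": ", paste(utils::head(miss, 5), collapse = ", ")))
  }
  d <- cross_distance(cand, ref)
  mind <- apply(d, 1, min)
  nearest <- apply(d, 1, which.min)  # which.min = first on ties
  tie <- vapply(seq_len(nrow(d)), function(i) sum(d[i, ] == mind[i]) > 1,
                logical(1))
  if (any(tie)) message(sum(tie), " candidate(s) with tied nearest neighbours; first in reference order kept")
  out <- data.frame(candidate = rownames(cand) %||% paste0("cand", seq_len(nrow(cand))),
                    min_distance = unname(mind),
                    nearest = rownames(ref)[nearest] %||% nearest,
                    tie = tie,
                    distinct = unname(mind) >= threshold,
                    threshold = threshold)
  out$edv_flag <- !out$distinct
  rownames(out) <- NULL
  class(out) <- c("DusDecision", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed-lot uniformity metric
#'
#' Uniformity of a candidate's seed lot is judged from the normalized
#' genomic distances among its seeds: the lot passes when its maximum
#' within-lot distance does not exceed the ceiling — by default the
#' candidate's minimum distance to the common-knowledge reference panel
#' (the seeds of a variety must be closer to one another than the variety
#' is to any other variety). Per-seed heterozygosity is reported alongside.
#'
#' @param seed_lot dosage matrix of individual seeds (heterozygotes
#'   allowed, dosage 1).
#' @param ceiling distance ceiling; computed from `reference` when `NULL`.
#' @param reference optional reference panel used to derive the ceiling
#'   (min distance of the lot's consensus to the panel).
#' @return object of class `LotMetrics`: `max_within`, `mean_within`,
#'   `het_per_seed`, `ceiling`, `pass`.
#' @export
uniformity_metric <- function(seed_lot, ceiling = NULL, reference = NULL) {
  lot <- as.matrix(seed_lot)
  if (nrow(lot) < 2) stop("need at least 2 seeds for a uniformity test")
  d <- as.matrix(stats::dist(lot, method = "manhattan")) / ncol(lot)
  within <- d[upper.tri(d)]
  if (is.null(ceiling) && !is.null(reference)) {
    ref <- if (inherits(reference, "GenotypePanel")) reference$geno else as.matrix(reference)
    consensus <- round(colMeans(lot))
    ceiling <- min(cross_distance(matrix(consensus, 1,
                                         dimnames = list("consensus", colnames(lot))),
                                  ref))
  }
  structure(list(max_within = max(within),
                 mean_within = mean(within),
                 het_per_seed = rowMeans(lot == 1),
                 ceiling = ceiling,
                 pass = if (is.null(ceiling)) NA else max(within) <= ceiling),
            class = "LotMetrics")
}

#' Seed-lot stability metric with drift-referenced test
#'
#' Compares allele frequencies between the initial (DUS application) and
#' final (commercial) seed lots of a variety. The per-marker shift is
#' standardized by its null variance under binomial sampling of both lots
#' plus Wright-Fisher drift over the stated number of multiplication
#' generations at the stated effective size, giving a z-like statistic per
#' marker; markers with |z| above the normal 97.5% quantile are flagged.
#'
#' @param lot_initial,lot_final dosage matrices on a shared marker set.
#' @param effective_size effective population size of seed multiplication.
#' @param generations multiplication generations between the lots.
#' @return object of class `LotMetrics`: `per_marker` data.frame (`marker`,
#'   `p_initial`, `p_final`, `shift`, `z`, `flag`), `het_change`,
#'   `n_flagged`.
#' @export
stability_metric <- function(lot_initial, lot_final, effective_size = 100,
                             generations = 1) {
  a <- as.matrix(lot_initial)
  b <- as.matrix(lot_final)
  if (nrow(a) == 0 || nrow(b) == 0) stop("zero-depth seed lots")
  if (!identical(colnames(a), colnames(b))) {
    stop("lots must be genotyped on the same marker set")
  }
  p1 <- colMeans(a) / 2
  p2 <- colMeans(b) / 2
  pbar <- (p1 + p2) / 2
  v_samp <- pbar * (1 - pbar) * (1 / (2 * nrow(a)) + 1 / (2 * nrow(b)))
  v_drift <- pbar * (1 - pbar) *
    (1 - (1 - 1 / (2 * effective_size))^generations)
  v <- v_samp + v_drift
  z <- ifelse(v > 0, (p2 - p1) / sqrt(v), 0)
  per <- data.frame(marker = colnames(a) %||% seq_along(p1),
                    p_initial = unname(p1), p_final = unname(p2),
                    shift = unname(p2 - p1), z = unname(z),
                    flag = abs(unname(z)) > stats::qnorm(0.975))
  structure(list(per_marker = per,
                 het_change = mean(b == 1) - mean(a == 1),
                 n_flagged = sum(per$flag)),
            class = "LotMetrics")
}

#' @export
print.LotMetrics <- function(x, ...) {
  if (!is.null(x$per_marker)) {
    cat(sprintf("LotMetrics (stability): %d/%d markers flagged, het change %+.4f\n",
                x$n_flagged, nrow(x$per_marker), x$het_change))
  } else {
    cat(sprintf("LotMetrics (uniformity): max within-lot distance %.4f (ceiling %s) -> %s\n",
                x$max_within,
                if (is.null(x$ceiling)) "none" else sprintf("%.4f", x$ceiling),
                if (isTRUE(x$pass)) "pass" else if (isFALSE(x$pass)) "FAIL" else "no decision"))
  }
  invisible(x)
}

#' Correlation of trait distances with marker distances across subset sizes
#'
#' Random marker subsets of size `1` to the full marker count on a
#' log10-0.1 grid; for each size one random subset is drawn (a `replicates`
#' flag averages several for smoother curves) and the Pearson correlation
#' between the vectorized pairwise trait distances and marker distances is
#' recorded, over all varieties shared between the tables — overall and
#' split into high-heritability (h2 > 0.5) and low-heritability (h2 < 0.5)
#' trait groups when heritabilities are supplied.
#'
#' @param traits a `TraitTable`.
#' @param panel a `GenotypePanel`.
#' @param h2 optional named vector of per-trait heritabilities for the
#'   group split (names matching trait columns).
#' @param seed integer seed for the marker sampling.
#' @param replicates subsets per grid size (default 1, as a single draw per
#'   size is the convention; increase for smoother curves).
#' @return data.frame with columns `n_markers`, `group`
#'   (`all` / `high_h2` / `low_h2`), `correlation`,
#'   `marker_distance_variance`.
#' @export
marker_subsample_curve <- function(traits, panel, h2 = NULL, seed = 1,
                                   replicates = 1) {
  stopifnot(inherits(traits, "TraitTable"), inherits(panel, "GenotypePanel"))
  ids <- intersect(rownames(traits$scores), rownames(panel$geno))
  if (length(ids) < 3) stop("no (or too few) shared varieties between tables")
  geno <- panel$geno[ids, , drop = FALSE]
  m <- ncol(geno)
  tt <- trait_table(traits$scores[ids, , drop = FALSE], traits$scale)
  groups <- list(all = colnames(tt$scores))
  if (!is.null(h2)) {
    h2 <- h2[colnames(tt$scores)]
    groups$high_h2 <- colnames(tt$scores)[!is.na(h2) & h2 > 0.5]
    groups$low_h2 <- colnames(tt$scores)[!is.na(h2) & h2 < 0.5]
    groups <- groups[vapply(groups, length, 1L) > 0]  # a split may be empty
  }
  tdist <- lapply(groups, function(trs) {
    sub <- trait_table(tt$scores[, trs, drop = FALSE], tt$scale[trs])
    dmat <- trait_distance_matrix(sub)
    # as.dist vectorization matches the pair order of stats::dist
    as.vector(stats::as.dist(dmat))
  })
  sizes <- unique(c(pmin(m, round(10^seq(0, log10(m), by = 0.1))), m))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  for (sz in sizes) {
    cors <- matrix(NA_real_, replicates, length(groups))
    vars <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sub <- geno[, sample.int(m, sz), drop = FALSE]
      md <- stats::dist(sub, method = "manhattan") / sz
      mdv <- as.vector(md)
      vars[r] <- stats::var(mdv)
      cors[r, ] <- vapply(seq_along(groups), function(gi) {
        suppressWarnings(stats::cor(tdist[[gi]], mdv,
                                    use = "pairwise.complete.obs"))
      }, numeric(1))
    }
    rows[[length(rows) + 1]] <-
      data.frame(n_markers = sz, group = names(groups),
                 correlation = colMeans(cors, na.rm = TRUE),
                 marker_distance_variance = mean(vars))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
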