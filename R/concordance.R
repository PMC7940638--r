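#' Per-variety score discrepancy between two scoring organizations
#'
#' For every variety present in both tables, compares trait cells that are
#' non-missing in both ("complete pairwise data" only). Per variety it
#' reports the mean absolute score difference, the consistency (proportion
#' of traits that match exactly) and the number of traits compared. The
#' overall mean and SD are taken over per-variety mean differences (so `n`
#' is the number of comparable varieties, not cells), and a two-sided
#' one-sample t-test of the per-variety mean absolute differences against
#' zero is attached. Binary traits should be recoded to 1/2 first
#' ([recode_binary_traits()]) so every trait contributes comparable steps.
#'
#' @param a,b `TraitTable`s over overlapping variety sets, sharing trait
#'   columns.
#' @return an object of class `DiscrepancyResult`: `per_variety`
#'   data.frame, `overall` list (`mean`, `sd`, `n`, `t_p`,
#'   `prop_with_discrepancy`, `mean_consistency`), `excluded` ids with zero
#'   comparable traits.
#' @export
per_variety_discrepancy <- function(a, b) {
  stopifnot(inherits(a, "TraitTable"), inherits(b, "TraitTable"))
  ids <- intersect(rownames(a$scores), rownames(b$scores))
  if (length(ids) == 0) stop("no shared varieties between the two tables")
  trs <- intersect(colnames(a$scores), colnames(b$scores))
  if (length(trs) == 0) stop("no shared traits between the two tables")
  sa <- a$scores[ids, trs, drop = FALSE]
  sb <- b$scores[ids, trs, drop = FALSE]
  both <- !is.na(sa) & !is.na(sb)
  d <- abs(sa - sb)
  d[!both] <- NA
  n_comp <- rowSums(both)
  per <- data.frame(variety_id = ids,
                    mean_abs_diff = rowMeans(d, na.rm = TRUE),
                    consistency = rowSums(d == 0, na.rm = TRUE) /
                      pmax(n_comp, 1),
                    n_traits = n_comp)
  excluded <- per$variety_id[per$n_traits == 0]
  if (length(excluded)) {
    message(length(excluded), " variety(ies) with zero comparable traits excluded")
  }
  per <- per[per$n_traits > 0, , drop = FALSE]
  rownames(per) <- NULL
  tt <- if (nrow(per) > 1 && stats::sd(per$mean_abs_diff) > 0) {
    stats::t.test(per$mean_abs_diff, mu = 0)$p.value
  } else {
    NA_real_
  }
  overall <- list(mean = mean(per$mean_abs_diff),
                  sd = stats::sd(per$mean_abs_diff),
                  n = nrow(per),
                  t_p = tt,
                  prop_with_discrepancy = mean(per$mean_abs_diff > 0),
                  n_with_discrepancy = sum(per$mean_abs_diff > 0),
                  mean_consistency = mean(per$consistency))
  structure(list(per_variety = per, overall = overall, excluded = excluded),
            class = "DiscrepancyResult")
}

#' @export
print.DiscrepancyResult <- function(x, ...) {
  o <- x$overall
  cat(sprintf("DiscrepancyResult: mean = %.2f, sd = %.2f, n = %d\n",
              o$mean, o$sd, o$n))
  cat(sprintf("  varieties with >=1 discrepancy: %d/%d; mean consistency %.2f; t-test p = %.3g\n",
              o$n_with_discrepancy, o$n, o$mean_consistency, o$t_p))
  invisible(x)
}

#' Per-trait signed score bias between two organizations
#'
#' Mean of (first table minus second table) per trait over varieties where
#' both scores are present; the sign convention is first-minus-second, so
#' `per_trait_bias(a, b) == -per_trait_bias(b, a)`. Traits never jointly
#' observed are reported as `NA` (undefined), not zero.
#'
#' @param a,b `TraitTable`s.
#' @return data.frame with columns `trait`, `bias`, `n`.
#' @export
per_trait_bias <- function(a, b) {
  stopifnot(inherits(a, "TraitTable"), inherits(b, "TraitTable"))
  ids <- intersect(rownames(a$scores), rownames(b$scores))
  if (length(ids) == 0) stop("no shared varieties between the two tables")
  trs <- intersect(colnames(a$scores), colnames(b$scores))
  sa <- a$scores[ids, trs, drop = FALSE]
  sb <- b$scores[ids, trs, drop = FALSE]
  d <- sa - sb
  d[is.na(sa) | is.na(sb)] <- NA
  data.frame(trait = trs,
             bias = colMeans(d, na.rm = TRUE),
             n = colSums(!is.na(d)),
             row.names = NULL)
}

#' Normalized trait-score distance between variety pairs
#'
#' The Manhattan distance on trait scores, averaged over the traits
#' non-missing in both varieties (`normalize = TRUE`, default) or the raw
#' sum over those traits (`normalize = FALSE`). Normalization keeps pairs
#' with different missingness comparable.
#'
#' @param table a `TraitTable`.
#' @param normalize divide by the number of jointly observed traits.
#' @return symmetric distance matrix with `NA` for pairs sharing no trait.
#' @export
trait_distance_matrix <- function(table, normalize = TRUE) {
  sc <- table$scores
  obs <- !is.na(sc)
  sc0 <- sc
  sc0[!obs] <- 0
  # sum over jointly observed traits of |x - y| decomposes into terms
  # computable by cross-products is messy with missing data; n is small for
  # trait tables so a direct loop over pairs is fine
  n <- nrow(sc)
  d <- matrix(0, n, n, dimnames = list(rownames(sc), rownames(sc)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      share <- obs[i, ] & obs[j, ]
      if (!any(share)) {
        d[i, j] <- d[j, i] <- NA
      } else {
        s <- sum(abs(sc[i, share] - sc[j, share]))
        d[i, j] <- d[j, i] <- if (normalize) s / sum(share) else s
      }
    }
  }
  d
}

#' Rolling window of mean pairwise trait distances over submission order
#'
#' Sorts varieties by submission order, slides a window (default 20
#' varieties) one variety at a time, and returns the mean of all pairwise
#' trait distances within each window. A shrinking series over time
#' indicates a narrowing trait combinatorial space.
#'
#' @param table a `TraitTable`.
#' @param order vector ordering the varieties (e.g. AFP submission rank),
#'   named by variety id or aligned with the table rows.
#' @param window window size (default 20 varieties).
#' @param normalize see [trait_distance_matrix()].
#' @return data.frame with columns `window_start` (1-based position of the
#'   window's first variety in submission order) and `mean_distance`;
#'   length `n - window + 1`.
#' @export
rolling_trait_distance <- function(table, order, window = 20,
                                   normalize = TRUE) {
  stopifnot(inherits(table, "TraitTable"))
  n <- nrow(table$scores)
  if (n < window) stop("need at least ", window, " varieties, got ", n)
  if (!is.null(names(order))) order <- order[rownames(table$scores)]
  if (length(order) != n) stop("order must cover every variety")
  idx <- base::order(order)
  sorted <- trait_table(table$scores[idx, , drop = FALSE], table$scale)
  d <- trait_distance_matrix(sorted, normalize = normalize)
  out <- vapply(seq_len(n - window + 1), function(s) {
    w <- s:(s + window - 1)
    sub <- d[w, w]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  data.frame(window_start = seq_len(n - window + 1), mean_distance = out)
}
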