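#' Construct a genotype panel
#'
#' A `GenotypePanel` bundles a varieties-by-markers dosage matrix with its
#' marker map and per-variety metadata. Dosages are counts of the alternate
#' allele in \{0, 1, 2\}; fully inbred panels contain only \{0, 2\}. Variety
#' identifiers play the role of AFP (Application For Protection) numbers:
#' they are unique and their numeric `afp_order` reflects submission order,
#' which is the only ordering the package ever relies on (variety names are
#' not trusted to be unique).
#'
#' @param geno numeric matrix, varieties in rows and markers in columns.
#'   Row names are variety ids, column names marker ids.
#' @param map data.frame with columns `marker`, `chrom`, `cM`, `bp`, one row
#'   per marker, sorted by chromosome then genetic position.
#' @param info data.frame with columns `variety_id`, `seasonal_type`
#'   (`"spring"`, `"winter"` or `"alternative"`), `listing_year` and
#'   `afp_order` (integer submission rank).
#' @return an object of class `GenotypePanel`.
#' @export
genotype_panel <- function(geno, map, info) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix must have variety row names and marker column names")
  }
  if (anyDuplicated(rownames(geno))) stop("variety ids must be unique")
  if (anyDuplicated(colnames(geno))) stop("marker ids must be unique")
  map <- as.data.frame(map)
  need <- c("marker", "chrom", "cM", "bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.character(map$marker), colnames(geno))) {
    stop("map markers must match genotype columns in order")
  }
  info <- as.data.frame(info)
  needi <- c("variety_id", "seasonal_type", "listing_year", "afp_order")
  if (!all(needi %in% names(info))) {
    stop("info must have columns: ", paste(needi, collapse = ", "))
  }
  if (!identical(as.character(info$variety_id), rownames(geno))) {
    stop("info variety_id must match genotype rows in order")
  }
  bad <- !info$seasonal_type %in% c("spring", "winter", "alternative")
  if (any(bad)) stop("unknown seasonal_type: ", info$seasonal_type[bad][1])
  if (any(is.na(geno))) stop("genotype matrix must not contain missing dosages")
  if (!all(geno %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  structure(list(geno = geno, map = map, info = info),
            class = "GenotypePanel")
}

#' @export
print.GenotypePanel <- function(x, ...) {
  tab <- table(x$info$seasonal_type)
  cat(sprintf("GenotypePanel: %d varieties x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat("  seasonal types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  het <- mean(x$geno == 1)
  cat(sprintf("  heterozygous calls: %.2f%%\n", 100 * het))
  invisible(x)
}

#' Number of varieties / markers in a panel
#' @param panel a `GenotypePanel`.
#' @return integer count.
#' @export
n_varieties <- function(panel) nrow(panel$geno)

#' @rdname n_varieties
#' @export
n_markers <- function(panel) ncol(panel$geno)

#' Construct an ordinal trait table
#'
#' Varieties-by-traits ordinal scores. Each trait has an admissible set of
#' levels (a subset of 1..9, or the binary pair \{1, 9\}); `NA` encodes a
#' missing score and is the only missing sentinel used anywhere in the
#' package.
#'
#' @param scores numeric matrix, varieties in rows, traits in columns.
#' @param scale named list giving the admissible levels of every trait
#'   (names matching the columns of `scores`).
#' @return an object of class `TraitTable`.
#' @export
trait_table <- function(scores, scale) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("trait scores must have variety row names and trait column names")
  }
  if (anyDuplicated(rownames(scores))) stop("variety ids must be unique")
  if (!identical(sort(names(scale)), sort(colnames(scores)))) {
    stop("scale must be a named list covering every trait column")
  }
  for (tr in colnames(scores)) {
    v <- scores[, tr]
    bad <- !is.na(v) & !v %in% scale[[tr]]
    if (any(bad)) {
      stop(sprintf("trait %s has value %s outside its scale", tr,
                   v[bad][1]))
    }
  }
  structure(list(scores = scores, scale = scale[colnames(scores)]),
            class = "TraitTable")
}

#' @export
print.TraitTable <- function(x, ...) {
  cat(sprintf("TraitTable: %d varieties x %d traits, %.1f%% missing\n",
              nrow(x$scores), ncol(x$scores), 100 * mean(is.na(x$scores))))
  invisible(x)
}

#' @export
print.ProgenySet <- function(x, ...) {
  cat(sprintf("ProgenySet: %d %s progeny of (%s x %s), %d markers\n",
              nrow(x$geno), x$scheme$name, x$parents[1], x$parents[2],
              ncol(x$geno)))
  cat(sprintf("  residual heterozygosity: %.3f%%\n",
              100 * mean(x$geno == 1)))
  invisible(x)
}
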