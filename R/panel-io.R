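#' Read a genotype panel from disk
#'
#' Supports two on-disk formats: a tab-delimited dosage matrix (varieties in
#' rows, header of marker ids, first column `variety_id`) accompanied by
#' `<stem>.info.tsv` and `<stem>.map.tsv` side files, and a minimal VCF with
#' genotype calls (inbred lines carry `0/0` or `1/1`; `0/1` is read as
#' dosage 1). Markers with any missing call are dropped — missing genotype
#' data is never imputed — and the number of dropped markers is reported via
#' `message()`. Non-biallelic VCF sites are dropped with a warning.
#'
#' @param path file path (`.tsv` matrix or `.vcf`).
#' @param format `"matrix"` or `"vcf"`.
#' @param info,map optional data.frames overriding the side files (required
#'   for VCF input, which carries no variety metadata).
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"),
                           info = NULL, map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "variety_id") {
      stop("malformed genotype matrix: first column must be variety_id (",
           path, " line 1)")
    }
    geno <- as.matrix(tab[, -1, drop = FALSE])
    rownames(geno) <- tab$variety_id
    stem <- sub("\\.tsv$", "", path)
    if (is.null(info)) info <- utils::read.delim(paste0(stem, ".info.tsv"),
                                                 stringsAsFactors = FALSE)
    if (is.null(map)) map <- utils::read.delim(paste0(stem, ".map.tsv"),
                                               stringsAsFactors = FALSE)
  } else {
    parsed <- read_vcf_dosages(path)
    geno <- parsed$geno
    if (is.null(map)) map <- parsed$map
    if (is.null(info)) {
      info <- data.frame(variety_id = rownames(geno),
                         seasonal_type = "spring",
                         listing_year = NA_integer_,
                         afp_order = seq_len(nrow(geno)))
    }
  }
  n_miss <- sum(colSums(is.na(geno)) > 0)
  if (n_miss > 0) {
    keep <- colSums(is.na(geno)) == 0
    geno <- geno[, keep, drop = FALSE]
    map <- map[map$marker %in% colnames(geno), , drop = FALSE]
    message(n_miss, " marker(s) with missing calls removed, ",
            ncol(geno), " retained")
  }
  map <- map[match(colnames(geno), map$marker), , drop = FALSE]
  genotype_panel(geno, map, info)
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " non-biallelic site(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  geno <- t(apply(gt, 1, code))
  dimnames(geno) <- dimnames(gt)
  geno <- t(geno)  # varieties x markers
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    cM = as.numeric(fix[, "POS"]) / 1e6,
                    bp = as.integer(fix[, "POS"]))
  list(geno = geno, map = map)
}

#' Write a genotype panel to disk
#'
#' The matrix format writes `<stem>.tsv` (dosages), `<stem>.info.tsv` and
#' `<stem>.map.tsv`. The VCF format writes a minimal sites-with-genotypes
#' VCF (1-based positions, dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`).
#'
#' @param panel a `GenotypePanel`.
#' @param path output path (`.tsv` stem path for matrix, `.vcf` for vcf).
#' @param format `"matrix"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "matrix") {
    out <- data.frame(variety_id = rownames(panel$geno),
                      panel$geno, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    stem <- sub("\\.tsv$", "", path)
    utils::write.table(panel$info, paste0(stem, ".info.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(panel$map, paste0(stem, ".map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    gt_chr <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(panel$geno)),
                     collapse = "\t"))
    body <- vapply(seq_len(ncol(panel$geno)), function(j) {
      paste(c(panel$map$chrom[j], panel$map$bp[j], panel$map$marker[j],
              "A", "G", ".", "PASS", ".", "GT",
              gt_chr[panel$geno[, j] + 1L]), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read / write ordinal trait tables
#'
#' Tab-delimited layout: first column `variety_id`, remaining columns trait
#' scores (`NA` for missing). Trait scales default to the full 1..9 range
#' with binary \{1,9\} inferred for traits whose observed values are a
#' subset of \{1,9\}.
#'
#' @param path file path.
#' @param scale optional named list of admissible levels per trait.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, scale = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "variety_id") {
    stop("malformed trait table: first column must be variety_id")
  }
  scores <- as.matrix(tab[, -1, drop = FALSE])
  rownames(scores) <- tab$variety_id
  if (is.null(scale)) {
    scale <- lapply(colnames(scores), function(tr) {
      v <- scores[, tr]
      if (all(is.na(v) | v %in% c(1, 9)) && any(v == 9, na.rm = TRUE)) c(1, 9) else 1:9
    })
    names(scale) <- colnames(scores)
  }
  message("read ", nrow(scores), " varieties x ", ncol(scores), " traits")
  trait_table(scores, scale)
}

#' @rdname read_trait_table
#' @param traits a `TraitTable` to write.
#' @export
write_trait_table <- function(traits, path) {
  out <- data.frame(variety_id = rownames(traits$scores), traits$scores,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recode binary 1/9 traits to 1/2
#'
#' Binary DUS traits are scored 1 or 9; for comparability with the 1-step
#' ordinal traits they are recoded 1 -> 1 and 9 -> 2 before any discrepancy
#' analysis, so one scale step means one score class everywhere. Missing
#' values are preserved; any other value in a listed trait is an error.
#'
#' @param table a `TraitTable`.
#' @param binary_traits character vector of trait columns to recode
#'   (default: traits whose scale is exactly \{1, 9\}).
#' @return a recoded `TraitTable` (recoded traits get scale \{1, 2\}).
#' @export
recode_binary_traits <- function(table, binary_traits = NULL) {
  stopifnot(inherits(table, "TraitTable"))
  if (is.null(binary_traits)) {
    binary_traits <- names(Filter(function(s) setequal(s, c(1, 9)), table$scale))
  }
  sc <- table$scores
  scale <- table$scale
  for (tr in binary_traits) {
    if (!tr %in% colnames(sc)) stop("unknown trait: ", tr)
    v <- sc[, tr]
    bad <- !is.na(v) & !v %in% c(1, 9)
    if (any(bad)) {
      stop(sprintf("trait %s contains value %s; binary recode needs values in {1, 9}",
                   tr, v[bad][1]))
    }
    v[v == 9] <- 2
    sc[, tr] <- v
    scale[[tr]] <- c(1, 2)
  }
  trait_table(sc, scale)
}

#' Inner-join two tables by a unique key
#'
#' Both inputs must have unique keys; the result contains the intersection,
#' with the retained/dropped counts attached as the `"merge_counts"`
#' attribute and reported via `message()`. Join output is ordered by key so
#' `merge_by_id(a, b)` and `merge_by_id(b, a)` contain the same records.
#'
#' @param a,b data.frames.
#' @param key shared key column name (e.g. the AFP number).
#' @param suffixes column-name suffixes for clashes, as in [merge()].
#' @return joined data.frame.
#' @export
merge_by_id <- function(a, b, key = "variety_id", suffixes = c(".a", ".b")) {
  for (nm in c("a", "b")) {
    tab <- get(nm)
    if (!key %in% names(tab)) stop("table ", nm, " lacks key column ", key)
    if (anyDuplicated(tab[[key]])) {
      stop("duplicated keys in table ", nm, ": ",
           tab[[key]][duplicated(tab[[key]])][1])
    }
  }
  j <- merge(a, b, by = key, suffixes = suffixes)
  j <- j[order(j[[key]]), , drop = FALSE]
  rownames(j) <- NULL
  counts <- c(joined = nrow(j),
              dropped_a = nrow(a) - nrow(j),
              dropped_b = nrow(b) - nrow(j))
  attr(j, "merge_counts") <- counts
  message(sprintf("join: %d records kept, %d dropped from a, %d from b",
                  counts[1], counts[2], counts[3]))
  j
}

#' Merge two trait tables from the same scoring organization
#'
#' Combines a newer and an older source covering overlapping variety sets
#' (union of varieties, union of traits). Where both sources score the same
#' variety/trait cell and disagree, the newer source wins and the conflict
#' is counted; conflicts are returned in the `"conflicts"` attribute.
#'
#' @param newer,older `TraitTable`s (the newer source takes precedence).
#' @return merged `TraitTable` with a `"conflicts"` attribute data.frame.
#' @export
merge_trait_sources <- function(newer, older) {
  stopifnot(inherits(newer, "TraitTable"), inherits(older, "TraitTable"))
  ids <- union(rownames(newer$scores), rownames(older$scores))
  trs <- union(colnames(newer$scores), colnames(older$scores))
  out <- matrix(NA_real_, length(ids), length(trs),
                dimnames = list(ids, trs))
  fill <- function(m, src) {
    m[rownames(src), colnames(src)] <- ifelse(is.na(m[rownames(src), colnames(src)]),
                                              src, m[rownames(src), colnames(src)])
    m
  }
  conflicts <- data.frame(variety_id = character(), trait = character(),
                          newer = numeric(), older = numeric())
  shared_ids <- intersect(rownames(newer$scores), rownames(older$scores))
  shared_trs <- intersect(colnames(newer$scores), colnames(older$scores))
  if (length(shared_ids) && length(shared_trs)) {
    nv <- newer$scores[shared_ids, shared_trs, drop = FALSE]
    ov <- older$scores[shared_ids, shared_trs, drop = FALSE]
    cf <- which(!is.na(nv) & !is.na(ov) & nv != ov, arr.ind = TRUE)
    if (nrow(cf)) {
      conflicts <- data.frame(variety_id = shared_ids[cf[, 1]],
                              trait = shared_trs[cf[, 2]],
                              newer = nv[cf], older = ov[cf])
    }
  }
  out <- fill(out, newer$scores)
  out <- fill(out, older$scores)
  scale <- c(newer$scale, older$scale[setdiff(trs, names(newer$scale))])
  res <- trait_table(out, scale[trs])
  attr(res, "conflicts") <- conflicts
  message(sprintf("merged sources: %d varieties, %d conflicting cells (newer kept)",
                  length(ids), nrow(conflicts)))
  res
}

#' Curation summary of a trait table
#'
#' Reports the counts used when auditing a compiled national-list trait
#' data set: number of varieties, per-trait missing rates, traits with
#' missingness above a threshold, and traits non-segregating (at most one
#' observed level) within each seasonal type.
#'
#' @param traits a `TraitTable`.
#' @param seasonal_type named character vector (`variety_id` -> type), or
#'   `NULL` to skip the per-type segregation audit.
#' @param high_missing threshold for the high-missingness list (default
#'   0.10).
#' @param exclude_traits trait columns excluded from the segregation audit
#'   (default `"t28"`, the seasonal type itself).
#' @return list with `n_varieties`, `missing_rate` (named vector),
#'   `max_missing`, `traits_high_missing`, `nonseg_spring`, `nonseg_winter`.
#' @export
curation_summary <- function(traits, seasonal_type = NULL,
                             high_missing = 0.10,
                             exclude_traits = "t28") {
  sc <- traits$scores
  miss <- colMeans(is.na(sc))
  out <- list(n_varieties = nrow(sc),
              missing_rate = miss,
              max_missing = max(miss),
              traits_high_missing = names(miss)[miss > high_missing])
  if (!is.null(seasonal_type)) {
    audit <- setdiff(colnames(sc), exclude_traits)
    nonseg <- function(type) {
      idx <- rownames(sc) %in% names(seasonal_type)[seasonal_type == type]
      names(Filter(function(tr) {
        v <- sc[idx, tr]
        length(unique(v[!is.na(v)])) <= 1
      }, stats::setNames(audit, audit)))
    }
    out$nonseg_spring <- nonseg("spring")
    out$nonseg_winter <- nonseg("winter")
  }
  out
}

#' Read / write small delimited tables (pedigree, map, trials)
#'
#' Thin wrappers over tab-delimited files that report record counts.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_logged <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  message("read ", nrow(tab), " records from ", basename(path))
  tab
}

#' @rdname read_table_logged
#' @param tab data.frame to write.
#' @export
write_table_logged <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
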