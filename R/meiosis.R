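#' Build a genetic map
#'
#' @param n_markers total number of markers.
#' @param n_chromosomes number of chromosomes (barley has 7).
#' @param chrom_length_cM chromosome length(s) in centimorgans, recycled to
#'   `n_chromosomes`.
#' @return data.frame with columns `marker`, `chrom`, `cM`, `bp`, sorted by
#'   chromosome then position. Markers are spread uniformly at random along
#'   each chromosome; physical positions are a fixed 1 Mb/cM expansion and
#'   carried for reporting only — all recombination uses cM.
#' @param seed optional integer seed for the marker placement.
#' @export
make_genetic_map <- function(n_markers, n_chromosomes = 7,
                             chrom_length_cM = 150, seed = NULL) {
  if (n_markers < n_chromosomes) {
    stop("need at least one marker per chromosome")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  len <- rep_len(chrom_length_cM, n_chromosomes)
  per <- diff(floor(seq(0, n_markers, length.out = n_chromosomes + 1)))
  pieces <- lapply(seq_len(n_chromosomes), function(k) {
    pos <- sort(stats::runif(per[k], 0, len[k]))
    data.frame(chrom = paste0("chr", k), cM = pos)
  })
  map <- do.call(rbind, pieces)
  map$marker <- sprintf("m%05d", seq_len(nrow(map)))
  map$bp <- as.integer(round(map$cM * 1e6)) + 1L
  rownames(map) <- NULL
  map[, c("marker", "chrom", "cM", "bp")]
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Per-interval gamete haplotype switch probabilities implied by a crossover
# point process with no interference. Between adjacent markers d cM apart the
# number of crossovers is Poisson(d/100) and the gamete switches parental
# haplotype iff that count is odd, i.e. with probability (1 - exp(-2d/100))/2
# (the Haldane map function). The first marker of each chromosome gets 0.5
# (independent assortment / random start haplotype).
interval_switch_prob <- function(map, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  d <- c(0, diff(map$cM))
  new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-nrow(map)])
  if (any(d[!new_chrom] < 0)) stop("map positions must be sorted within chromosome")
  r <- switch(map_function,
              haldane = 0.5 * (1 - exp(-2 * d / 100)),
              kosambi = 0.5 * tanh(2 * d / 100))
  r[new_chrom] <- 0.5
  r
}

# Vectorized meiosis for a cohort: h1, h2 are n x m haplotype matrices (0/1
# alleles); every row is one individual's phased pair. Returns an n x m
# matrix of gamete haplotypes. The switch process is Markov along the map,
# which is exactly the marker-genotype law of the Poisson crossover model.
meiosis_cohort <- function(h1, h2, rprob) {
  n <- nrow(h1)
  m <- ncol(h1)
  sw <- matrix(stats::runif(n * m) < rep(rprob, each = n), n, m)
  idx <- sw
  if (m > 1) {
    for (j in 2:m) idx[, j] <- xor(idx[, j - 1L], sw[, j])
  }
  out <- h1
  out[idx] <- h2[idx]
  out
}

#' Simulate one gamete from a phased parent
#'
#' Crossovers follow a Poisson process on the genetic (cM) scale with no
#' interference (Haldane model); chromosomes assort independently. A fully
#' homozygous parent therefore always transmits a copy of its single
#' haplotype.
#'
#' @param parent either a numeric dosage vector in \{0,1,2\} for a fully
#'   phased-trivial (inbred) parent, or a list with elements `h1`, `h2`
#'   giving the two phased haplotypes in \{0,1\}.
#' @param map genetic map covering all markers (see [make_genetic_map()]).
#' @param map_function `"haldane"` (default) or `"kosambi"` (per-interval
#'   approximation).
#' @return numeric haplotype vector in \{0,1\}, one entry per marker.
#' @export
simulate_gamete <- function(parent, map, map_function = "haldane") {
  hp <- parent_haplotypes(parent, map)
  r <- interval_switch_prob(map, map_function)
  drop(meiosis_cohort(matrix(hp$h1, 1), matrix(hp$h2, 1), r))
}

parent_haplotypes <- function(parent, map) {
  if (is.list(parent) && all(c("h1", "h2") %in% names(parent))) {
    h1 <- parent$h1; h2 <- parent$h2
  } else {
    g <- as.numeric(parent)
    if (any(g == 1)) {
      stop("dosage-coded parents must be fully inbred; pass phased haplotypes for heterozygous parents")
    }
    h1 <- h2 <- g / 2
  }
  if (length(h1) != nrow(map) || length(h2) != nrow(map)) {
    stop("parent haplotypes and map cover different marker sets")
  }
  list(h1 = h1, h2 = h2)
}

#' Define an inbred crossing scheme
#'
#' `F6` is an F1 selfed for five generations by single-seed descent;
#' `BC1S4` is one backcross to a recurrent parent followed by four selfing
#' generations. A generic scheme takes explicit backcross and selfing
#' counts.
#'
#' @param name `"F6"`, `"BC1S4"` or `"generic"`.
#' @param recurrent_parent which parent recurs in backcrosses, `"first"`
#'   (default) or `"second"`.
#' @param n_backcross,n_self generation counts for `"generic"` schemes.
#' @return an object of class `CrossScheme`.
#' @export
cross_scheme <- function(name = c("F6", "BC1S4", "generic"),
                         recurrent_parent = c("first", "second"),
                         n_backcross = 0, n_self = 0) {
  name <- match.arg(name)
  recurrent_parent <- match.arg(recurrent_parent)
  gen <- switch(name,
                F6 = list(n_backcross = 0L, n_self = 5L),
                BC1S4 = list(n_backcross = 1L, n_self = 4L),
                generic = list(n_backcross = as.integer(n_backcross),
                               n_self = as.integer(n_self)))
  structure(c(list(name = name, recurrent_parent = recurrent_parent), gen),
            class = "CrossScheme")
}

#' Simulate progeny of a biparental cross
#'
#' Builds the F1 from two inbred parents, applies the scheme's backcross and
#' selfing generations, and returns `n` independent single-seed-descent
#' lineages.
#'
#' @param p1,p2 inbred parent dosage vectors in \{0,2\} (named or plain).
#' @param scheme a [cross_scheme()] or a scheme name like `"F6"`.
#' @param n number of progeny.
#' @param map genetic map.
#' @param seed integer seed.
#' @param map_function see [simulate_gamete()].
#' @return an object of class `ProgenySet` with elements `geno`
#'   (n x markers dosage matrix), `parents`, `scheme`, `seed`, `map`.
#' @export
simulate_cross <- function(p1, p2, scheme = "F6", n = 1000, map,
                           seed = 1, map_function = "haldane") {
  if (is.character(scheme)) scheme <- cross_scheme(scheme)
  if (n < 1) stop("n must be at least 1")
  if (length(p1) != nrow(map) || length(p2) != nrow(map)) {
    stop("parents and map cover different marker sets")
  }
  if (any(p1 == 1) || any(p2 == 1)) stop("parents must be fully inbred")
  if (all(p1 == p2)) {
    warning("identical parents: all progeny will match both parents")
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  r <- interval_switch_prob(map, map_function)
  hp1 <- p1 / 2
  hp2 <- p2 / 2
  # F1 cohort: identical phased heterozygotes
  h1 <- matrix(hp1, n, length(hp1), byrow = TRUE)
  h2 <- matrix(hp2, n, length(hp2), byrow = TRUE)
  rec <- if (scheme$recurrent_parent == "first") hp1 else hp2
  for (b in seq_len(scheme$n_backcross)) {
    g <- meiosis_cohort(h1, h2, r)
    h1 <- g
    h2 <- matrix(rec, n, length(rec), byrow = TRUE)
  }
  for (s in seq_len(scheme$n_self)) {
    g1 <- meiosis_cohort(h1, h2, r)
    g2 <- meiosis_cohort(h1, h2, r)
    h1 <- g1
    h2 <- g2
  }
  geno <- h1 + h2
  rownames(geno) <- sprintf("prog%05d", seq_len(n))
  colnames(geno) <- as.character(map$marker)
  structure(list(geno = geno,
                 parents = c(name_or(p1, "P1"), name_or(p2, "P2")),
                 scheme = scheme, seed = seed, map = map),
            class = "ProgenySet")
}

name_or <- function(x, default) {
  nm <- attr(x, "variety_id")
  if (is.null(nm)) default else nm
}

#' Exact-match report for simulated progeny
#'
#' Compares every progeny against each target genotype on a marker subset:
#' an exact match means identical dosage at every subset marker. Match
#' percentages are bootstrapped over progeny to give a mean and percentile
#' confidence interval, and a uniqueness table counts how often each
#' distinct progeny haplotype (on the subset) occurs.
#'
#' @param progeny a `ProgenySet` (or dosage matrix with marker columns).
#' @param targets named list (or matrix rows) of target dosage vectors, e.g.
#'   the parents and the registered sibling variety.
#' @param marker_subset character vector of marker ids to compare on;
#'   defaults to all markers.
#' @param n_bootstrap bootstrap resamples of the progeny set (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return an object of class `MatchReport`: `per_target` data.frame with
#'   match percentage, bootstrap mean and CI; `uniqueness` table of
#'   occurrence counts per distinct subset haplotype.
#' @export
match_report <- function(progeny, targets, marker_subset = NULL,
                         n_bootstrap = 1000, seed = 1, conf = 0.95) {
  geno <- if (inherits(progeny, "ProgenySet")) progeny$geno else as.matrix(progeny)
  if (is.matrix(targets)) {
    targets <- stats::setNames(lapply(seq_len(nrow(targets)), function(i) targets[i, ]),
                               rownames(targets))
  }
  if (is.null(marker_subset)) marker_subset <- colnames(geno)
  if (length(marker_subset) == 0) stop("marker subset must be non-empty")
  missing_m <- setdiff(marker_subset, colnames(geno))
  if (length(missing_m)) {
    stop("markers absent from progeny: ", paste(utils::head(missing_m, 5), collapse = ", "))
  }
  sub <- geno[, marker_subset, drop = FALSE]
  n <- nrow(sub)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  per <- lapply(names_or_index(targets), function(nm) {
    tg <- targets[[nm]]
    if (!is.null(names(tg))) {
      tg <- tg[marker_subset]
    } else {
      if (length(tg) != ncol(geno)) {
        stop("unnamed target ", nm, " must cover all progeny markers")
      }
      tg <- tg[match(marker_subset, colnames(geno))]
    }
    if (anyNA(tg)) stop("target ", nm, " lacks some subset markers")
    hit <- rowSums(sub != rep(tg, each = n)) == 0
    pct <- 100 * mean(hit)
    boot <- replicate(n_bootstrap, mean(hit[sample.int(n, n, replace = TRUE)]))
    a <- (1 - conf) / 2
    data.frame(target = nm, match_pct = pct,
               boot_mean_pct = 100 * mean(boot),
               boot_lo_pct = 100 * unname(stats::quantile(boot, a)),
               boot_hi_pct = 100 * unname(stats::quantile(boot, 1 - a)))
  })
  hapkey <- apply(sub, 1, paste, collapse = "")
  uniq <- sort(table(hapkey), decreasing = TRUE)
  structure(list(per_target = do.call(rbind, per),
                 uniqueness = uniq,
                 n_progeny = n,
                 markers = marker_subset),
            class = "MatchReport")
}

names_or_index <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("target", seq_along(x))
  names(x) <- nm
  nm
}

#' @export
print.MatchReport <- function(x, ...) {
  cat(sprintf("MatchReport: %d progeny on %d markers\n",
              x$n_progeny, length(x$markers)))
  print(x$per_target, row.names = FALSE)
  cat(sprintf("  distinct subset haplotypes: %d\n", length(x$uniqueness)))
  invisible(x)
}
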