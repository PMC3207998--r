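## GWAS-catalog enrichment of MRESS/CNM SNPs: LD-proxy expansion,
## unique-locus merging, observed overlap, and the resampling null.

#' Load a GWAS catalog table
#'
#' @param path TSV with columns `rsid`, `trait`, `pvalue`, `pmid`.
#' @param p_max Significance threshold applied at load (default 1e-5,
#'   records kept when `pvalue < p_max`).
#' @return Data frame of retained records.
#' @export
load_gwas_catalog <- function(path, p_max = 1e-5) {
  cat <- read_tsv_meta(path)
  stopifnot(all(c("rsid", "trait", "pvalue", "pmid") %in% names(cat)))
  cat[cat$pvalue < p_max, , drop = FALSE]
}

#' Load a pairwise LD table
#'
#' @param path TSV with columns `rsid_a`, `rsid_b`, `r2`.
#' @return Data frame `rsid_a`, `rsid_b`, `r2` (stored one row per
#'   unordered pair; lookups are symmetric).
#' @export
load_ld_table <- function(path) {
  ld <- read_tsv_meta(path)
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(ld)))
  ld
}

## symmetric adjacency as a named list of neighbor vectors, r2 strictly >
ld_neighbors <- function(ld, r2_min) {
  if (is.null(ld) || nrow(ld) == 0L) return(list())
  keep <- ld$r2 > r2_min
  a <- c(ld$rsid_a[keep], ld$rsid_b[keep])
  b <- c(ld$rsid_b[keep], ld$rsid_a[keep])
  split(b, a)
}

#' Expand SNPs to their LD proxy sets
#'
#' The proxy set of a SNP is itself plus every SNP with pairwise
#' r-squared strictly above `r2_min` (direct lookups only, no transitive
#' closure). SNPs absent from the LD table map to themselves.
#'
#' @param rsids Character vector of SNP identifiers.
#' @param ld LD table (`rsid_a`, `rsid_b`, `r2`) or `NULL`.
#' @param r2_min LD threshold (default 0.8, strict inequality).
#' @return Named list mapping each rsid to its proxy set.
#' @export
expand_ld <- function(rsids, ld = NULL, r2_min = 0.8) {
  nb <- ld_neighbors(ld, r2_min)
  out <- lapply(rsids, function(s) unique(c(s, nb[[s]])))
  names(out) <- rsids
  out
}

#' Merge GWAS catalog SNPs into unique loci
#'
#' Counts connected components of the graph on catalog SNPs whose edges
#' are pairwise r-squared above `r2_min`; catalog SNPs in LD with each
#' other collapse into one locus.
#'
#' @param catalog_rsids Character vector of (possibly repeated) catalog
#'   SNP identifiers.
#' @param ld LD table or `NULL`.
#' @param r2_min LD threshold (default 0.8).
#' @return Integer locus count.
#' @export
merge_catalog_loci <- function(catalog_rsids, ld = NULL, r2_min = 0.8) {
  snps <- unique(catalog_rsids)
  if (length(snps) == 0L) return(0L)
  if (is.null(ld) || nrow(ld) == 0L) return(length(snps))
  keep <- ld$r2 > r2_min & ld$rsid_a %in% snps & ld$rsid_b %in% snps
  if (!any(keep)) return(length(snps))
  g <- igraph::graph_from_data_frame(
    ld[keep, c("rsid_a", "rsid_b")], directed = FALSE,
    vertices = data.frame(name = snps))
  as.integer(igraph::count_components(g))
}

#' Observed overlap of catalog proxy sets with MRESS/CNM SNPs
#'
#' Expands every catalog SNP to its LD proxy set (which contains the
#' catalog SNP itself) and counts the unique MRESS and CNM SNPs that
#' appear in any proxy set. A SNP in both input sets is counted in both
#' class tallies but once in the total.
#'
#' @param catalog_rsids Catalog SNP identifiers.
#' @param ld LD table or `NULL`.
#' @param mress_set,cnm_set Character vectors of MRESS / CNM SNP rsids.
#' @param r2_min LD threshold (default 0.8).
#' @return List `n_mress`, `n_cnm`, `n_total`, and `hits` (data frame
#'   with the tagging catalog SNP for each overlapped SNP).
#' @export
observed_overlap <- function(catalog_rsids, ld, mress_set, cnm_set,
                             r2_min = 0.8) {
  proxies <- expand_ld(unique(catalog_rsids), ld, r2_min)
  tagged <- data.frame(catalog_rsid = rep(names(proxies),
                                          lengths(proxies)),
                       rsid = unlist(proxies, use.names = FALSE),
                       stringsAsFactors = FALSE)
  in_mress <- tagged$rsid %in% mress_set
  in_cnm <- tagged$rsid %in% cnm_set
  hits <- tagged[in_mress | in_cnm, , drop = FALSE]
  hits$class <- ifelse(hits$rsid %in% mress_set & hits$rsid %in% cnm_set,
                       "both",
                       ifelse(hits$rsid %in% mress_set, "mress", "cnm"))
  rownames(hits) <- NULL
  list(
    n_mress = length(unique(tagged$rsid[in_mress])),
    n_cnm = length(unique(tagged$rsid[in_cnm])),
    n_total = length(unique(hits$rsid)),
    hits = hits
  )
}

#' Resampling null for the catalog-overlap count
#'
#' Each replicate draws `n_draw` SNPs without replacement from the
#' MAF-filtered universe, expands LD proxies, and counts the unique
#' members of the MRESS/CNM set tagged. Deterministic given `rng_seed`.
#'
#' @param universe Data frame with `rsid` and `maf` (folded minor-allele
#'   frequency; the maximum across populations is the conventional
#'   choice).
#' @param set Character vector, the combined MRESS/CNM SNP set.
#' @param ld LD table or `NULL`.
#' @param n_draw SNPs drawn per replicate.
#' @param reps Number of replicates (default 1000).
#' @param maf_min MAF filter on the universe (default 0.01, kept when
#'   `maf >= maf_min`).
#' @param r2_min LD threshold (default 0.8).
#' @param rng_seed Integer seed.
#' @return Object of class `null_distribution`: list with
#'   `replicate_counts`, `mean`, `sd`, `reps`, `n_draw`, `rng_seed`.
#' @export
resample_null <- function(universe, set, ld = NULL, n_draw, reps = 1000L,
                          maf_min = 0.01, r2_min = 0.8, rng_seed = 1L) {
  pool <- universe$rsid[!is.na(universe$maf) & universe$maf >= maf_min]
  if (length(pool) < n_draw) {
    stop(sprintf("universe too small after MAF filter: need %d, have %d",
                 n_draw, length(pool)))
  }
  ## precompute, per universe SNP, the integer ids of set members tagged
  set <- unique(set)
  nb <- ld_neighbors(ld, r2_min)
  tags <- lapply(pool, function(s) {
    prox <- c(s, nb[[s]])
    match(prox[prox %in% set], set)
  })
  counts <- integer(reps)
  old_seed <- withr_seed(rng_seed)
  on.exit(restore_seed(old_seed))
  for (r in seq_len(reps)) {
    draw <- sample.int(length(pool), n_draw)
    counts[r] <- length(unique(unlist(tags[draw], use.names = FALSE)))
  }
  out <- list(replicate_counts = counts, mean = mean(counts),
              sd = stats::sd(counts), reps = reps, n_draw = n_draw,
              rng_seed = rng_seed)
  class(out) <- "null_distribution"
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("resampling null: %d replicates of %d draws; mean %.2f, sd %.2f\n",
              x$reps, x$n_draw, x$mean, x$sd))
  invisible(x)
}

#' Tail probability of an observed overlap under the resampling null
#'
#' @param null A `null_distribution` from [resample_null()].
#' @param observed Observed overlap count.
#' @return List `z` (standardized observed), `p_normal` (upper-tail
#'   standard-normal probability; `NA` when the null SD is zero) and
#'   `p_empirical` (add-one permutation estimate,
#'   `(1 + #\{replicates >= observed\}) / (reps + 1)`).
#' @export
tail_probability <- function(null, observed) {
  z <- if (null$sd > 0) (observed - null$mean) / null$sd else NA_real_
  p_normal <- if (!is.na(z)) stats::pnorm(z, lower.tail = FALSE) else NA_real_
  p_empirical <- (1 + sum(null$replicate_counts >= observed)) / (null$reps + 1)
  list(z = z, p_normal = p_normal, p_empirical = p_empirical)
}

## seed handling: set the RNG deterministically, restore afterwards
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
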