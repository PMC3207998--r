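## Intersection of SNPs with seed sites, position-in-MRE calls, and
## disruption verdicts from allele-substituted re-classification.

#' Fold an allele frequency to the minor-allele frequency
#'
#' @param freq Numeric vector of allele frequencies in \[0, 1\].
#' @return `pmin(freq, 1 - freq)`; `NA` passes through.
#' @export
fold_maf <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    stop("allele frequency outside [0, 1]")
  }
  pmin(freq, 1 - freq)
}

#' Folded MAF of SNPs from their per-population frequency columns
#'
#' The conventional summary for universe filtering: the maximum over
#' populations of the folded allele frequency. SNPs with no reported
#' frequency in any population get `NA` (distinct from 0).
#'
#' @param snps Data frame with `af_<pop>` columns (and optionally a
#'   precomputed `maf` column, returned as-is).
#' @return Numeric vector of folded MAFs.
#' @export
snp_maf <- function(snps) {
  if (!is.null(snps$maf)) return(snps$maf)
  af_cols <- grep("^af_", names(snps), value = TRUE)
  if (length(af_cols) == 0L) return(rep(NA_real_, nrow(snps)))
  af <- as.matrix(snps[, af_cols, drop = FALSE])
  apply(af, 1L, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) NA_real_ else max(fold_maf(p))
  })
}

#' Position of a SNP within an 8-position MRE frame
#'
#' Returns the MRE position of a SNP falling inside a site's genomic
#' span, or `NA` when outside. Under the default miR-position numbering,
#' position k is the mRNA base pairing with miR position k, so position
#' 1 is the 3'-most base of the site on the mRNA and position 8 the
#' 5'-most; `numbering = "mrna"` counts 1-8 along the mRNA 5'->3'
#' instead.
#'
#' @param site One-row data frame or list with `chrom`, `genomic_start`,
#'   `genomic_end` (1-based inclusive) and `strand`.
#' @param snp One-row data frame or list with `chrom` and `pos`.
#' @param numbering `"mir"` (default) or `"mrna"`.
#' @return Integer 1-8 or `NA_integer_`.
#' @export
snp_in_site <- function(site, snp, numbering = c("mir", "mrna")) {
  numbering <- match.arg(numbering)
  if (normalize_chrom(as.character(site$chrom)) !=
      normalize_chrom(as.character(snp$chrom))) {
    return(NA_integer_)
  }
  pos <- as.integer(snp$pos)
  gs <- as.integer(site$genomic_start)
  ge <- as.integer(site$genomic_end)
  if (pos < gs || pos > ge) return(NA_integer_)
  ## frame index along the mRNA 5'->3'
  widx <- if (site$strand == "+") pos - gs + 1L else ge - pos + 1L
  if (numbering == "mir") 9L - widx else widx
}

#' Classify the effect of a SNP on a seed site
#'
#' Re-classifies the 8-base frame with the reference and with the
#' alternate allele substituted (strand-aware: for minus-strand sites
#' the genomic alleles are complemented onto the mRNA strand) and calls
#' a verdict under the class order 8mer > 7mer-m8 > 7mer-A1 > 6mer >
#' none: `abolished` (to none), `downgraded`, `unchanged`, `upgraded`.
#'
#' @param site Site as in [snp_in_site()], plus `window_start` and
#'   `utr_name`/`mir_name` carried through.
#' @param snp One-row data frame or list with `rsid`, `chrom`, `pos`,
#'   `ref`, `alt` (genomic plus-strand alleles).
#' @param mir_seq Mature miR sequence for the site's miR.
#' @param utr_seq UTR sequence (mRNA strand) the site was called on.
#' @param numbering Passed to [snp_in_site()].
#' @return One-row data frame: `rsid`, `utr_name`, `mir_name`,
#'   `pos_in_mre`, `ref_class`, `alt_class`, `verdict`.
#' @export
classify_disruption <- function(site, snp, mir_seq, utr_seq,
                                numbering = c("mir", "mrna")) {
  numbering <- match.arg(numbering)
  pos_in_mre <- snp_in_site(site, snp, numbering = numbering)
  if (is.na(pos_in_mre)) stop("SNP does not fall inside the site frame")
  widx <- if (site$strand == "+") {
    as.integer(snp$pos) - as.integer(site$genomic_start) + 1L
  } else {
    as.integer(site$genomic_end) - as.integer(snp$pos) + 1L
  }

  utr <- dna_normalize(utr_seq)
  window <- substr(utr, site$window_start, site$window_start + 7L)
  ref_mrna <- if (site$strand == "+") snp$ref else complement_base(snp$ref)
  alt_mrna <- if (site$strand == "+") snp$alt else complement_base(snp$alt)
  have <- substr(window, widx, widx)
  if (have != ref_mrna) {
    stop(sprintf(
      "reference allele mismatch at %s:%s — UTR has '%s' (mRNA strand), VCF ref maps to '%s'",
      snp$chrom, snp$pos, have, ref_mrna))
  }

  pat <- build_site_patterns(mir_seq)
  alt_window <- window
  substr(alt_window, widx, widx) <- alt_mrna
  ref_class <- classify_frames(window, pat)
  alt_class <- classify_frames(alt_window, pat)

  dr <- site_rank(ref_class)
  da <- site_rank(alt_class)
  verdict <- if (da == dr) "unchanged"
  else if (da > dr) "upgraded"
  else if (da == 0L) "abolished"
  else "downgraded"

  data.frame(
    rsid = snp$rsid,
    utr_name = if (!is.null(site$utr_name)) site$utr_name else NA_character_,
    mir_name = if (!is.null(site$mir_name)) site$mir_name else NA_character_,
    pos_in_mre = pos_in_mre,
    ref_class = ref_class,
    alt_class = alt_class,
    verdict = verdict,
    stringsAsFactors = FALSE
  )
}

#' Intersect SNPs with seed-site hits and call disruptions
#'
#' For every (site, SNP) pair on the same chromosome with the SNP inside
#' the site's 8-position genomic frame, emits one disruption call. A SNP
#' intersecting two overlapping sites yields two independent calls (one
#' per miR), matching per-interaction row semantics.
#'
#' @param hits Hit table from [scan_utrs()] with genomic coordinates.
#' @param snps SNP table (`rsid`, `chrom`, `pos`, `ref`, `alt`).
#' @param mirs miR table (`name`, `seq`).
#' @param utrs UTR table (`name`, `seq`).
#' @param numbering Passed to [snp_in_site()].
#' @return Data frame of calls (see [classify_disruption()]) plus
#'   `site_type`, `chrom`, `pos`, `ref`, `alt`.
#' @export
call_disruptions <- function(hits, snps, mirs, utrs,
                             numbering = c("mir", "mrna")) {
  numbering <- match.arg(numbering)
  empty <- data.frame(
    rsid = character(), utr_name = character(), mir_name = character(),
    pos_in_mre = integer(), ref_class = character(), alt_class = character(),
    verdict = character(), site_type = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(snps) == 0L) return(empty)

  snps$chrom <- normalize_chrom(as.character(snps$chrom))
  hits$chrom <- normalize_chrom(as.character(hits$chrom))
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    site <- hits[i, ]
    sel <- which(snps$chrom == site$chrom &
                   snps$pos >= site$genomic_start &
                   snps$pos <= site$genomic_end)
    if (length(sel) == 0L) next
    mir_seq <- mirs$seq[match(site$mir_name, mirs$name)]
    utr_seq <- utrs$seq[match(site$utr_name, utrs$name)]
    calls <- lapply(sel, function(j) {
      cl <- classify_disruption(site, snps[j, ], mir_seq, utr_seq,
                                numbering = numbering)
      cbind(cl, data.frame(site_type = site$site_type,
                           chrom = snps$chrom[j], pos = snps$pos[j],
                           ref = snps$ref[j], alt = snps$alt[j],
                           stringsAsFactors = FALSE))
    })
    out[[i]] <- do.call(rbind, calls)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Count disruption calls by the seed type they interrupt
#'
#' @param calls Call table from [call_disruptions()]; the site's
#'   reference class (`ref_class`) is tallied.
#' @return Named integer vector over the four site classes; sums to
#'   `nrow(calls)`.
#' @export
summarize_by_seed_type <- function(calls) {
  counts <- stats::setNames(integer(length(SITE_TYPES)), SITE_TYPES)
  if (nrow(calls) > 0L) {
    tab <- table(factor(calls$ref_class, levels = SITE_TYPES))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
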