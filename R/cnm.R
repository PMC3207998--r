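## Created-site (CNM) detection: allele-centered 45-mer windows, strict
## class-increase calling, and a documented proxy duplex scorer standing
## behind the pairing-score / energy filters.

#' Proxy duplex scoring parameters
#'
#' The scorer is a deliberately simple, fully documented stand-in for a
#' full target-alignment thermodynamic model: Watson-Crick pairs score
#' +5, G:U wobbles +2, mismatches -3, gaps -8, with per-position scores
#' doubled over miR seed positions 2-8. On this scale a perfect 21-nt
#' duplex scores 140, about twice the default `score_min` of 70 (the
#' proxy-scale equivalent of the conventional pairing-score cutoff of
#' 150). The energy proxy is -(3*GC + 2*AU + 1*GU) pseudo-kcal/mol over
#' paired positions of the best local alignment, filtered at
#' `energy_max` (default -20).
#'
#' @param match_wc Watson-Crick pair score (default 5).
#' @param match_gu G:U wobble pair score (default 2).
#' @param mismatch Mismatch score (default -3).
#' @param gap Gap score (default -8).
#' @param seed_weight Multiplier over miR positions 2-8 (default 2).
#' @param score_min Minimum pairing score for a reported hit (default 70).
#' @param energy_max Maximum (least negative) energy proxy (default -20).
#' @return List of class `proxy_params`.
#' @export
proxy_params <- function(match_wc = 5, match_gu = 2, mismatch = -3,
                         gap = -8, seed_weight = 2,
                         score_min = 70, energy_max = -20) {
  out <- list(match_wc = match_wc, match_gu = match_gu, mismatch = mismatch,
              gap = gap, seed_weight = seed_weight,
              score_min = score_min, energy_max = energy_max)
  class(out) <- "proxy_params"
  out
}

#' Extract the allele-centered window around a 3'UTR SNP
#'
#' Retrieves `flank` bases on each side of the SNP on the mRNA strand
#' (minus-strand UTRs are assumed already reverse-complemented), giving
#' a window of length `2*flank + 1` with the SNP at offset `flank + 1`
#' (23 of 45 at the default flank of 22). Positions truncated by the UTR
#' ends are padded with the sentinel `N`, which never matches a seed
#' pattern and never pairs in the duplex scorer.
#'
#' @param utr_seq UTR sequence (mRNA strand).
#' @param snp One-row data frame or list (`rsid`, `chrom`, `pos`, `ref`,
#'   `alt`, genomic plus-strand alleles).
#' @param placement BED placement of the UTR (`chrom`, `start`, `end`,
#'   `strand`, 0-based half-open).
#' @param flank Flank length in bases (default 22).
#' @return List of class `snp_window`: `rsid`, `seq_ref`, `seq_alt`,
#'   `snp_offset`, `strand`; or `NULL` (with a warning) when the SNP
#'   does not map inside the UTR.
#' @export
extract_window <- function(utr_seq, snp, placement, flank = 22L) {
  utr <- dna_normalize(utr_seq)
  L <- nchar(utr)
  start0 <- as.integer(placement$start[1L])
  end0 <- as.integer(placement$end[1L])
  strand <- as.character(placement$strand[1L])
  if (normalize_chrom(as.character(snp$chrom)) !=
      normalize_chrom(as.character(placement$chrom[1L]))) {
    warning("SNP ", snp$rsid, " on a different chromosome than the UTR; skipped")
    return(NULL)
  }
  pos <- as.integer(snp$pos)
  if (pos <= start0 || pos > end0) {
    warning("SNP ", snp$rsid, " outside the UTR; skipped")
    return(NULL)
  }
  u <- if (strand == "+") pos - start0 else end0 - pos + 1L

  ref_mrna <- if (strand == "+") snp$ref else complement_base(snp$ref)
  alt_mrna <- if (strand == "+") snp$alt else complement_base(snp$alt)
  if (substr(utr, u, u) != ref_mrna) {
    stop(sprintf(
      "reference allele mismatch for %s: UTR has '%s' (mRNA strand), VCF ref maps to '%s'",
      snp$rsid, substr(utr, u, u), ref_mrna))
  }

  lo <- u - flank
  hi <- u + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - L)
  core <- substr(utr, max(1L, lo), min(L, hi))
  seq_ref <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  snp_offset <- flank + 1L
  seq_alt <- seq_ref
  substr(seq_alt, snp_offset, snp_offset) <- alt_mrna
  out <- list(rsid = snp$rsid, seq_ref = seq_ref, seq_alt = seq_alt,
              snp_offset = snp_offset, strand = strand)
  class(out) <- "snp_window"
  out
}

## pair score matrix builder: miR base vs target (mRNA) base
pair_score <- function(mb, tb, params) {
  if (mb == "N" || tb == "N") return(-1e6)
  if (tb == complement_base(mb)) return(params$match_wc)
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return(params$match_gu)
  params$mismatch
}

## energy contribution of a formed pair (0 for an unpaired/mismatch column)
pair_energy <- function(mb, tb) {
  if ((mb == "G" && tb == "C") || (mb == "C" && tb == "G")) return(3)
  if ((mb == "A" && tb == "T") || (mb == "T" && tb == "A")) return(2)
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return(1)
  0
}

#' Score a miR:target duplex with the proxy scorer
#'
#' Performs a local (Smith-Waterman) alignment of the miR (5'->3')
#' against the reversed target, i.e. an antiparallel duplex, with the
#' `proxy_params` scoring scheme and seed positions 2-8 doubled. The
#' energy proxy sums -(3 GC + 2 AU + 1 GU) over the paired (matched)
#' positions of the best-scoring alignment. Deterministic: ties in the
#' dynamic program are broken diagonal > up > left, and the traceback
#' starts at the first maximal cell in column-major order.
#'
#' @param mir_seq Mature miR sequence (5'->3').
#' @param target Target mRNA fragment (5'->3'), length >= 8; `N` bases
#'   never pair.
#' @param params A [proxy_params()] object.
#' @return List with `pairing_score` and `energy_proxy`.
#' @export
duplex_score <- function(mir_seq, target, params = proxy_params()) {
  mir <- strsplit(dna_normalize(mir_seq, allow_n = FALSE), "", fixed = TRUE)[[1L]]
  tg <- strsplit(dna_normalize(target), "", fixed = TRUE)[[1L]]
  if (length(tg) < 8L) stop("target must be at least 8 nt")
  tg <- rev(tg) # antiparallel: miR 5'->3' vs target 3'->5'
  m <- length(mir)
  n <- length(tg)
  w <- ifelse(seq_len(m) >= 2L & seq_len(m) <= 8L, params$seed_weight, 1)

  S <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      S[i, j] <- w[i] * pair_score(mir[i], tg[j], params)
    }
  }
  H <- matrix(0, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    hprev <- H[i, ]
    hrow <- H[i + 1L, ]
    for (j in seq_len(n)) {
      hrow[j + 1L] <- max(0, hprev[j] + S[i, j],
                          hprev[j + 1L] + params$gap,
                          hrow[j] + params$gap)
    }
    H[i + 1L, ] <- hrow
  }
  best <- max(H)
  if (best <= 0) {
    return(list(pairing_score = 0, energy_proxy = 0))
  }
  idx <- which(H == best)[1L]
  i <- (idx - 1L) %% (m + 1L)
  j <- (idx - 1L) %/% (m + 1L)
  energy <- 0
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    h <- H[i + 1L, j + 1L]
    if (h == H[i, j] + S[i, j]) {
      if (pair_score(mir[i], tg[j], params) > 0) {
        energy <- energy - pair_energy(mir[i], tg[j])
      }
      i <- i - 1L
      j <- j - 1L
    } else if (h == H[i, j + 1L] + params$gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairing_score = best, energy_proxy = energy)
}

#' Detect seed sites created by the non-reference allele
#'
#' Examines every 8-position frame of the window that contains the SNP
#' offset and, for each miR, reports a created-site hit when the frame's
#' class with the alternate allele strictly exceeds its class with the
#' reference allele (none -> any, or lower -> higher) and the proxy
#' duplex against the alternate window passes `score_min` and
#' `energy_max`. No conservation filter is applied to created sites.
#' With `mode = "any_frame"` the class comparison is taken against the
#' best reference-allele class across the considered frames instead of
#' the same frame.
#'
#' @param window A `snp_window` from [extract_window()].
#' @param mirs miR table (`name`, `seq`).
#' @param params A [proxy_params()] object.
#' @param mode `"same_frame"` (default, strict per-frame creation) or
#'   `"any_frame"`.
#' @return Data frame: `rsid`, `mir_name`, `site_type` (class created),
#'   `ref_class`, `window_offset` (frame start within the window),
#'   `pairing_score`, `energy_proxy`.
#' @export
detect_created_sites <- function(window, mirs, params = proxy_params(),
                                 mode = c("same_frame", "any_frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "snp_window"))
  L <- nchar(window$seq_alt)
  off <- window$snp_offset
  starts <- max(1L, off - 7L):min(L - 7L, off)
  ref_frames <- substring(window$seq_ref, starts, starts + 7L)
  alt_frames <- substring(window$seq_alt, starts, starts + 7L)

  out <- list()
  for (i in seq_len(nrow(mirs))) {
    pat <- build_site_patterns(mirs$seq[i], mirs$name[i])
    rc <- classify_frames(ref_frames, pat)
    ac <- classify_frames(alt_frames, pat)
    ref_rank <- if (mode == "any_frame") max(site_rank(rc)) else site_rank(rc)
    created <- which(site_rank(ac) > ref_rank)
    if (length(created) == 0L) next
    sc <- duplex_score(mirs$seq[i], window$seq_alt, params)
    if (sc$pairing_score < params$score_min ||
        sc$energy_proxy > params$energy_max) next
    out[[length(out) + 1L]] <- data.frame(
      rsid = window$rsid,
      mir_name = mirs$name[i],
      site_type = ac[created],
      ref_class = rc[created],
      window_offset = starts[created],
      pairing_score = sc$pairing_score,
      energy_proxy = sc$energy_proxy,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(rsid = character(), mir_name = character(),
                      site_type = character(), ref_class = character(),
                      window_offset = integer(), pairing_score = numeric(),
                      energy_proxy = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Run created-site detection over a SNP table
#'
#' Extracts the allele-centered window for every SNP that maps inside
#' its UTR and collects [detect_created_sites()] hits.
#'
#' @param snps SNP table (`rsid`, `chrom`, `pos`, `ref`, `alt`).
#' @param utrs UTR table (`name`, `seq`).
#' @param placements BED placements (`name`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param mirs miR table (`name`, `seq`).
#' @param params A [proxy_params()] object.
#' @param flank Flank length (default 22).
#' @inheritParams detect_created_sites
#' @return Row-bound hit table (see [detect_created_sites()]).
#' @export
call_created_sites <- function(snps, utrs, placements, mirs,
                               params = proxy_params(), flank = 22L,
                               mode = c("same_frame", "any_frame")) {
  mode <- match.arg(mode)
  out <- list()
  for (j in seq_len(nrow(snps))) {
    snp <- snps[j, ]
    pl <- placements[normalize_chrom(placements$chrom) ==
                       normalize_chrom(as.character(snp$chrom)) &
                       placements$start < snp$pos &
                       placements$end >= snp$pos, , drop = FALSE]
    for (k in seq_len(nrow(pl))) {
      utr_seq <- utrs$seq[match(pl$name[k], utrs$name)]
      win <- extract_window(utr_seq, snp, pl[k, ], flank = flank)
      if (is.null(win)) next
      out[[length(out) + 1L]] <- detect_created_sites(win, mirs, params,
                                                      mode = mode)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(rsid = character(), mir_name = character(),
                      site_type = character(), ref_class = character(),
                      window_offset = integer(), pairing_score = numeric(),
                      energy_proxy = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
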