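## Canonical seed-site patterns and UTR scanning.
##
## All sequences are handled internally in the DNA alphabet {A,C,G,T}; U on
## input is mapped to T at ingestion, so genomic (dbSNP-style) coordinates
## and alleles can be compared directly against mature miR sequences.

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Uppercases the input and maps U to T. Any character outside
#' \{A,C,G,T,U,N\} raises an error naming the first offending position
#' (N is tolerated as an unknown/sentinel base that never matches a
#' pattern and never pairs).
#'
#' @param x Character scalar, nucleotide sequence (DNA or RNA alphabet).
#' @param allow_n Logical; accept N as a sentinel base (default `TRUE`).
#' @return Character scalar over \{A,C,G,T\} (plus N when allowed).
#' @export
dna_normalize <- function(x, allow_n = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) stop("empty sequence")
  out <- chartr("u", "t", toupper(x))
  out <- chartr("U", "T", out)
  ok_set <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(out, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% ok_set)
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  out
}

#' Reverse complement of a DNA/RNA sequence
#'
#' Accepts U on input (mapped to T); N complements to N. Applying the
#' function twice returns the (normalized) input.
#'
#' @param seq Character scalar nucleotide sequence.
#' @return Character scalar, the reverse complement in DNA alphabet.
#' @examples
#' reverse_complement("AAGG") # "CCTT"
#' @export
reverse_complement <- function(seq) {
  s <- dna_normalize(seq)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Build the four canonical seed-site patterns for a mature miR
#'
#' Patterns are the target (mRNA) strand written 5'->3'. The 6mer is the
#' reverse complement of miR positions 2-7; the 7mer-m8 prepends the
#' complement of miR position 8; the 7mer-A1 appends a literal A
#' (regardless of the base at miR position 1); the 8mer does both.
#'
#' @param mir_seq Mature miR sequence, 5'->3', length >= 8.
#' @param name Optional miR identifier carried in the result.
#' @return Object of class `site_patterns`: list with `name`, `seed`
#'   (miR positions 2-7), `m8_base` (mRNA base complementary to miR
#'   position 8) and the four patterns `p6`, `p7a1`, `p7m8`, `p8`.
#' @export
build_site_patterns <- function(mir_seq, name = NA_character_) {
  s <- dna_normalize(mir_seq, allow_n = FALSE)
  if (nchar(s) < 8L) stop("miR sequence must be at least 8 nt")
  seed <- substr(s, 2L, 7L)
  p6 <- reverse_complement(seed)
  m8_base <- complement_base(substr(s, 8L, 8L))
  out <- list(
    name = name,
    seed = seed,
    m8_base = m8_base,
    p6 = p6,
    p7a1 = paste0(p6, "A"),
    p7m8 = paste0(m8_base, p6),
    p8 = paste0(m8_base, p6, "A")
  )
  class(out) <- "site_patterns"
  out
}

#' @export
print.site_patterns <- function(x, ...) {
  cat(sprintf("seed-site patterns%s\n",
              if (is.na(x$name)) "" else paste0(" for ", x$name)))
  cat(sprintf("  6mer    %s\n  7mer-A1 %s\n  7mer-m8 %s\n  8mer    %s\n",
              x$p6, x$p7a1, x$p7m8, x$p8))
  invisible(x)
}

#' Classify an 8-base MRE frame against a pattern set
#'
#' The frame is the target-strand (mRNA 5'->3') window whose position j
#' pairs with miR position 9-j. Returns the maximal matching class under
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer; the 6mer is tested against frame
#' positions 2-7. `NA` when the seed (positions 2-7) does not match.
#'
#' @param window8 Character scalar of length 8.
#' @param patterns A `site_patterns` object.
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"` or
#'   `NA_character_`.
#' @export
classify_window <- function(window8, patterns) {
  stopifnot(inherits(patterns, "site_patterns"))
  if (!is.character(window8) || length(window8) != 1L || nchar(window8) != 8L) {
    stop("window must be a single string of length 8")
  }
  classify_frames(dna_normalize(window8), patterns)
}

## vectorized frame classification (internal); windows already normalized
classify_frames <- function(windows, patterns) {
  seed_ok <- substr(windows, 2L, 7L) == patterns$p6
  a1 <- substr(windows, 8L, 8L) == "A"
  m8 <- substr(windows, 1L, 1L) == patterns$m8_base
  cls <- rep(NA_character_, length(windows))
  cls[seed_ok] <- "6mer"
  cls[seed_ok & a1] <- "7mer-A1"
  cls[seed_ok & m8] <- "7mer-m8"
  cls[seed_ok & m8 & a1] <- "8mer"
  cls
}

## rank used for disruption/creation verdicts; NA (no site) ranks 0
site_rank <- function(cls) {
  r <- match(cls, SITE_TYPES)
  r[is.na(r)] <- 0L
  r
}

#' Scan a 3'UTR for canonical seed sites of a set of miRs
#'
#' Slides an 8-base frame over the UTR (mRNA strand, 5'->3') and reports
#' every (miR, offset) pair achieving a seed-site class. Overlapping hits
#' are all reported. When `placement` is given, 1-based inclusive genomic
#' coordinates are attached (BED placement is 0-based half-open;
#' minus-strand UTR sequences are assumed already reverse-complemented to
#' the mRNA strand, and their frames are mapped back through the
#' placement). When `site_scores` is given, hits failing the PhastCons
#' or mirSVR cutoffs are dropped; without annotation no conservation
#' filter applies.
#'
#' @param utr_seq UTR sequence (mRNA strand, 5'->3').
#' @param mirs Data frame with columns `name`, `seq` (mature miR 5'->3').
#' @param utr_name Identifier attached to hits.
#' @param placement Optional one-row data frame (`chrom`, `start`, `end`,
#'   `strand`) with BED (0-based half-open) coordinates of the UTR.
#' @param site_scores Optional data frame (`utr_name`, `mir_name`,
#'   `window_start`, `phastcons`, `mirsvr`) of per-site annotation.
#' @param min_phastcons PhastCons cutoff, sites kept when `>=` (default 0.57).
#' @param mirsvr_max mirSVR cutoff, sites kept when `<=` (default -0.6).
#' @return Data frame of hits: `utr_name`, `mir_name`, `site_type`,
#'   `window_start`, `window_end` (1-based inclusive UTR offsets of the
#'   8-position frame), and when placed, `chrom`, `genomic_start`,
#'   `genomic_end`, `strand`; plus `phastcons`, `mirsvr` when annotated.
#' @export
scan_utr <- function(utr_seq, mirs, utr_name = "utr",
                     placement = NULL, site_scores = NULL,
                     min_phastcons = 0.57, mirsvr_max = -0.6) {
  seq <- dna_normalize(utr_seq)
  L <- nchar(seq)
  if (L < 8L) stop("UTR must be at least 8 nt")
  starts <- seq_len(L - 7L)
  windows <- substring(seq, starts, starts + 7L)

  res <- lapply(seq_len(nrow(mirs)), function(i) {
    pat <- build_site_patterns(mirs$seq[i], mirs$name[i])
    cls <- classify_frames(windows, pat)
    hit <- which(!is.na(cls))
    if (length(hit) == 0L) return(NULL)
    data.frame(
      utr_name = utr_name,
      mir_name = mirs$name[i],
      site_type = cls[hit],
      window_start = starts[hit],
      window_end = starts[hit] + 7L,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, res)
  if (is.null(hits)) {
    hits <- data.frame(utr_name = character(), mir_name = character(),
                       site_type = character(), window_start = integer(),
                       window_end = integer(), stringsAsFactors = FALSE)
  }

  if (!is.null(placement)) {
    hits <- add_genomic_coords(hits, placement)
  }

  if (!is.null(site_scores) && nrow(hits) > 0L) {
    key <- paste(hits$utr_name, hits$mir_name, hits$window_start, sep = "\r")
    skey <- paste(site_scores$utr_name, site_scores$mir_name,
                  site_scores$window_start, sep = "\r")
    idx <- match(key, skey)
    hits$phastcons <- site_scores$phastcons[idx]
    hits$mirsvr <- site_scores$mirsvr[idx]
    keep <- !is.na(idx) &
      hits$phastcons >= min_phastcons &
      hits$mirsvr <= mirsvr_max
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

## Attach 1-based inclusive genomic coordinates from a BED placement.
## On the minus strand, mRNA offset i maps to genomic position end - i + 1.
add_genomic_coords <- function(hits, placement) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(placement)))
  if (nrow(hits) == 0L) {
    hits$chrom <- character(0)
    hits$genomic_start <- integer(0)
    hits$genomic_end <- integer(0)
    hits$strand <- character(0)
    return(hits)
  }
  start0 <- as.integer(placement$start[1L])
  end0 <- as.integer(placement$end[1L])
  strand <- as.character(placement$strand[1L])
  hits$chrom <- normalize_chrom(as.character(placement$chrom[1L]))
  if (strand == "+") {
    hits$genomic_start <- start0 + hits$window_start
    hits$genomic_end <- start0 + hits$window_end
  } else {
    hits$genomic_start <- end0 - hits$window_end + 1L
    hits$genomic_end <- end0 - hits$window_start + 1L
  }
  hits$strand <- strand
  hits
}

#' Scan a set of UTRs for seed sites
#'
#' Convenience wrapper applying [scan_utr()] to each sequence of a UTR
#' table with optional per-UTR genomic placements.
#'
#' @param utrs Data frame with columns `name`, `seq`.
#' @param mirs miR table as in [scan_utr()].
#' @param placements Optional BED-like data frame (`name`, `chrom`,
#'   `start`, `end`, `strand`), one row per UTR.
#' @inheritParams scan_utr
#' @return Row-bound hit table (see [scan_utr()]).
#' @export
scan_utrs <- function(utrs, mirs, placements = NULL, site_scores = NULL,
                      min_phastcons = 0.57, mirsvr_max = -0.6) {
  out <- lapply(seq_len(nrow(utrs)), function(i) {
    pl <- NULL
    if (!is.null(placements)) {
      pl <- placements[placements$name == utrs$name[i], , drop = FALSE]
      if (nrow(pl) == 0L) stop("no genomic placement for UTR ", utrs$name[i])
    }
    scan_utr(utrs$seq[i], mirs, utr_name = utrs$name[i], placement = pl,
             site_scores = site_scores, min_phastcons = min_phastcons,
             mirsvr_max = mirsvr_max)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
normalize_chrom <- function(x) sub("^chr", "", x)
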