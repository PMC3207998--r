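## Independent oracles used to cross-check the implementation. These are
## deliberately written by other routes (character vectors, recursion,
## stats::aov) than the package code they verify.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## reverse complement by explicit per-character lookup
oracle_revcomp <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  ch[ch == "U"] <- "T"
  paste(rev(unname(COMP[ch])), collapse = "")
}

## classify an 8-base frame straight from the class definitions:
## frame position j pairs miR position 9-j; seed = miR 2-7 must pair
## Watson-Crick; 8mer needs an A opposite miR position 1 and a pairing
## base at position 8.
oracle_classify <- function(window8, mir_seq) {
  w <- strsplit(window8, "", fixed = TRUE)[[1L]]
  m <- strsplit(mir_seq, "", fixed = TRUE)[[1L]]
  pairs <- function(mir_pos) {
    j <- 9L - mir_pos
    !is.na(COMP[m[mir_pos]]) && w[j] == unname(COMP[m[mir_pos]])
  }
  seed_ok <- all(vapply(2:7, pairs, logical(1L)))
  if (!seed_ok) return(NA_character_)
  a1 <- w[8L] == "A"
  m8 <- pairs(8L)
  if (a1 && m8) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
}

## exhaustive per-offset scan of a UTR for one miR
oracle_scan <- function(utr_seq, mir_seq) {
  L <- nchar(utr_seq)
  out <- list()
  for (i in seq_len(L - 7L)) {
    cls <- oracle_classify(substr(utr_seq, i, i + 7L), mir_seq)
    if (!is.na(cls)) {
      out[[length(out) + 1L]] <- data.frame(window_start = i,
                                            site_type = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    data.frame(window_start = integer(), site_type = character())
  } else do.call(rbind, out)
}

## brute-force local alignment score by memoized recursion over suffix
## extensions; mirrors the proxy scheme (antiparallel, seed weight on
## miR positions 2-8), feasible for short sequences only.
oracle_duplex_score <- function(mir_seq, target, params = proxy_params()) {
  mir <- strsplit(mir_seq, "", fixed = TRUE)[[1L]]
  tg <- rev(strsplit(target, "", fixed = TRUE)[[1L]])
  m <- length(mir)
  n <- length(tg)
  w <- ifelse(seq_len(m) >= 2 & seq_len(m) <= 8, params$seed_weight, 1)
  ps <- function(a, b) {
    if (a == "N" || b == "N") return(-1e6)
    if (b == unname(COMP[a])) return(params$match_wc)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(params$match_gu)
    params$mismatch
  }
  memo <- new.env(hash = TRUE)
  best_from <- function(i, j) { # best alignment score starting at (i, j)
    if (i > m || j > n) return(0)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- max(0,
             w[i] * ps(mir[i], tg[j]) + best_from(i + 1L, j + 1L),
             params$gap + best_from(i + 1L, j),
             params$gap + best_from(i, j + 1L))
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    best <- max(best, best_from(i, j))
  }
  best
}

## Weir-Cockerham theta for one SNP through stats::aov on expanded 0/1
## allele vectors (independent route to the mean squares).
oracle_fst_aov <- function(counts, sizes) {
  x <- unlist(lapply(seq_along(counts), function(g) {
    c(rep(1, counts[g]), rep(0, sizes[g] - counts[g]))
  }))
  pop <- factor(rep(seq_along(counts), sizes))
  ms <- anova(stats::aov(x ~ pop))[["Mean Sq"]]
  msp <- ms[1L]
  msg <- ms[2L]
  N <- sum(sizes)
  nc <- (N - sum(sizes^2) / N) / (length(sizes) - 1L)
  min(1, max(0, (msp - msg) / (msp + (nc - 1) * msg)))
}

## small fully-specified world for deterministic unit tests: one UTR on
## each strand with one planted 8mer site each for a single miR
tiny_two_strand_world <- function() {
  mir <- "TCACAACCTCCTAGAAAGAGT" # arbitrary fixed 21-mer
  pat <- build_site_patterns(mir, "mirX")
  plus_seq <- paste0(strrep("T", 40), pat$p8, strrep("C", 40))
  minus_seq <- paste0(strrep("G", 30), pat$p8, strrep("T", 50))
  utrs <- data.frame(name = c("utrP", "utrM"),
                     seq = c(plus_seq, minus_seq),
                     stringsAsFactors = FALSE)
  placements <- data.frame(
    name = c("utrP", "utrM"), chrom = c("1", "2"),
    start = c(100L, 500L), end = c(100L + 88L, 500L + 88L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  mirs <- data.frame(name = "mirX", seq = mir, stringsAsFactors = FALSE)
  list(mirs = mirs, utrs = utrs, placements = placements, pat = pat)
}
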