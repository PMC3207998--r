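## Sliding-window SNP density over the 42-base region around validated
## seed sites (18 bases either side of the 6-base seed, window 6, step 1).

#' Sliding-window SNP density profile over seed sites
#'
#' For every site the 6-base seed (frame positions 2-7 of the 8-position
#' MRE) anchors a region running from `flank` bases upstream of the
#' first seed base to `flank` bases downstream of the last, scanned with
#' a `window`-base window at a 1-base step: with the defaults, 37
#' windows over a 42-base region, window start offsets -18..+18 relative
#' to the first seed base. Offsets follow the mRNA 5'->3' direction, so
#' minus-strand sites count along decreasing genomic coordinate. The
#' count at an offset is the number of (site, SNP) pairs whose SNP falls
#' inside that site's window; density is count * 1000 / (n_sites *
#' window) in SNPs/kb.
#'
#' @param sites Hit table with `chrom`, `genomic_start`, `genomic_end`,
#'   `strand` (the 8-position frame, 1-based inclusive).
#' @param snps SNP table with `chrom`, `pos`.
#' @param window Window size in bases (default 6).
#' @param flank Bases either side of the seed (default 18).
#' @return Data frame of class `density_profile` with columns `offset`,
#'   `count`, `density`; attribute `n_sites`.
#' @export
window_density <- function(sites, snps, window = 6L, flank = 18L) {
  offsets <- seq.int(-flank, flank)
  counts <- stats::setNames(integer(length(offsets)), offsets)
  n_sites <- nrow(sites)
  if (n_sites > 0L && nrow(snps) > 0L) {
    snp_chrom <- normalize_chrom(as.character(snps$chrom))
    for (i in seq_len(n_sites)) {
      ## first seed base (genomic): frame position 2 from the mRNA 5' end
      on_plus <- sites$strand[i] == "+"
      seed_first <- if (on_plus) sites$genomic_start[i] + 1L
                    else sites$genomic_end[i] - 1L
      sel <- snp_chrom == normalize_chrom(as.character(sites$chrom[i]))
      if (!any(sel)) next
      rel <- if (on_plus) snps$pos[sel] - seed_first
             else seed_first - snps$pos[sel]
      rel <- rel[rel >= -flank & rel <= flank + window - 1L]
      for (r in rel) {
        lo <- max(-flank, r - window + 1L)
        hi <- min(flank, r)
        if (lo <= hi) {
          idx <- (lo:hi) + flank + 1L
          counts[idx] <- counts[idx] + 1L
        }
      }
    }
  }
  out <- data.frame(
    offset = offsets,
    count = as.integer(counts),
    density = if (n_sites > 0L) as.integer(counts) * 1000 / (n_sites * window)
              else rep(0, length(offsets))
  )
  attr(out, "n_sites") <- n_sites
  attr(out, "window") <- window
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Average SNP density over the seed windows
#'
#' The mean of the density at the `window` offsets whose windows start
#' on seed positions (offsets 0..window-1 with the defaults).
#'
#' @param profile A `density_profile` from [window_density()].
#' @return Numeric scalar, SNPs/kb.
#' @export
seed_average <- function(profile) {
  window <- attr(profile, "window")
  if (is.null(window)) window <- 6L
  sel <- profile$offset >= 0L & profile$offset <= window - 1L
  if (!any(sel)) stop("profile does not cover the seed offsets")
  mean(profile$density[sel])
}
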