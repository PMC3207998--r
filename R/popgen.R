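## Population differentiation of MRESS/CNM SNPs: Weir-Cockerham F_ST
## from per-group allele counts, Box-Cox normalization, group
## comparison, outlier selection and binned summaries.

#' Weir-Cockerham F_ST from per-group allele counts
#'
#' Multi-population Weir-Cockerham theta computed from allele counts
#' (allele-sample ANOVA form): with group allele-sample sizes n_i and
#' frequencies p_i, theta = (MSP - MSG) / (MSP + (n_c - 1) MSG), where
#' MSP is the among-group mean square of frequencies, MSG the
#' within-group (binomial) mean square, and n_c the variance-corrected
#' average sample size. Negative estimates are clamped to 0; SNPs
#' monomorphic across all groups return 0.
#'
#' @param counts Numeric matrix (SNPs x groups) of reference-allele
#'   counts.
#' @param sizes Numeric matrix (or vector recycled across SNPs) of
#'   allele-sample sizes per group.
#' @return Numeric vector of theta in \[0, 1\], one per SNP.
#' @export
fst_weir_cockerham <- function(counts, sizes) {
  counts <- as.matrix(counts)
  if (is.vector(sizes)) {
    sizes <- matrix(sizes, nrow = nrow(counts), ncol = ncol(counts),
                    byrow = TRUE)
  }
  sizes <- as.matrix(sizes)
  stopifnot(all(dim(counts) == dim(sizes)), all(counts <= sizes))
  vapply(seq_len(nrow(counts)), function(i) {
    n <- sizes[i, ]
    keep <- n > 0
    n <- n[keep]
    if (length(n) < 2L) stop("need at least 2 groups with nonzero sample size")
    p <- counts[i, keep] / n
    r <- length(n)
    N <- sum(n)
    pbar <- sum(n * p) / N
    if (pbar <= 0 || pbar >= 1) return(0) # monomorphic across groups
    msp <- sum(n * (p - pbar)^2) / (r - 1)
    msg <- sum(n * p * (1 - p)) / (N - r)
    nc <- (N - sum(n^2) / N) / (r - 1)
    denom <- msp + (nc - 1) * msg
    if (denom <= 0) return(0)
    min(1, max(0, (msp - msg) / denom))
  }, numeric(1L))
}

#' Fit a Box-Cox transformation by profile likelihood on a grid
#'
#' The power parameter lambda maximizes the Box-Cox profile
#' log-likelihood over a grid (default -3..3 in steps of 0.01). Zeros
#' (and any non-positive values) are offset by `eps` before fitting;
#' values still non-positive after the offset raise an error. The
#' transform is (x^lambda - 1) / lambda, or log(x) at lambda = 0.
#'
#' @param values Numeric vector of (near-)positive values.
#' @param eps Additive offset applied to values `<= 0` (default 1e-6).
#' @param grid Candidate lambda values.
#' @return List of class `boxcox_fit`: `lambda`, `transformed`, `eps`,
#'   and the profile (`grid`, `loglik`).
#' @export
boxcox_fit <- function(values, eps = 1e-6, grid = seq(-3, 3, by = 0.01)) {
  x <- values
  nz <- sum(x <= 0)
  if (nz > 0) x[x <= 0] <- x[x <= 0] + eps
  if (any(x <= 0)) stop("values non-positive after offset")
  n <- length(x)
  lx <- log(x)
  slx <- sum(lx)
  loglik <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) lx else (x^l - 1) / l
    v <- stats::var(y) * (n - 1) / n
    -n / 2 * log(v) + (l - 1) * slx
  }, numeric(1L))
  lambda <- grid[which.max(loglik)]
  transformed <- if (abs(lambda) < 1e-12) lx else (x^lambda - 1) / lambda
  out <- list(lambda = lambda, transformed = transformed, eps = eps,
              n_offset = nz, grid = grid, loglik = loglik)
  class(out) <- "boxcox_fit"
  out
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("Box-Cox fit: lambda = %.2f (%d values offset by %g)\n",
              x$lambda, x$n_offset, x$eps))
  invisible(x)
}

#' Unpaired Student's t-test between two transformed F_ST groups
#'
#' @param mre Transformed values for the MRESS/CNM group.
#' @param other Transformed values for the comparison group.
#' @return List `t`, `p`, `df` (two-sided, pooled-variance Student's
#'   t-test).
#' @export
compare_groups <- function(mre, other) {
  if (length(mre) < 2L || length(other) < 2L) stop("each group needs n >= 2")
  if (stats::var(mre) == 0 && stats::var(other) == 0) {
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(mre, other, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Select F_ST outliers
#'
#' Returns the records whose transformed value lies `k` or more
#' standard deviations above the mean of the MRESS/CNM distribution
#' (upper tail by default; `two_sided = TRUE` also takes the lower
#' tail). The mean and SD are computed over the flagged (`is_mre`)
#' records when the flag is present, otherwise over all records, and
#' selection is restricted to the same subset. `scale = "raw"` applies
#' the cut on the raw `fst` column instead.
#'
#' @param records Data frame with columns `rsid`, `fst`, `transformed`
#'   and optionally `is_mre`.
#' @param k SD multiplier (default 2).
#' @param two_sided Also select the lower tail (default `FALSE`).
#' @param scale `"transformed"` (default) or `"raw"`.
#' @return Subset of `records` (row order preserved).
#' @export
fst_outliers <- function(records, k = 2, two_sided = FALSE,
                         scale = c("transformed", "raw")) {
  scale <- match.arg(scale)
  if (nrow(records) < 2L) stop("need at least 2 records")
  pool <- if ("is_mre" %in% names(records) && any(records$is_mre)) {
    records[records$is_mre, , drop = FALSE]
  } else records
  v <- if (scale == "transformed") pool$transformed else pool$fst
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) { # degenerate distribution has no outliers
    out <- pool[integer(0), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  hi <- v >= m + k * s
  sel <- if (two_sided) hi | (v <= m - k * s) else hi
  out <- pool[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned F_ST counts for the MRESS/CNM group and a matched sample
#'
#' Bins raw F_ST values into `nbins` equal-width bins on \[0, 1\] (final
#' bin right-closed so 1.0 lands in the last bin). The comparison group
#' is down-sampled without replacement to the MRESS/CNM group's size
#' with a seeded RNG, matching group sizes before binning.
#'
#' @param mre_values F_ST values of the MRESS/CNM group.
#' @param other_values F_ST values of the comparison group (length >=
#'   `length(mre_values)`).
#' @param nbins Number of bins (default 10).
#' @param rng_seed Seed for the down-sampling.
#' @return Data frame `bin_lo`, `bin_hi`, `mre_count`, `other_count`.
#' @export
bin_counts <- function(mre_values, other_values, nbins = 10L, rng_seed = 1L) {
  stopifnot(all(mre_values >= 0 & mre_values <= 1),
            all(other_values >= 0 & other_values <= 1))
  n <- length(mre_values)
  if (length(other_values) < n) stop("comparison group smaller than MRE group")
  old_seed <- withr_seed(rng_seed)
  on.exit(restore_seed(old_seed))
  other <- sample(other_values, n)
  breaks <- seq(0, 1, length.out = nbins + 1L)
  bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  data.frame(
    bin_lo = breaks[-(nbins + 1L)],
    bin_hi = breaks[-1L],
    mre_count = tabulate(bin_of(mre_values), nbins),
    other_count = tabulate(bin_of(other), nbins)
  )
}
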