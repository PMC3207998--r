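test_that("fold_maf folds to the minor allele", {
  expect_equal(fold_maf(0.992), 0.008)
  expect_equal(fold_maf(0.306), 0.306)
  expect_equal(fold_maf(0.5), 0.5)
  expect_error(fold_maf(1.2), "outside")
  set.seed(201)
  f <- runif(50)
  expect_equal(fold_maf(f), fold_maf(1 - f))       # symmetry
  expect_equal(fold_maf(fold_maf(f)), fold_maf(f)) # idempotence
})

test_that("snp_maf folds and maximizes over population columns", {
  snps <- data.frame(rsid = c("a", "b", "c"),
                     af_eur = c(0.95, NA, NA),
                     af_afr = c(0.40, 0.02, NA))
  expect_equal(snp_maf(snps), c(0.40, 0.02, NA))
  ## a precomputed maf column wins
  snps$maf <- c(0.1, 0.2, 0.3)
  expect_equal(snp_maf(snps), c(0.1, 0.2, 0.3))
  expect_true(all(is.na(snp_maf(data.frame(rsid = "x")))))
})

test_that("snp_in_site maps genomic positions to MRE positions", {
  site_p <- list(chrom = "3", genomic_start = 148459985L,
                 genomic_end = 148459992L, strand = "+")
  snp <- list(chrom = "3", pos = 148459988L)
  ## miR-position numbering: frame index 4 from the 5' end pairs miR 5
  expect_identical(snp_in_site(site_p, snp), 5L)
  expect_identical(snp_in_site(site_p, snp, numbering = "mrna"), 4L)

  ## boundary exclusion and chromosome normalization
  expect_true(is.na(snp_in_site(site_p, list(chrom = "3", pos = 148459984L))))
  expect_true(is.na(snp_in_site(site_p, list(chrom = "4", pos = 148459988L))))
  expect_identical(snp_in_site(site_p, list(chrom = "chr3", pos = 148459985L)), 8L)

  ## minus strand: genomic_end is the mRNA 5'-most base, pairing miR 8
  site_m <- list(chrom = "1", genomic_start = 551L, genomic_end = 558L,
                 strand = "-")
  expect_identical(snp_in_site(site_m, list(chrom = "1", pos = 558L)), 8L)

  ## all 8 offsets on both strands against direct arithmetic
  for (d in 0:7) {
    expect_identical(
      snp_in_site(site_p, list(chrom = "3", pos = 148459985L + d)), 8L - d)
    expect_identical(
      snp_in_site(site_m, list(chrom = "1", pos = 551L + d)), d + 1L)
    expect_identical(
      snp_in_site(site_m, list(chrom = "1", pos = 551L + d),
                  numbering = "mrna"), 8L - d)
  }
})

test_that("disruption verdicts match exhaustive allele substitution", {
  w <- tiny_two_strand_world()
  hits <- scan_utrs(w$utrs, w$mirs, w$placements)
  for (nm in c("utrP", "utrM")) {
    site <- hits[hits$utr_name == nm, ]
    utr_seq <- w$utrs$seq[w$utrs$name == nm]
    window <- substr(utr_seq, site$window_start, site$window_start + 7L)
    for (widx in 1:8) {
      gpos <- if (site$strand == "+") site$genomic_start + widx - 1L
              else site$genomic_end - widx + 1L
      ref_mrna <- substr(window, widx, widx)
      ref_g <- if (site$strand == "+") ref_mrna else oracle_revcomp(ref_mrna)
      for (alt_mrna in setdiff(c("A", "C", "G", "T"), ref_mrna)) {
        alt_g <- if (site$strand == "+") alt_mrna else oracle_revcomp(alt_mrna)
        snp <- list(rsid = "rsT", chrom = site$chrom, pos = gpos,
                    ref = ref_g, alt = alt_g)
        call <- classify_disruption(site, snp, w$mirs$seq, utr_seq)
        ## oracle: substitute on the mRNA window and reclassify
        aw <- window
        substr(aw, widx, widx) <- alt_mrna
        expect_identical(call$ref_class, "8mer")
        expect_identical(call$alt_class, oracle_classify(aw, w$mirs$seq))
        want <- if (is.na(call$alt_class)) "abolished"
                else if (call$alt_class == "8mer") "unchanged"
                else "downgraded"
        expect_identical(call$verdict, want)
      }
    }
  }
})

test_that("a position-1 change to A upgrades a 7mer-m8 to an 8mer", {
  mir <- "TGAGGTAGTAGGTTGTATAGT"
  pat <- build_site_patterns(mir, "m")
  utr <- paste0(strrep("T", 20), pat$p7m8, "G", strrep("T", 20))
  mirs <- data.frame(name = "m", seq = mir)
  utrs <- data.frame(name = "u", seq = utr)
  pl <- data.frame(name = "u", chrom = "1", start = 0L,
                   end = nchar(utr), strand = "+")
  hits <- scan_utrs(utrs, mirs, pl)
  expect_identical(hits$site_type, "7mer-m8")
  ## the frame's 8th mRNA base (miR position 1) is the trailing G
  snp <- list(rsid = "rsU", chrom = "1", pos = hits$genomic_end,
              ref = "G", alt = "A")
  call <- classify_disruption(hits[1, ], snp, mir, utr)
  expect_identical(call$pos_in_mre, 1L)
  expect_identical(call$alt_class, "8mer")
  expect_identical(call$verdict, "upgraded")
})

test_that("reference-allele mismatches are data-integrity errors", {
  w <- tiny_two_strand_world()
  hits <- scan_utrs(w$utrs, w$mirs, w$placements)
  site <- hits[hits$utr_name == "utrP", ]
  utr_seq <- w$utrs$seq[w$utrs$name == "utrP"]
  truth <- substr(utr_seq, site$window_start, site$window_start)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  snp <- list(rsid = "rsB", chrom = site$chrom, pos = site$genomic_start,
              ref = wrong, alt = truth)
  expect_error(classify_disruption(site, snp, w$mirs$seq, utr_seq),
               "mismatch")
})

test_that("call_disruptions emits one call per overlapping interaction", {
  ## a 9-base region carrying 8mer frames for two different miRs,
  ## shifted by one base; a SNP in the shared span yields two calls
  W <- "CGTCGTAAA"
  mk_mir <- function(frame8) paste0("A", oracle_revcomp(substr(frame8, 1, 7)),
                                    strrep("C", 13))
  m1 <- mk_mir(substr(W, 1, 8))
  m2 <- mk_mir(substr(W, 2, 9))
  utr <- paste0(strrep("T", 30), W, strrep("T", 30))
  mirs <- data.frame(name = c("m1", "m2"), seq = c(m1, m2))
  utrs <- data.frame(name = "u", seq = utr)
  pl <- data.frame(name = "u", chrom = "1", start = 0L, end = nchar(utr),
                   strand = "+")
  hits <- scan_utrs(utrs, mirs, pl)
  h8 <- hits[hits$site_type == "8mer", ]
  expect_setequal(h8$mir_name, c("m1", "m2"))
  expect_identical(sort(h8$window_start), c(31L, 32L))

  pos <- h8$genomic_start[h8$mir_name == "m1"] + 3L # inside both frames
  u <- pos # start0 = 0, so UTR offset equals genomic position
  ref <- substr(utr, u, u)
  snps <- data.frame(rsid = "rsS", chrom = "1", pos = pos, ref = ref,
                     alt = setdiff(c("A", "C", "G", "T"), ref)[1])
  calls <- call_disruptions(h8, snps, mirs, utrs)
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$mir_name, c("m1", "m2"))
})

test_that("seed-type summaries partition the calls", {
  expect_identical(sum(summarize_by_seed_type(
    data.frame(ref_class = character(0)))), 0L)
  calls <- data.frame(ref_class = c(rep("8mer", 3), rep("7mer-m8", 2)))
  counts <- summarize_by_seed_type(calls)
  expect_identical(unname(counts["8mer"]), 3L)
  expect_identical(unname(counts["7mer-m8"]), 2L)
  expect_identical(sum(counts), nrow(calls))
})
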