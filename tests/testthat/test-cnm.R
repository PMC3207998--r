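test_that("extract_window centers the SNP with sentinel padding", {
  utr <- rand_dna_fixed <- {
    set.seed(301)
    rand_dna(45)
  }
  pl <- data.frame(name = "u", chrom = "1", start = 0L, end = 45L,
                   strand = "+")
  snp <- list(rsid = "rs1", chrom = "1", pos = 23L,
              ref = substr(utr, 23, 23),
              alt = setdiff(c("A", "C", "G", "T"), substr(utr, 23, 23))[1])
  w <- extract_window(utr, snp, pl)
  expect_identical(w$seq_ref, utr)                # SNP at 23 of a 45-mer
  expect_identical(w$snp_offset, 23L)
  expect_identical(nchar(w$seq_alt), 45L)
  diffs <- which(strsplit(w$seq_ref, "")[[1]] != strsplit(w$seq_alt, "")[[1]])
  expect_identical(diffs, 23L)
  expect_identical(substr(w$seq_alt, 23, 23), snp$alt)

  ## SNP near the 5' end: left sentinel pad
  snp5 <- list(rsid = "rs2", chrom = "1", pos = 5L,
               ref = substr(utr, 5, 5), alt = "A")
  if (snp5$ref == "A") snp5$alt <- "G"
  w5 <- extract_window(utr, snp5, pl)
  expect_identical(substr(w5$seq_ref, 1, 18), strrep("N", 18))
  expect_identical(substr(w5$seq_ref, 19, 19 + 26), substr(utr, 1, 27))

  ## SNP outside the UTR is skipped with a warning
  out <- list(rsid = "rs3", chrom = "1", pos = 99L, ref = "A", alt = "G")
  expect_warning(res <- extract_window(utr, out, pl), "outside")
  expect_null(res)

  ## minus-strand UTR: genomic alleles are complemented onto the mRNA
  plm <- data.frame(name = "u", chrom = "1", start = 0L, end = 45L,
                    strand = "-")
  u_mrna <- substr(utr, 45 - 10 + 1, 45 - 10 + 1) # genomic pos 10 -> mRNA 36
  snpm <- list(rsid = "rs4", chrom = "1", pos = 10L,
               ref = reverse_complement(u_mrna), alt = "A")
  if (snpm$alt == snpm$ref) snpm$alt <- "C"
  wm <- extract_window(utr, snpm, plm)
  expect_identical(substr(wm$seq_ref, 23, 23), u_mrna)
  expect_identical(substr(wm$seq_alt, 23, 23),
                   reverse_complement(snpm$alt))
})

test_that("duplex scorer matches a brute-force alignment oracle", {
  params <- proxy_params()
  set.seed(302)
  ## perfect 21-nt duplex: all Watson-Crick, seed doubled
  mir <- rand_dna(21)
  perfect <- reverse_complement(mir)
  sc <- duplex_score(mir, perfect, params)
  expect_equal(sc$pairing_score, 5 * (21 + 7)) # 140 on the proxy scale
  expect_lt(sc$energy_proxy, -40)

  ## a single seed mismatch scores strictly lower
  mm <- perfect
  j <- nchar(mm) - 3L # pairs miR position 4 (seed)
  old <- substr(mm, j, j)
  substr(mm, j, j) <- setdiff(c("A", "C", "G", "T"),
                              c(old, "G", "T"))[1] # avoid wobble rescue
  expect_lt(duplex_score(mir, mm, params)$pairing_score, sc$pairing_score)

  ## oracle equivalence on small random pairs (recursion is exponential)
  for (i in 1:10) {
    m <- rand_dna(sample(8:10, 1))
    t <- rand_dna(sample(8:12, 1))
    expect_equal(duplex_score(m, t, params)$pairing_score,
                 oracle_duplex_score(m, t, params))
  }
})

test_that("energy proxy decreases with GC pairing, all else fixed", {
  params <- proxy_params()
  for (k in 0:5) {
    mir <- paste0(strrep("G", k), strrep("A", 21 - k))
    target <- reverse_complement(mir)
    e <- duplex_score(mir, target, params)$energy_proxy
    expect_equal(e, -(3 * k + 2 * (21 - k)))
  }
})

test_that("created sites are detected exactly at SNP-containing frames", {
  set.seed(303)
  mir <- rand_dna(21)
  pat <- build_site_patterns(mir, "m")
  mirs <- data.frame(name = "m", seq = mir)
  params <- proxy_params()

  ## plant a full-complementarity site whose seed is broken by the ref
  embed <- reverse_complement(mir)
  substr(embed, 21, 21) <- "A"                     # A1 position
  frame_in_embed <- 14L                            # embed[14..21] is the frame
  b <- 4L                                          # frame seed position
  alt_base <- substr(embed, frame_in_embed + b - 1L, frame_in_embed + b - 1L)
  ref_base <- setdiff(c("A", "C", "G", "T"), alt_base)[1]
  broken <- embed
  substr(broken, frame_in_embed + b - 1L, frame_in_embed + b - 1L) <- ref_base

  lead <- 10L
  seq_ref <- paste0(rand_dna(lead), broken, rand_dna(45 - lead - 21))
  snp_off <- lead + frame_in_embed + b - 1L
  ## shift so the SNP sits at offset 23 of 45
  pad <- 23L - snp_off
  seq_ref <- if (pad > 0) paste0(rand_dna(pad), substr(seq_ref, 1, 45 - pad))
             else substr(paste0(seq_ref, rand_dna(-pad)), 1 - pad, 45 - pad)
  win <- structure(list(rsid = "rsC", seq_ref = seq_ref,
                        seq_alt = `substr<-`(seq_ref, 23L, 23L, alt_base),
                        snp_offset = 23L, strand = "+"),
                   class = "snp_window")
  hits <- detect_created_sites(win, mirs, params)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_type, "8mer")
  expect_true(hits$window_offset >= 16L && hits$window_offset <= 23L)
  expect_gte(hits$pairing_score, params$score_min)
  expect_lte(hits$energy_proxy, params$energy_max)

  ## an intact site in a frame NOT containing offset 23 is never a hit
  far <- paste0(pat$p8, rand_dna(37))              # frame 1..8 only
  win2 <- structure(list(rsid = "rsD", seq_ref = far,
                         seq_alt = `substr<-`(far, 23L, 23L,
                                              setdiff(c("A","C","G","T"),
                                                      substr(far, 23, 23))[1]),
                         snp_offset = 23L, strand = "+"),
                    class = "snp_window")
  hits2 <- detect_created_sites(win2, mirs, params)
  expect_identical(nrow(hits2), 0L)

  ## no creation when the ref already carries the site (strict increase)
  intact <- win
  intact$seq_ref <- intact$seq_alt
  hits3 <- detect_created_sites(intact, mirs, params)
  expect_identical(nrow(hits3), 0L)
})

test_that("creation is allele-asymmetric with disruption calling", {
  ## swapping ref<->alt turns the created site into a disrupted one
  set.seed(304)
  w <- simulate_world(sim_config(rng_seed = 17, n_planted_cnm = 10L,
                                 n_snps = 0L))
  cnm <- call_created_sites(w$snps, w$utrs, w$placements, w$mirs)
  expect_gte(nrow(cnm), 10L)
  swapped <- w$snps
  tmp <- swapped$ref
  swapped$ref <- swapped$alt
  swapped$alt <- tmp
  ## with the alleles swapped the alternate-bearing sequence is the
  ## reference; rebuild the UTRs accordingly and scan
  utrs2 <- w$utrs
  for (i in seq_len(nrow(w$truth$cnm))) {
    tr <- w$truth$cnm[i, ]
    snp <- w$snps[w$snps$rsid == tr$rsid, ]
    ui <- match(tr$utr_name, utrs2$name)
    pl <- w$placements[w$placements$name == tr$utr_name, ]
    u <- if (pl$strand == "+") snp$pos - pl$start else pl$end - snp$pos + 1L
    alt_mrna <- if (pl$strand == "+") snp$alt else reverse_complement(snp$alt)
    substr(utrs2$seq[ui], u, u) <- alt_mrna
  }
  hits2 <- scan_utrs(utrs2, w$mirs, w$placements)
  calls <- call_disruptions(hits2, swapped, w$mirs, utrs2)
  ## every planted creation event shows up as a disruption of the same
  ## miR's site after the swap
  key_truth <- paste(w$truth$cnm$rsid, w$truth$cnm$mir_name)
  key_calls <- paste(calls$rsid, calls$mir_name)
  expect_true(all(key_truth %in% key_calls))
  expect_true(all(calls$verdict[key_calls %in% key_truth] %in%
                    c("abolished", "downgraded")))
})
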