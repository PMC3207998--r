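## Synthetic-data generator: every input the pipeline consumes, with
## controllable ground truth — planted seed sites, SNPs placed inside or
## outside seed frames, planted creation events, Balding-Nichols
## population frequencies, block LD by correlated allele copying, and a
## GWAS catalog with a controllable enrichment of MRESS/CNM loci.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study conditions used
#' throughout the test-suite and the analysis scripts: a desk-scale
#' world of 12 mature miRs (21 nt) against 30 UTRs of 2 kb, 60 planted
#' seed sites across the four classes, 20 planted creation events, 400
#' survey SNPs of which 30% fall inside planted seed frames, four
#' ancestry groups of 120 allele samples each with Balding-Nichols
#' differentiation F = 0.25 for MRESS/CNM SNPs versus 0.10 for the
#' remainder, LD blocks of 5 SNPs targeting r-squared 0.9, and a
#' 40-record GWAS catalog drawn with 5-fold odds for loci tagging an
#' MRESS/CNM SNP.
#'
#' @param rng_seed Integer seed controlling the whole world.
#' @param n_mirs,mir_length miR count and length.
#' @param n_utrs,utr_length UTR count and length.
#' @param n_planted_sites Named integer vector of planted sites per
#'   class (`8mer`, `7mer-m8`, `7mer-A1`, `6mer`).
#' @param n_planted_cnm Planted creation events (full-complementarity
#'   sites broken by the reference allele and restored by the alternate).
#' @param n_snps Survey SNPs (creation-event SNPs are additional).
#' @param p_snp_in_seed Probability a survey SNP is placed inside a
#'   planted 8-position seed frame.
#' @param populations Named vector of allele-sample sizes per group.
#' @param f_mre,f_bg Balding-Nichols F for MRESS/CNM vs background SNPs.
#' @param ld_block_size,target_r2,n_hap LD block size, target pairwise
#'   r-squared within blocks, and haplotypes used for the correlated
#'   copying.
#' @param catalog_size,enrichment_factor GWAS catalog size and the odds
#'   multiplier for catalog SNPs whose LD block contains an MRESS/CNM
#'   SNP.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_mirs = 12L, mir_length = 21L,
                       n_utrs = 30L, utr_length = 2000L,
                       n_planted_sites = c("8mer" = 20L, "7mer-m8" = 20L,
                                           "7mer-A1" = 10L, "6mer" = 10L),
                       n_planted_cnm = 20L,
                       n_snps = 400L, p_snp_in_seed = 0.3,
                       populations = c(ASN = 120L, AFR = 120L,
                                       EUR = 120L, AMR = 120L),
                       f_mre = 0.25, f_bg = 0.10,
                       ld_block_size = 5L, target_r2 = 0.9, n_hap = 200L,
                       catalog_size = 40L, enrichment_factor = 5) {
  stopifnot(n_mirs > 0, mir_length >= 8, n_utrs > 0, utr_length >= 64,
            all(n_planted_sites >= 0), n_planted_cnm >= 0, n_snps >= 0,
            p_snp_in_seed >= 0, p_snp_in_seed <= 1,
            all(populations > 0), f_mre > 0, f_mre < 1, f_bg > 0, f_bg < 1,
            ld_block_size >= 1, target_r2 >= 0, target_r2 <= 1,
            catalog_size >= 0, enrichment_factor > 0)
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

#' Balding-Nichols per-population allele frequencies
#'
#' Draws population frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F)
#' around the ancestral frequency `p_anc`.
#'
#' @param p_anc Ancestral allele frequency (scalar or vector).
#' @param F Differentiation parameter in (0, 1).
#' @param n_groups Number of populations.
#' @return Matrix (`length(p_anc)` x `n_groups`) of frequencies.
#' @export
balding_nichols <- function(p_anc, F, n_groups) {
  k <- (1 - F) / F
  m <- vapply(seq_len(n_groups), function(g) {
    stats::rbeta(length(p_anc), p_anc * k, (1 - p_anc) * k)
  }, numeric(length(p_anc)))
  matrix(m, nrow = length(p_anc), ncol = n_groups)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## pick an offset whose [o, o + len - 1] does not intersect occupied rows
place_nonoverlapping <- function(occupied, utr_len, len, max_tries = 500L) {
  for (t in seq_len(max_tries)) {
    o <- sample.int(utr_len - len + 1L, 1L)
    if (nrow(occupied) == 0L ||
        !any(o <= occupied$hi & (o + len - 1L) >= occupied$lo)) {
      return(o)
    }
  }
  NA_integer_
}

#' Simulate a complete synthetic input bundle
#'
#' Generates miRs, UTRs with genomic placements on both strands, planted
#' seed sites of all four classes (written so the planted class is the
#' maximal class at that frame), planted creation events (a
#' full-complementarity site whose reference allele breaks the seed and
#' whose alternate restores it), survey SNPs inside and outside seed
#' frames, Balding-Nichols per-group allele frequencies with class-
#' specific F, block LD fabricated by correlated allele copying, and a
#' GWAS catalog enriched for loci tagging MRESS/CNM SNPs. Fully
#' deterministic given `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_world`: `mirs`, `utrs`, `placements`,
#'   `snps`, `ld`, `catalog`, `group_counts`, `truth` (list `sites`,
#'   `cnm`, `snps`), `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- withr_seed(config$rng_seed)
  on.exit(restore_seed(old_seed))

  mirs <- data.frame(
    name = sprintf("mir-%03d", seq_len(config$n_mirs)),
    seq = vapply(seq_len(config$n_mirs), function(i)
      random_dna(config$mir_length), character(1L)),
    family_conserved = TRUE,
    stringsAsFactors = FALSE
  )
  pats <- lapply(seq_len(nrow(mirs)),
                 function(i) build_site_patterns(mirs$seq[i], mirs$name[i]))

  utr_seqs <- vapply(seq_len(config$n_utrs), function(i)
    random_dna(config$utr_length), character(1L))
  utrs <- data.frame(name = sprintf("utr%03d", seq_len(config$n_utrs)),
                     seq = utr_seqs, stringsAsFactors = FALSE)
  placements <- data.frame(
    name = utrs$name,
    chrom = as.character(seq_len(config$n_utrs)),
    start = 1000L,
    end = 1000L + config$utr_length,
    strand = rep(c("+", "-"), length.out = config$n_utrs),
    stringsAsFactors = FALSE
  )
  occupied <- lapply(seq_len(config$n_utrs),
                     function(i) data.frame(lo = integer(), hi = integer()))

  ## ---- planted seed sites -------------------------------------------------
  other_than <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  truth_sites <- list()
  for (cls in names(config$n_planted_sites)) {
    for (k in seq_len(config$n_planted_sites[[cls]])) {
      mi <- sample.int(nrow(mirs), 1L)
      ui <- sample.int(nrow(utrs), 1L)
      o <- place_nonoverlapping(occupied[[ui]], config$utr_length, 8L)
      if (is.na(o)) {
        stop(sprintf("infeasible planting: %d sites requested, UTR capacity exhausted",
                     sum(config$n_planted_sites)))
      }
      p <- pats[[mi]]
      win <- switch(cls,
        "8mer" = p$p8,
        "7mer-m8" = paste0(p$p7m8, other_than(c("A"))),
        "7mer-A1" = paste0(other_than(p$m8_base), p$p6, "A"),
        "6mer" = paste0(other_than(p$m8_base), p$p6, other_than("A")))
      substr(utrs$seq[ui], o, o + 7L) <- win
      occupied[[ui]] <- rbind(occupied[[ui]],
                              data.frame(lo = o, hi = o + 7L))
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        utr_name = utrs$name[ui], mir_name = mirs$name[mi],
        window_start = o, site_type = cls, stringsAsFactors = FALSE)
    }
  }
  truth_sites <- if (length(truth_sites) > 0L) do.call(rbind, truth_sites)
    else data.frame(utr_name = character(), mir_name = character(),
                    window_start = integer(), site_type = character())

  ## ---- planted creation events -------------------------------------------
  ## Embed the full reverse complement of the miR (a strong site, as a
  ## duplex-filter-passing prediction would be), force the A1 position,
  ## then break one internal seed base with the reference allele.
  mrna_pos_to_genomic <- function(ui, u) {
    if (placements$strand[ui] == "+") placements$start[ui] + u
    else placements$end[ui] - u + 1L
  }
  mrna_base_to_genomic <- function(ui, b) {
    if (placements$strand[ui] == "+") b else complement_base(b)
  }

  truth_cnm <- list()
  snp_rows <- list()
  rs_counter <- 0L
  next_rsid <- function() {
    rs_counter <<- rs_counter + 1L
    sprintf("rs%06d", rs_counter)
  }
  m <- config$mir_length
  for (k in seq_len(config$n_planted_cnm)) {
    mi <- sample.int(nrow(mirs), 1L)
    ui <- sample.int(nrow(utrs), 1L)
    o <- place_nonoverlapping(occupied[[ui]], config$utr_length, m)
    if (is.na(o)) stop("infeasible planting of creation events")
    embed <- reverse_complement(mirs$seq[mi])
    substr(embed, m, m) <- "A" # literal A at the A1 position
    substr(utrs$seq[ui], o, o + m - 1L) <- embed
    frame_start <- o + m - 8L
    b <- sample(2:7, 1L) # internal seed position of the frame
    u <- frame_start + b - 1L
    alt_mrna <- substr(utrs$seq[ui], u, u)
    ref_mrna <- other_than(alt_mrna)
    substr(utrs$seq[ui], u, u) <- ref_mrna
    occupied[[ui]] <- rbind(occupied[[ui]],
                            data.frame(lo = o, hi = o + m - 1L))
    rsid <- next_rsid()
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      rsid = rsid, utr_idx = ui, u = u,
      ref = mrna_base_to_genomic(ui, ref_mrna),
      alt = mrna_base_to_genomic(ui, alt_mrna),
      in_seed = FALSE, is_cnm = TRUE, stringsAsFactors = FALSE)
    truth_cnm[[length(truth_cnm) + 1L]] <- data.frame(
      rsid = rsid, utr_name = utrs$name[ui], mir_name = mirs$name[mi],
      window_offset = frame_start, site_type = "8mer",
      stringsAsFactors = FALSE)
  }
  truth_cnm <- if (length(truth_cnm) > 0L) do.call(rbind, truth_cnm)
    else data.frame(rsid = character(), utr_name = character(),
                    mir_name = character(), window_offset = integer(),
                    site_type = character())

  ## ---- survey SNPs --------------------------------------------------------
  ## Out-of-seed SNPs avoid every seed frame the reference sequences carry
  ## (planted or incidental), so seed-frame SNPs arrive only through
  ## p_snp_in_seed and the truth labels are exact.
  ref_hits <- scan_utrs(utrs, mirs)
  frame_pos <- lapply(seq_len(config$n_utrs), function(ui) {
    h <- ref_hits[ref_hits$utr_name == utrs$name[ui], , drop = FALSE]
    unique(unlist(lapply(h$window_start, function(s) s:(s + 7L))))
  })
  taken <- lapply(seq_len(config$n_utrs), function(i) integer())
  for (r in seq_len(length(snp_rows))) {
    taken[[snp_rows[[r]]$utr_idx]] <- c(taken[[snp_rows[[r]]$utr_idx]],
                                        snp_rows[[r]]$u)
  }
  site_frames <- truth_sites
  for (k in seq_len(config$n_snps)) {
    placed <- FALSE
    for (t in seq_len(500L)) {
      if (nrow(site_frames) > 0L && stats::runif(1) < config$p_snp_in_seed) {
        si <- sample.int(nrow(site_frames), 1L)
        ui <- match(site_frames$utr_name[si], utrs$name)
        u <- site_frames$window_start[si] + sample.int(8L, 1L) - 1L
        in_seed <- TRUE
      } else {
        ui <- sample.int(config$n_utrs, 1L)
        u <- sample.int(config$utr_length, 1L)
        if (nrow(occupied[[ui]]) > 0L &&
            any(u >= occupied[[ui]]$lo & u <= occupied[[ui]]$hi)) next
        if (u %in% frame_pos[[ui]]) next
        in_seed <- FALSE
      }
      if (u %in% taken[[ui]]) next
      taken[[ui]] <- c(taken[[ui]], u)
      ref_mrna <- substr(utrs$seq[ui], u, u)
      alt_mrna <- other_than(ref_mrna)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        rsid = next_rsid(), utr_idx = ui, u = u,
        ref = mrna_base_to_genomic(ui, ref_mrna),
        alt = mrna_base_to_genomic(ui, alt_mrna),
        in_seed = in_seed, is_cnm = FALSE, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place survey SNP ", k)
  }
  sr <- do.call(rbind, snp_rows)
  snps <- data.frame(
    rsid = sr$rsid,
    chrom = placements$chrom[sr$utr_idx],
    pos = vapply(seq_len(nrow(sr)), function(i)
      mrna_pos_to_genomic(sr$utr_idx[i], sr$u[i]), integer(1L)),
    ref = sr$ref, alt = sr$alt, stringsAsFactors = FALSE
  )
  is_mre <- sr$in_seed | sr$is_cnm

  ## ---- population frequencies (Balding-Nichols) ---------------------------
  pops <- names(config$populations)
  p_anc <- stats::runif(nrow(snps), 0.05, 0.95)
  freqs <- matrix(NA_real_, nrow(snps), length(pops),
                  dimnames = list(NULL, pops))
  for (i in seq_len(nrow(snps))) {
    F <- if (is_mre[i]) config$f_mre else config$f_bg
    freqs[i, ] <- balding_nichols(p_anc[i], F, length(pops))[1L, ]
  }
  gc_rows <- list()
  for (g in seq_along(pops)) {
    size <- config$populations[[g]]
    cnt <- stats::rbinom(nrow(snps), size, freqs[, g])
    gc_rows[[g]] <- data.frame(rsid = snps$rsid, group = pops[g],
                               count = cnt, size = size,
                               stringsAsFactors = FALSE)
    snps[[paste0("af_", tolower(pops[g]))]] <- freqs[, g]
  }
  group_counts <- do.call(rbind, gc_rows)
  snps$maf <- apply(freqs, 1L, function(p) max(fold_maf(p)))

  ## ---- block LD by correlated allele copying ------------------------------
  ord <- order(as.integer(snps$chrom), snps$pos)
  block <- integer(nrow(snps))
  bid <- 0L
  for (ch in unique(snps$chrom[ord])) {
    idx <- ord[snps$chrom[ord] == ch]
    nb <- ceiling(length(idx) / config$ld_block_size)
    for (j in seq_len(nb)) {
      bid <- bid + 1L
      sel <- idx[((j - 1L) * config$ld_block_size + 1L):
                   min(j * config$ld_block_size, length(idx))]
      block[sel] <- bid
    }
  }
  snps$ld_block <- block

  flip <- (1 - sqrt(config$target_r2)) / 2
  ld_rows <- list()
  for (b in unique(block)) {
    sel <- which(block == b)
    if (length(sel) < 2L) next
    q <- mean(freqs[sel[1L], ])
    lead <- stats::rbinom(config$n_hap, 1L, q)
    hap <- vapply(sel, function(i) {
      if (i == sel[1L]) return(lead)
      fl <- stats::rbinom(config$n_hap, 1L, flip)
      as.integer(xor(lead, fl))
    }, integer(config$n_hap))
    for (a in seq_along(sel)) {
      for (bb in seq_along(sel)) {
        if (bb <= a) next
        r2 <- suppressWarnings(stats::cor(hap[, a], hap[, bb])^2)
        if (is.na(r2)) r2 <- 0
        ld_rows[[length(ld_rows) + 1L]] <- data.frame(
          rsid_a = snps$rsid[sel[a]], rsid_b = snps$rsid[sel[bb]],
          r2 = r2, stringsAsFactors = FALSE)
      }
    }
  }
  ld <- if (length(ld_rows) > 0L) do.call(rbind, ld_rows)
    else data.frame(rsid_a = character(), rsid_b = character(),
                    r2 = numeric())

  ## ---- GWAS catalog -------------------------------------------------------
  mre_blocks <- unique(snps$ld_block[is_mre])
  w <- ifelse(snps$ld_block %in% mre_blocks, config$enrichment_factor, 1)
  traits <- c("lipid levels", "type 2 diabetes", "height", "asthma",
              "psoriasis", "blood pressure", "triglycerides",
              "autoimmune disease")
  n_cat <- min(config$catalog_size, nrow(snps))
  pick <- sample.int(nrow(snps), n_cat, prob = w)
  catalog <- data.frame(
    rsid = snps$rsid[pick],
    trait = sample(traits, n_cat, replace = TRUE),
    pvalue = 10^-stats::runif(n_cat, 5.1, 25),
    pmid = sample(10000000:29999999, n_cat),
    stringsAsFactors = FALSE
  )

  truth_snps <- data.frame(rsid = snps$rsid,
                           utr_name = utrs$name[sr$utr_idx],
                           utr_pos = sr$u,
                           in_seed = sr$in_seed, is_cnm = sr$is_cnm,
                           is_mre = is_mre, stringsAsFactors = FALSE)

  out <- list(mirs = mirs, utrs = utrs, placements = placements,
              snps = snps, ld = ld, catalog = catalog,
              group_counts = group_counts,
              truth = list(sites = truth_sites, cnm = truth_cnm,
                           snps = truth_snps),
              config = config)
  class(out) <- "sim_world"
  out
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf(
    "synthetic world: %d miRs, %d UTRs, %d planted sites, %d creation events, %d SNPs\n",
    nrow(x$mirs), nrow(x$utrs), nrow(x$truth$sites), nrow(x$truth$cnm),
    nrow(x$snps)))
  invisible(x)
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits miRs and UTRs as FASTA, placements as BED6, SNPs as VCF (with
#' per-population frequencies in INFO), and LD / catalog /
#' group-count / truth tables as TSV.
#'
#' @param world A `sim_world` from [simulate_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$mirs, file.path(dir, "mirs.fasta"))
  write_fasta(world$utrs, file.path(dir, "utrs.fasta"))
  write_bed(world$placements, file.path(dir, "utrs.bed"))
  write_snvs_vcf(world$snps, file.path(dir, "snps.vcf"))
  utils::write.table(world$ld, file.path(dir, "ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$catalog, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$group_counts, file.path(dir, "group_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth$cnm, file.path(dir, "truth_cnm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic world back through the standard readers
#'
#' @param dir Directory written by [write_world()].
#' @param populations Population labels whose `AF_<POP>` INFO keys to
#'   parse from the VCF.
#' @return List with the same components as [simulate_world()] (minus
#'   `config`).
#' @export
read_world <- function(dir, populations = c("ASN", "AFR", "EUR", "AMR")) {
  af_keys <- stats::setNames(paste0("AF_", populations),
                             tolower(populations))
  list(
    mirs = read_fasta(file.path(dir, "mirs.fasta")),
    utrs = read_fasta(file.path(dir, "utrs.fasta")),
    placements = read_bed(file.path(dir, "utrs.bed")),
    snps = read_snvs_vcf(file.path(dir, "snps.vcf"), af_keys = af_keys),
    ld = read_tsv_meta(file.path(dir, "ld.tsv")),
    catalog = read_tsv_meta(file.path(dir, "catalog.tsv")),
    group_counts = read_tsv_meta(file.path(dir, "group_counts.tsv")),
    truth = list(
      sites = read_tsv_meta(file.path(dir, "truth_sites.tsv")),
      cnm = read_tsv_meta(file.path(dir, "truth_cnm.tsv")),
      snps = read_tsv_meta(file.path(dir, "truth_snps.tsv"))
    )
  )
}

#' Simulate a SNP universe for enrichment calibration studies
#'
#' A lightweight generator for the GWAS-enrichment stage alone: a
#' universe of SNPs with folded MAFs, a configurable fraction flagged as
#' MRESS/CNM members, and (optionally) consecutive LD blocks with a
#' fixed pairwise r-squared.
#'
#' @param n_snps Universe size.
#' @param set_fraction Fraction of SNPs in the MRESS/CNM set.
#' @param ld_block_size Block size; `1` (default) disables LD.
#' @param block_r2 Pairwise r-squared recorded within blocks.
#' @param maf_range Range of folded MAFs (uniform).
#' @param rng_seed Integer seed.
#' @return List `universe` (data frame `rsid`, `maf`, `in_set`,
#'   `ld_block`) and `ld` (pairwise table, `NULL` without LD).
#' @export
simulate_snp_universe <- function(n_snps = 10000L, set_fraction = 0.05,
                                  ld_block_size = 1L, block_r2 = 0.9,
                                  maf_range = c(0.01, 0.5), rng_seed = 1L) {
  old_seed <- withr_seed(rng_seed)
  on.exit(restore_seed(old_seed))
  universe <- data.frame(
    rsid = sprintf("u%06d", seq_len(n_snps)),
    maf = stats::runif(n_snps, maf_range[1L], maf_range[2L]),
    in_set = stats::runif(n_snps) < set_fraction,
    ld_block = if (ld_block_size > 1L)
      rep(seq_len(ceiling(n_snps / ld_block_size)),
          each = ld_block_size)[seq_len(n_snps)]
    else seq_len(n_snps),
    stringsAsFactors = FALSE
  )
  ld <- NULL
  if (ld_block_size > 1L) {
    rows <- list()
    for (b in unique(universe$ld_block)) {
      sel <- which(universe$ld_block == b)
      if (length(sel) < 2L) next
      pr <- utils::combn(sel, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid_a = universe$rsid[pr[1L, ]],
        rsid_b = universe$rsid[pr[2L, ]],
        r2 = block_r2, stringsAsFactors = FALSE)
    }
    ld <- do.call(rbind, rows)
  }
  list(universe = universe, ld = ld)
}

#' Draw a GWAS catalog from a SNP universe
#'
#' Samples `size` SNPs without replacement from the MAF-filtered
#' universe with odds multiplied by `enrichment_factor` for SNPs whose
#' LD block contains a set member; `enrichment_factor = 1` draws
#' uniformly (the calibration condition).
#'
#' @param universe Universe data frame from [simulate_snp_universe()].
#' @param size Catalog size.
#' @param enrichment_factor Odds multiplier (default 1).
#' @param maf_min MAF filter (default 0.01).
#' @param rng_seed Integer seed.
#' @return Character vector of catalog rsids.
#' @export
draw_catalog <- function(universe, size, enrichment_factor = 1,
                         maf_min = 0.01, rng_seed = 1L) {
  old_seed <- withr_seed(rng_seed)
  on.exit(restore_seed(old_seed))
  pool <- universe[universe$maf >= maf_min, , drop = FALSE]
  if (nrow(pool) < size) stop("universe too small for catalog draw")
  set_blocks <- unique(pool$ld_block[pool$in_set])
  w <- ifelse(pool$ld_block %in% set_blocks, enrichment_factor, 1)
  pool$rsid[sample.int(nrow(pool), size, prob = w)]
}
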