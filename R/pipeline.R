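## Pipeline configuration and stage orchestration. Stages run in
## dependency order (scan -> cnm -> density/enrich/fst -> report); every
## output TSV carries a commented metadata header (version, seed,
## thresholds) and rerunning with an identical configuration reproduces
## byte-identical bodies.

#' Pipeline configuration
#'
#' Collects every numeric threshold of the survey with its conventional
#' default: PhastCons minimum 0.57 and mirSVR maximum -0.6 for
#' conserved predicted sites, LD r-squared 0.8, universe MAF minimum
#' 0.01, proxy pairing-score minimum 70 and energy maximum -20, 1000
#' resampling replicates, 2-SD outlier cut, 6-base density window with
#' 18-base flanks, and 22-base creation-window flanks.
#'
#' @param phastcons_min,mirsvr_max Conservation / score filters for
#'   predicted sites.
#' @param r2_min LD proxy threshold (strict `>`).
#' @param maf_min Resampling-universe MAF filter.
#' @param score_min,energy_max Proxy duplex filters.
#' @param reps Resampling replicates.
#' @param outlier_k F_ST outlier SD multiplier.
#' @param window,flank Density window and flank (bases).
#' @param cnm_flank Creation-window flank (bases).
#' @param rng_seed Seed for every stochastic stage.
#' @param populations Ancestry-group labels expected in the inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(phastcons_min = 0.57, mirsvr_max = -0.6,
                            r2_min = 0.8, maf_min = 0.01,
                            score_min = 70, energy_max = -20,
                            reps = 1000L, outlier_k = 2,
                            window = 6L, flank = 18L, cnm_flank = 22L,
                            rng_seed = 1L,
                            populations = c("ASN", "AFR", "EUR", "AMR")) {
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

#' Write a pipeline configuration to a YAML file
#' @param config A [pipeline_config()].
#' @param path Output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file written by [write_pipeline_config()].
#' @return A `pipeline_config` (defaults fill any missing field).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, vals)
  cfg
}

pipeline_meta <- function(config) {
  list(package = "mressnp",
       version = as.character(utils::packageVersion("mressnp")),
       rng_seed = config$rng_seed,
       phastcons_min = config$phastcons_min,
       mirsvr_max = config$mirsvr_max,
       r2_min = config$r2_min,
       maf_min = config$maf_min,
       score_min = config$score_min,
       energy_max = config$energy_max)
}

#' Run the survey pipeline over an input bundle
#'
#' Executes the requested stages over a synthetic world (or a directory
#' of inputs in the standard formats, read through [read_world()]) and
#' writes per-stage TSV/JSON artifacts under `out_dir`. Inputs are
#' never mutated; all randomness flows from `config$rng_seed`.
#'
#' Stages: `scan` (seed-site scan + disruption calls), `cnm`
#' (created-site calls), `density` (sliding-window SNP density over
#' scanned sites), `enrich` (catalog locus merge, observed overlap,
#' resampling null, tail probabilities), `fst` (Weir-Cockerham theta,
#' Box-Cox, group comparison, outliers, bins), `report` (packaged
#' worked-example table summaries).
#'
#' @param input A `sim_world` from [simulate_world()] or a directory
#'   path readable by [read_world()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages (default all).
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         stages = c("scan", "cnm", "density", "enrich",
                                    "fst", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  world <- if (is.character(input)) read_world(input, config$populations)
           else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- pipeline_meta(config)
  res <- list()

  need_scan <- any(c("scan", "density", "enrich", "fst") %in% stages)
  if (need_scan) {
    hits <- scan_utrs(world$utrs, world$mirs, world$placements)
    calls <- call_disruptions(hits, world$snps, world$mirs, world$utrs)
    res$hits <- hits
    res$calls <- calls
    res$seed_type_counts <- summarize_by_seed_type(calls)
    if ("scan" %in% stages) {
      write_tsv_meta(hits, file.path(out_dir, "sites.tsv"), meta)
      write_tsv_meta(calls, file.path(out_dir, "disruption_calls.tsv"), meta)
    }
  }

  need_cnm <- any(c("cnm", "enrich", "fst") %in% stages)
  if (need_cnm) {
    params <- proxy_params(score_min = config$score_min,
                           energy_max = config$energy_max)
    cnm <- call_created_sites(world$snps, world$utrs, world$placements,
                              world$mirs, params, flank = config$cnm_flank)
    res$cnm <- cnm
    if ("cnm" %in% stages) {
      out <- data.frame(rsid = cnm$rsid, miR = cnm$mir_name,
                        `S-T` = cnm$site_type, frame = cnm$window_offset,
                        PS = cnm$pairing_score, ES = cnm$energy_proxy,
                        check.names = FALSE)
      write_tsv_meta(out, file.path(out_dir, "cnm_hits.tsv"), meta)
    }
  }

  if ("density" %in% stages) {
    profile <- window_density(res$hits, world$snps,
                              window = config$window, flank = config$flank)
    res$density <- profile
    res$seed_density <- seed_average(profile)
    write_tsv_meta(as.data.frame(profile),
                   file.path(out_dir, "density_profile.tsv"),
                   c(meta, list(n_sites = attr(profile, "n_sites"),
                                seed_average = res$seed_density)))
  }

  mre_set <- NULL
  if (need_cnm && need_scan) {
    mre_set <- union(res$calls$rsid, res$cnm$rsid)
    res$mre_set <- mre_set
  }

  if ("enrich" %in% stages) {
    universe <- data.frame(rsid = world$snps$rsid, maf = snp_maf(world$snps))
    n_loci <- merge_catalog_loci(world$catalog$rsid, world$ld, config$r2_min)
    obs <- observed_overlap(world$catalog$rsid, world$ld,
                            mress_set = res$calls$rsid,
                            cnm_set = res$cnm$rsid, r2_min = config$r2_min)
    null <- resample_null(universe, mre_set, world$ld, n_draw = n_loci,
                          reps = config$reps, maf_min = config$maf_min,
                          r2_min = config$r2_min,
                          rng_seed = config$rng_seed)
    tail <- tail_probability(null, obs$n_total)
    res$enrich <- list(n_loci = n_loci, observed = obs, null = null,
                       tail = tail)
    jsonlite::write_json(
      list(n_catalog_snps = length(unique(world$catalog$rsid)),
           n_loci = n_loci,
           observed = obs[c("n_mress", "n_cnm", "n_total")],
           null_mean = null$mean, null_sd = null$sd,
           reps = null$reps, rng_seed = null$rng_seed,
           r2_min = config$r2_min, maf_min = config$maf_min,
           z = tail$z, p_normal = tail$p_normal,
           p_empirical = tail$p_empirical,
           replicate_counts = null$replicate_counts),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("fst" %in% stages) {
    gc <- world$group_counts
    groups <- config$populations
    wide_c <- do.call(cbind, lapply(groups, function(g)
      gc$count[gc$group == g][match(world$snps$rsid,
                                    gc$rsid[gc$group == g])]))
    wide_n <- do.call(cbind, lapply(groups, function(g)
      gc$size[gc$group == g][match(world$snps$rsid,
                                   gc$rsid[gc$group == g])]))
    theta <- fst_weir_cockerham(wide_c, wide_n)
    bc <- boxcox_fit(theta)
    records <- data.frame(rsid = world$snps$rsid, fst = theta,
                          is_mre = world$snps$rsid %in% mre_set,
                          transformed = bc$transformed,
                          stringsAsFactors = FALSE)
    cmp <- compare_groups(records$transformed[records$is_mre],
                          records$transformed[!records$is_mre])
    outl <- fst_outliers(records, k = config$outlier_k)
    n_mre <- sum(records$is_mre)
    bins <- bin_counts(records$fst[records$is_mre],
                       records$fst[!records$is_mre],
                       rng_seed = config$rng_seed)
    res$fst <- list(records = records, lambda = bc$lambda,
                    compare = cmp, outliers = outl, bins = bins)
    write_tsv_meta(records, file.path(out_dir, "fst.tsv"),
                   c(meta, list(lambda = bc$lambda)))
    write_tsv_meta(outl, file.path(out_dir, "fst_outliers.tsv"), meta)
    write_tsv_meta(bins, file.path(out_dir, "fst_bins.tsv"), meta)
    jsonlite::write_json(
      list(lambda = bc$lambda, t = cmp$t, p = cmp$p,
           n_mre = n_mre, n_other = nrow(records) - n_mre,
           n_outliers = nrow(outl)),
      file.path(out_dir, "fst_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }

  if ("report" %in% stages) {
    s1 <- summarize_table1(table1_validated_snps())
    s2 <- summarize_table2(table2_gwas_ld())
    res$report <- list(table1 = s1, table2 = s2)
    jsonlite::write_json(
      list(table1 = s1[c("unique_snps", "unique_genes", "n_freq_na",
                         "n_maf_le_02", "n_maf_gt_02", "n_disease_assoc")],
           table2 = s2),
      file.path(out_dir, "table_summaries.json"), auto_unbox = TRUE,
      digits = NA)
  }

  invisible(res)
}
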