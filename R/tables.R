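## Packaged worked-example tables (validated-site SNP table and the
## GWAS/LD/co-expression table), their printed-filter summaries, and
## evidence joins.

#' Load the packaged validated-MRESS SNP table
#'
#' 33 rows covering 31 unique SNPs found inside validated seed sites,
#' with printed allele frequencies (some are major-allele frequencies;
#' some are `NA`), the seed class interrupted, the position of the SNP
#' within the MRE, and the interacting miR, gene and literature source.
#' Two SNPs appear twice, once per overlapping miR site.
#'
#' @return Data frame of 33 rows.
#' @export
table1_validated_snps <- function() {
  path <- system.file("extdata", "table1_validated_mress_snps.tsv",
                      package = "mressnp", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Load the packaged GWAS/LD/co-expression table
#'
#' Rows pair GWAS-reported SNPs with the seed-site SNP they tag through
#' LD (r-squared above 0.8, or the SNP itself at r-squared 1).
#' Continuation rows (additional GWAS SNPs tagging the same proxy)
#' carry the proxy rsid with the remaining annotation fields `NA`.
#'
#' @return Data frame of 22 rows.
#' @export
table2_gwas_ld <- function() {
  path <- system.file("extdata", "table2_gwas_ld_coexpression.tsv",
                      package = "mressnp", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Summarize the validated-MRESS SNP table
#'
#' Reproduces the table's printed headline filters at the unique-SNP
#' level. Printed frequencies above 0.5 are treated as major-allele
#' frequencies and folded to the minor allele; the rare/common split
#' uses a strict cut at folded MAF 0.02 (the reading under which the
#' printed rare/common partition of the non-missing SNPs is reproduced,
#' since one SNP prints a frequency of exactly .02).
#'
#' @param rows Data frame from [table1_validated_snps()].
#' @param maf_thresh Rare/common threshold on the folded MAF
#'   (default 0.02, strict `<`).
#' @return List: `unique_snps`, `unique_genes`, `n_freq_na`,
#'   `n_maf_le_02`, `n_maf_gt_02`, `n_disease_assoc`,
#'   `counts_by_site_type` (per-row tally).
#' @export
summarize_table1 <- function(rows, maf_thresh = 0.02) {
  if (nrow(rows) != 33L) {
    stop("fixture integrity: expected 33 rows, got ", nrow(rows))
  }
  per_snp <- rows[!duplicated(rows$rsid), , drop = FALSE]
  maf <- fold_maf(per_snp$freq)
  list(
    unique_snps = nrow(per_snp),
    unique_genes = length(unique(rows$gene)),
    n_freq_na = sum(is.na(per_snp$freq)),
    n_maf_le_02 = sum(maf < maf_thresh, na.rm = TRUE),
    n_maf_gt_02 = sum(maf >= maf_thresh, na.rm = TRUE),
    n_disease_assoc = sum(per_snp$disease_flag),
    counts_by_site_type = table(rows$site_type)
  )
}

#' Summarize the GWAS/LD/co-expression table
#'
#' @param rows Data frame from [table2_gwas_ld()].
#' @return List: `n_proxy_snps` (distinct seed-site SNPs tagged),
#'   `n_gwas_snps`, `n_traits`.
#' @export
summarize_table2 <- function(rows) {
  if (nrow(rows) == 0L) {
    return(list(n_proxy_snps = 0L, n_gwas_snps = 0L, n_traits = 0L))
  }
  list(
    n_proxy_snps = length(unique(rows$proxy_rsid[!is.na(rows$proxy_rsid)])),
    n_gwas_snps = length(unique(rows$gwas_snp)),
    n_traits = length(unique(rows$phenotype[!is.na(rows$phenotype)]))
  )
}

#' Annotate hits with co-expression and eQTL evidence
#'
#' Left-joins hit rows against a miR/gene co-expression table and an
#' eQTL table: `coexpression_count` is the number of distinct tissues
#' in which the hit's miR and gene are co-listed; `eqtl_tissues`
#' concatenates the distinct tissues with eQTL evidence for the hit's
#' SNP and gene. No hit is dropped; annotating twice changes nothing.
#' Malformed evidence rows (missing required fields) are skipped with a
#' message.
#'
#' @param hits Data frame with columns `mir_name`, `gene` and (for the
#'   eQTL join) `rsid`.
#' @param coexpr Data frame (`mir`, `gene`, `tissue`) or `NULL`.
#' @param eqtl Data frame (`rsid`, `gene`, `tissue`, `direction`) or
#'   `NULL`.
#' @return `hits` with `coexpression_count` and `eqtl_tissues` columns.
#' @export
join_evidence <- function(hits, coexpr = NULL, eqtl = NULL) {
  hits$coexpression_count <- 0L
  hits$eqtl_tissues <- ""
  if (nrow(hits) == 0L) return(hits)

  if (!is.null(coexpr) && nrow(coexpr) > 0L) {
    ok <- !is.na(coexpr$mir) & !is.na(coexpr$gene) & !is.na(coexpr$tissue)
    if (any(!ok)) message(sum(!ok), " malformed co-expression rows skipped")
    coexpr <- coexpr[ok, , drop = FALSE]
    key <- paste(coexpr$mir, coexpr$gene, sep = "\r")
    counts <- tapply(coexpr$tissue, key, function(t) length(unique(t)))
    hkey <- paste(hits$mir_name, hits$gene, sep = "\r")
    got <- as.vector(counts[hkey])
    hits$coexpression_count <- ifelse(is.na(got), 0L, as.integer(got))
  }
  if (!is.null(eqtl) && nrow(eqtl) > 0L && "rsid" %in% names(hits)) {
    ok <- !is.na(eqtl$rsid) & !is.na(eqtl$gene) & !is.na(eqtl$tissue)
    if (any(!ok)) message(sum(!ok), " malformed eQTL rows skipped")
    eqtl <- eqtl[ok, , drop = FALSE]
    key <- paste(eqtl$rsid, eqtl$gene, sep = "\r")
    tiss <- tapply(eqtl$tissue, key,
                   function(t) paste(sort(unique(t)), collapse = ","))
    hkey <- paste(hits$rsid, hits$gene, sep = "\r")
    got <- as.vector(tiss[hkey])
    hits$eqtl_tissues <- ifelse(is.na(got), "", got)
  }
  hits
}
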