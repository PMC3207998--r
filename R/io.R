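## Readers and writers for the standard interchange formats the pipeline
## consumes: FASTA (miRs, UTRs), BED6 (UTR placements, emitted sites),
## VCF (bi-allelic SNVs with per-population frequencies in INFO), and
## plain TSV tables. FASTA goes through Biostrings; VCF reading through
## vcfR. VCF emission is a minimal text writer (vcfR's writer emits
## bgzipped output, which the text-based pipeline artifacts avoid).

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (DNA or RNA alphabet; U mapped to T).
#' @return Data frame with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(
    name = sub("\\s.*$", "", names(x)),
    seq = vapply(as.character(x), dna_normalize, character(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs Data frame with columns `name`, `seq`.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED6 file of UTR genomic placements
#'
#' BED is 0-based half-open; coordinates are kept in that convention in
#' the placement table and converted to 1-based inclusive only when
#' genomic coordinates are attached to hits.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return Data frame `name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "name", "score", "strand"))
  data.frame(name = b$name, chrom = normalize_chrom(b$chrom),
             start = as.integer(b$start), end = as.integer(b$end),
             strand = b$strand, stringsAsFactors = FALSE)
}

#' Write UTR placements (or site intervals) as BED6
#'
#' @param placements Data frame `name`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param path Output file.
#' @export
write_bed <- function(placements, path) {
  b <- data.frame(chrom = placements$chrom, start = placements$start,
                  end = placements$end, name = placements$name,
                  score = 0L, strand = placements$strand)
  utils::write.table(b, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read bi-allelic SNVs from a VCF
#'
#' Applies the bi-allelic single-base filter at ingestion: records with
#' multi-allelic ALT fields, indel alleles, or missing rsIDs are dropped.
#' Per-population allele frequencies are parsed from the INFO keys in
#' `af_keys` (e.g. `c(ASN = "AF_ASN", ...)`); absent keys yield `NA`,
#' which downstream code treats as "no frequency reported", distinct
#' from 0.
#'
#' @param path VCF file (plain text or gzipped).
#' @param af_keys Named character vector of INFO keys to parse as
#'   per-population allele frequencies.
#' @return Data frame `rsid`, `chrom`, `pos`, `ref`, `alt` plus one
#'   `af_<pop>` column per requested key.
#' @export
read_snvs_vcf <- function(path, af_keys = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  out <- data.frame(
    rsid = fix$ID[keep],
    chrom = normalize_chrom(fix$CHROM[keep]),
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(af_keys)) {
    for (pop in names(af_keys)) {
      vals <- vcfR::extract.info(v, element = af_keys[[pop]], as.numeric = TRUE)
      out[[paste0("af_", pop)]] <- as.numeric(vals[keep])
    }
  }
  out
}

#' Write SNVs as a minimal VCFv4.2 file
#'
#' @param snps Data frame `rsid`, `chrom`, `pos`, `ref`, `alt`; any
#'   `af_<pop>` columns are serialized into INFO as `AF_<POP>=` keys.
#' @param path Output file.
#' @export
write_snvs_vcf <- function(snps, path) {
  af_cols <- grep("^af_", names(snps), value = TRUE)
  info <- rep(".", nrow(snps))
  if (length(af_cols) > 0L) {
    parts <- lapply(af_cols, function(cl) {
      key <- paste0("AF_", toupper(sub("^af_", "", cl)))
      ifelse(is.na(snps[[cl]]), NA_character_,
             sprintf("%s=%.6g", key, snps[[cl]]))
    })
    info <- apply(do.call(cbind, parts), 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0L) "." else paste(r, collapse = ";")
    })
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Population allele frequency\">",
            toupper(sub("^af_", "", af_cols))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  snps$chrom, snps$pos, snps$rsid, snps$ref, snps$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a TSV with a commented metadata header
#'
#' Metadata lines are prefixed with `#` so the body remains a plain TSV;
#' identical inputs produce byte-identical bodies.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param meta Named list serialized as `# key=value` header lines.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()] (or any plain TSV)
#'
#' @param path Input file; `#`-prefixed lines are skipped.
#' @return Data frame.
#' @export
read_tsv_meta <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    check.names = FALSE)
}
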