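Package: mressnp
Title: SNPs That Disrupt or Create MicroRNA Seed Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-scale survey pipeline for single-nucleotide
    polymorphisms that abolish microRNA recognition element seed sites
    (MRESS SNPs) or create novel ones (CNM SNPs) in 3'UTRs. Provides
    canonical seed-site pattern construction and scanning
    (8mer/7mer-m8/7mer-A1/6mer), variant intersection and disruption
    calling, allele-specific created-site detection with a documented
    proxy duplex scorer, sliding-window SNP density profiles over
    validated sites, LD-proxy expansion of GWAS catalogs with a
    resampling null for enrichment testing, Weir-Cockerham F_ST with
    Box-Cox transformation and outlier selection, and a synthetic-data
    generator (Balding-Nichols population frequencies, block LD,
    enrichable GWAS catalogs) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
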