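#!/usr/bin/env Rscript
## Generate the synthetic study world — miRs, 3'UTRs with genomic
## placements, planted seed sites and creation events, SNPs with
## Balding-Nichols population frequencies, block LD, and a GWAS catalog
## enriched for MRESS/CNM loci — and write it in the pipeline's input
## formats (FASTA/BED/VCF/TSV) under results/world/.

library(mressnp)

cfg <- sim_config(rng_seed = 1L)
world <- simulate_world(cfg)
print(world)

dir.create("results", showWarnings = FALSE)
write_world(world, "results/world")
cat("inputs written to results/world:",
    paste(list.files("results/world"), collapse = ", "), "\n")
cat(sprintf("ground truth: %d planted sites, %d creation events, %d/%d SNPs in seed frames\n",
            nrow(world$truth$sites), nrow(world$truth$cnm),
            sum(world$truth$snps$in_seed), nrow(world$truth$snps)))
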