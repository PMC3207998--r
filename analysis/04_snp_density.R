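#!/usr/bin/env Rscript
## Sliding-window SNP density over the scanned seed sites: a 6-base
## window slid at 1-base steps across the 42-base region centered on
## the seed (18 bases of flank either side), densities in SNPs/kb.
## Writes results/density_profile.tsv.

library(mressnp)

world <- read_world("results/world")
cfg <- pipeline_config(rng_seed = 1L)
res <- run_pipeline(world, "results", cfg, stages = "density")

prof <- res$density
cat(sprintf("%d sites, %d SNP-window co-occurrences\n",
            attr(prof, "n_sites"), sum(prof$count)))
cat(sprintf("average density over the seed windows: %.2f SNPs/kb\n",
            res$seed_density))
cat(sprintf("flank maximum: %.2f SNPs/kb at offset %+d\n",
            max(prof$density[abs(prof$offset) > 5]),
            prof$offset[which.max(prof$density * (abs(prof$offset) > 5))]))
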