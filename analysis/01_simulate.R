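#!/usr/bin/env Rscript
# Step 1: build the three synthetic study datasets the later steps analyze.
#
# One cohort per planted regime — flat (no pattern), hourglass (early/late
# stages enriched for evolutionarily young expression, effect 2 TAI units)
# and reverse hourglass — each with 2,000 genes over 14 phylostrata, 8
# samples per tumor stage I-IV plus 4 NAT controls, and a DEG table with a
# 10-fold planted enrichment of phylostratum 6 (the vertebrate stratum).
# Everything is written as TSV + a provenance JSON under results/sim/.

suppressPackageStartupMessages(library(phylostage))

out_root <- "results/sim"
for (pattern in c("flat", "hourglass", "reverse_hourglass")) {
  cfg <- simulation_config(pattern = pattern, effect_size = 2,
                           enriched_strata = 6L, enrichment_fold = 10,
                           seed = 7L)
  dir <- file.path(out_root, pattern)
  write_simulation(cfg, dir)
  cat("wrote", dir, ":", cfg$n_genes, "genes,",
      sum(cfg$samples_per_stage), "samples, pattern =", pattern, "\n")
}
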