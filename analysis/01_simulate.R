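#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Emulates the downstream situation of a bulk RNA-seq contrast: a universe
# of 10,000 analyzed genes with jointly consistent log2 fold-changes,
# P-values and BH FDR, a library of 50 gene sets of 40 genes, and 5
# activated + 5 inhibited planted sets whose responding members carry a
# mean |log2FC| of 1.5. Writes the standard input files plus the ground
# truth under results/sim/.

suppressPackageStartupMessages(library(diaflux))

seed <- 20210417 %% 2147483647
cfg <- simulation_config(seed = seed)
sim <- simulate_study(cfg, dir = "results/sim")

deg <- select_deg(sim$table, 0.10)
counts <- count_by_direction(deg, sim$table)
message(sprintf(
  "Simulated %d genes: %d DEG at FDR <= 0.10 (%d up, %d down), %d at FDR <= 0.05.",
  nrow(sim$table), length(deg), counts$n_up, counts$n_down,
  length(select_deg(sim$table, 0.05))))
message(sprintf(
  "Planted %d activated and %d inhibited sets; files written to results/sim/.",
  cfg$n_planted_up, cfg$n_planted_down))
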