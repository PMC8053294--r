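#!/usr/bin/env Rscript
# Step 2 — pathway impact/flux scoring and hierarchy summaries.
#
# Scores every gene set against the simulated DEG table (impact = biological
# importance; flux = its signed direction), aggregates over the synthetic
# subcategory/category hierarchy, and ranks the top up- and downregulated
# sets. Requires results/sim/ from step 1.

suppressPackageStartupMessages(library(diaflux))

table <- read_deg_table("results/sim/deg.tsv")
sets <- read_gmt("results/sim/sets.gmt")
hierarchy <- read_hierarchy("results/sim/hierarchy.tsv")

scores <- score_collection(sets, table, fdr_cutoff = 0.10)
write_report(scores, "results/pathway_impact.tsv")
write_report(aggregate_hierarchy(scores, hierarchy, "subcategory"),
             "results/subcategory_impact.tsv")
write_report(aggregate_hierarchy(scores, hierarchy, "category"),
             "results/category_impact.tsv")
top_up <- rank_top(scores, 10, "up")
top_down <- rank_top(scores, 10, "down")
write_report(top_up, "results/top_up.tsv")
write_report(top_down, "results/top_down.tsv")

message(sprintf(
  "Scored %d sets; %d with positive flux, %d with negative flux.",
  nrow(scores), sum(scores$flux > 0), sum(scores$flux < 0)))
message(sprintf(
  "Most impacted upregulated set: %s (impact %.1f, flux %+.1f); downregulated: %s (impact %.1f, flux %+.1f).",
  top_up$set_id[1], top_up$impact[1], top_up$flux[1],
  top_down$set_id[1], top_down$impact[1], top_down$flux[1]))
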