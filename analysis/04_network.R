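#!/usr/bin/env Rscript
# Step 4 — multi-level pathway network and tri-partite assembly.
#
# Expands the pathway-link graph one level around the most impacted up- and
# downregulated sets, maps the DEG they contain, attaches the significant
# regulons as a TF layer, and exports node/edge tables. Requires steps 1-3.

suppressPackageStartupMessages(library(diaflux))

table <- read_deg_table("results/sim/deg.tsv")
sets <- read_gmt("results/sim/sets.gmt")
graph <- read_edges("results/sim/edges.tsv")
scores <- utils::read.delim("results/pathway_impact.tsv",
                            stringsAsFactors = FALSE)
tf <- utils::read.delim("results/tf_state.tsv", stringsAsFactors = FALSE)

seeds <- intersect(c(rank_top(scores, 1, "up")$set_id,
                     rank_top(scores, 1, "down")$set_id), graph$nodes)
deg <- select_deg(table, 0.10)
view <- expand_neighborhood(graph, seeds, levels = 1)
view <- map_genes_to_network(view, sets, deg, table)
view <- attach_tf_layer(view, tf)
export_network(view, "results/network_")

kinds <- table(view$nodes$node_kind)
message(sprintf(
  "Network seeded at %s: %d pathways, %d DEG, %d TFs, %d edges; exported to results/network_{nodes,edges}.tsv.",
  paste(seeds, collapse = " + "),
  kinds[["pathway"]], kinds[["gene"]],
  if ("tf" %in% names(kinds)) kinds[["tf"]] else 0L, nrow(view$edges)))
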