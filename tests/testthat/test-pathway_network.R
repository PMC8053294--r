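chain <- pathway_graph(data.frame(source_id = c("a", "b", "c"),
                                  target_id = c("b", "c", "d")))

test_that("expand_neighborhood performs a level-annotated BFS closure", {
  v <- expand_neighborhood(chain, "a", levels = 2)
  expect_setequal(v$nodes$node_id, c("a", "b", "c"))
  expect_equal(v$nodes$level[match(c("a", "b", "c"), v$nodes$node_id)],
               c(0L, 1L, 2L))
  expect_setequal(paste(v$edges$source_id, v$edges$target_id),
                  c("a b", "b c"))
  # levels 0: seeds only
  v0 <- expand_neighborhood(chain, "a", levels = 0)
  expect_equal(v0$nodes$node_id, "a")
  expect_equal(nrow(v0$edges), 0L)
  # seeding with every node keeps the whole graph at level 0
  vall <- expand_neighborhood(chain, c("a", "b", "c", "d"), levels = 3)
  expect_equal(sort(vall$nodes$node_id), c("a", "b", "c", "d"))
  expect_true(all(vall$nodes$level == 0L))
  expect_equal(nrow(vall$edges), 3L)
  expect_error(expand_neighborhood(chain, c("a", "zz"), 1), "zz")
})

test_that("neighborhood expansion is a monotone closure", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    nodes <- letters[1:n]
    m <- sample(1:(n * 2), 1)
    ed <- data.frame(source_id = sample(nodes, m, replace = TRUE),
                     target_id = sample(nodes, m, replace = TRUE))
    g <- suppressWarnings(pathway_graph(ed, nodes = nodes))
    seeds <- sample(nodes, sample(1:2, 1))
    prev <- character()
    for (L in 0:3) {
      cur <- expand_neighborhood(g, seeds, L)$nodes$node_id
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("levels equal naive shortest-path distances on random graphs", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    nodes <- sprintf("p%02d", 1:n)
    m <- sample(0:(n * 2), 1)
    ed <- data.frame(source_id = sample(nodes, m, replace = TRUE),
                     target_id = sample(nodes, m, replace = TRUE))
    g <- suppressWarnings(pathway_graph(ed, nodes = nodes))
    seeds <- sample(nodes, sample(seq_len(min(3, n)), 1))
    L <- sample(0:4, 1)
    v <- expand_neighborhood(g, seeds, L)
    dmat <- naive_distances(g$nodes, g$edges)
    dmin <- apply(dmat[seeds, , drop = FALSE], 2, min)
    expected <- names(dmin)[is.finite(dmin) & dmin <= L]
    expect_setequal(v$nodes$node_id, expected)
    expect_equal(v$nodes$level,
                 as.integer(dmin[v$nodes$node_id]))
  }
})

test_that("map_genes_to_network attaches only DEG in retained pathways", {
  fx <- fixture_small()
  deg <- select_deg(fx$table, 0.10)
  v <- expand_neighborhood(fx$graph, "PWY_A", levels = 0)
  vg <- map_genes_to_network(v, fx$sets, deg, fx$table)
  genes <- vg$nodes$node_id[vg$nodes$node_kind == "gene"]
  expect_setequal(genes, c("g01", "g02"))   # DEG in PWY_A; g05..g07 are not DEG
  expect_equal(vg$nodes$log2fc[vg$nodes$node_id == "g01"], 2)
  # a DEG in two retained pathways gets one node and two membership edges
  v2 <- expand_neighborhood(fx$graph, "PWY_A", levels = 1)
  vg2 <- map_genes_to_network(v2, fx$sets, deg, fx$table)
  mem <- vg2$edges[vg2$edges$edge_kind == "membership", ]
  expect_equal(sum(vg2$nodes$node_id == "g01"), 1L)
  expect_setequal(mem$target_id[mem$source_id == "g01"],
                  c("PWY_A", "PWY_B"))
  # no DEG in any retained pathway leaves the view unchanged
  v3 <- expand_neighborhood(fx$graph, "PWY_C", levels = 0)
  vg3 <- map_genes_to_network(v3, fx$sets, deg, fx$table)
  expect_equal(vg3$nodes, v3$nodes)
})

test_that("attach_tf_layer adds regulation edges and prunes isolated TFs", {
  fx <- fixture_small()
  deg <- select_deg(fx$table, 0.10)
  v <- expand_neighborhood(fx$graph, "PWY_A", levels = 0)
  v <- map_genes_to_network(v, fx$sets, deg, fx$table)  # genes g01, g02
  tf_results <- data.frame(
    tf_id = c("TF_HIT", "TF_MISS", "TF_SHARED"),
    impact = c(100, 50, 80), flux = c(60, -10, -40),
    predicted_state = c("Activated", "Inhibited", "Inhibited"),
    rank = 1:3, pvalue = c(1e-4, 1e-3, 1e-3), fdr = c(0.01, 0.02, 0.02),
    overlap_genes = c("g01,g02", "g09", "g01"),
    stringsAsFactors = FALSE)
  vt <- attach_tf_layer(v, tf_results)
  tfs <- vt$nodes$node_id[vt$nodes$node_kind == "tf"]
  expect_setequal(tfs, c("TF_HIT", "TF_SHARED"))  # TF_MISS pruned
  reg <- vt$edges[vt$edges$edge_kind == "regulation", ]
  expect_setequal(reg$target_id[reg$source_id == "TF_HIT"], c("g01", "g02"))
  expect_equal(reg$target_id[reg$source_id == "TF_SHARED"], "g01")
  expect_equal(vt$nodes$predicted_state[vt$nodes$node_id == "TF_SHARED"],
               "Inhibited")
  # tri-partite constraint: no gene-gene, tf-tf or tf-pathway edges
  kind_of <- setNames(vt$nodes$node_kind, vt$nodes$node_id)
  for (r in seq_len(nrow(vt$edges))) {
    pair <- sort(c(kind_of[[vt$edges$source_id[r]]],
                   kind_of[[vt$edges$target_id[r]]]))
    expect_true(paste(pair, collapse = "-") %in%
                  c("pathway-pathway", "gene-pathway", "gene-tf"))
  }
})

test_that("export_network round-trips and is byte-stable", {
  fx <- fixture_small()
  deg <- select_deg(fx$table, 0.10)
  v <- expand_neighborhood(fx$graph, "PWY_A", levels = 1)
  v <- map_genes_to_network(v, fx$sets, deg, fx$table)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "run1_")
  p2 <- file.path(dir, "run2_")
  export_network(v, p1)
  export_network(v, p2)
  expect_identical(readLines(paste0(p1, "nodes.tsv")),
                   readLines(paste0(p2, "nodes.tsv")))
  expect_identical(readLines(paste0(p1, "edges.tsv")),
                   readLines(paste0(p2, "edges.tsv")))
  back <- read_network(p1)
  expect_setequal(back$nodes$node_id, v$nodes$node_id)
  expect_equal(nrow(back$edges), nrow(v$edges))
  expect_equal(sort(back$nodes$log2fc), sort(v$nodes$log2fc))
  # empty view gives two header-only files
  export_network(diaflux:::network_view(), file.path(dir, "empty_"))
  expect_length(readLines(file.path(dir, "empty_nodes.tsv")), 1L)
  expect_length(readLines(file.path(dir, "empty_edges.tsv")), 1L)
})
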