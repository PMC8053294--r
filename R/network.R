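#' Empty tri-partite network view
#'
#' A `network_view` holds pathway, gene and transcription-factor nodes with
#' typed edges: `pathway_link` between pathways, `membership` from gene to
#' pathway, `regulation` from TF to gene. Pathway nodes carry their
#' breadth-first level (graph distance from the seed pathways), gene nodes
#' their log2 fold-change, TF nodes their predicted state.
#'
#' @param nodes data.frame with columns `node_id`, `node_kind`, `level`,
#'   `log2fc`, `predicted_state`.
#' @param edges data.frame with columns `source_id`, `target_id`,
#'   `edge_kind`.
#' @return An object of class `network_view`.
#' @keywords internal
network_view <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(node_id = character(), node_kind = character(),
                        level = integer(), log2fc = numeric(),
                        predicted_state = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(source_id = character(), target_id = character(),
                        edge_kind = character(), stringsAsFactors = FALSE)
  }
  endpoints <- unique(c(edges$source_id, edges$target_id))
  if (length(setdiff(endpoints, nodes$node_id)) > 0L) {
    stop("edge endpoint(s) missing from the node table", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "network_view")
}

#' @export
print.network_view <- function(x, ...) {
  kinds <- table(factor(x$nodes$node_kind,
                        levels = c("pathway", "gene", "tf")))
  cat(sprintf("<network_view: %d pathways, %d genes, %d TFs, %d edges>\n",
              kinds[["pathway"]], kinds[["gene"]], kinds[["tf"]],
              nrow(x$edges)))
  invisible(x)
}

#' Expand a multi-level pathway neighbourhood from seed pathways
#'
#' Breadth-first closure over the undirected pathway-link graph: retains
#' every pathway within `levels` link steps of any seed, annotated with its
#' shortest-path distance from the seed set (seeds are at level 0), and the
#' links among retained pathways.
#'
#' @param graph a [pathway_graph()].
#' @param seeds character vector of seed pathway ids, all present in the
#'   graph.
#' @param levels maximum distance to expand (>= 0); 0 retains seeds only.
#' @return A `network_view` containing pathway nodes and `pathway_link`
#'   edges.
#' @export
expand_neighborhood <- function(graph, seeds, levels = 1) {
  stopifnot(inherits(graph, "pathway_graph"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("at least one seed is required", call. = FALSE)
  unknown <- setdiff(seeds, graph$nodes)
  if (length(unknown) > 0L) {
    stop("seed pathway(s) not in graph: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(levels) || length(levels) != 1L || levels < 0) {
    stop("levels must be a single count >= 0", call. = FALSE)
  }
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = seeds, to = igraph::V(g))
  dist_min <- apply(d, 2, min)
  keep <- names(dist_min)[is.finite(dist_min) & dist_min <= levels]
  lev <- as.integer(dist_min[keep])
  ord <- order(keep)
  nodes <- data.frame(node_id = keep[ord], node_kind = "pathway",
                      level = lev[ord], log2fc = NA_real_,
                      predicted_state = NA_character_,
                      stringsAsFactors = FALSE)
  ed <- graph$edges
  ed <- ed[ed$source_id %in% keep & ed$target_id %in% keep, , drop = FALSE]
  edges <- data.frame(source_id = ed$source_id, target_id = ed$target_id,
                      edge_kind = rep("pathway_link", nrow(ed)),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  network_view(nodes, edges)
}

#' Attach differentially expressed genes to a pathway neighbourhood
#'
#' Adds one gene node for every DEG that belongs to at least one retained
#' pathway, with a `membership` edge to each retained pathway containing it.
#' Gene nodes carry the gene's log2 fold-change.
#'
#' @param view a `network_view` from [expand_neighborhood()].
#' @param membership a [gene_set_collection()] keyed by pathway id.
#' @param deg character vector of DEG ids.
#' @param table a [deg_table()].
#' @return The augmented `network_view`.
#' @export
map_genes_to_network <- function(view, membership, deg, table) {
  stopifnot(inherits(view, "network_view"),
            inherits(membership, "gene_set_collection"),
            inherits(table, "deg_table"))
  deg <- unique(as.character(deg))
  pathways <- view$nodes$node_id[view$nodes$node_kind == "pathway"]
  pathways <- intersect(pathways, names(membership))
  new_edges <- list()
  for (p in sort(pathways)) {
    hits <- intersect(intersect(membership$sets[[p]], deg), table$gene_id)
    if (length(hits) > 0L) {
      new_edges[[p]] <- data.frame(source_id = sort(hits), target_id = p,
                                   edge_kind = "membership",
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(new_edges) == 0L) return(view)
  mem <- do.call(rbind, new_edges)
  genes <- sort(unique(mem$source_id))
  gene_nodes <- data.frame(
    node_id = genes, node_kind = "gene", level = NA_integer_,
    log2fc = table$log2fc[match(genes, table$gene_id)],
    predicted_state = NA_character_, stringsAsFactors = FALSE)
  nodes <- rbind(view$nodes, gene_nodes)
  edges <- rbind(view$edges, mem)
  rownames(nodes) <- rownames(edges) <- NULL
  network_view(nodes, edges)
}

#' Attach the transcription-factor layer to a gene-mapped network
#'
#' Adds one TF node per significant regulon that regulates at least one gene
#' already in the view, with a `regulation` edge to each such gene (an edge
#' is present exactly when the gene is among the TF's overlapping DEG). TFs
#' with no regulated gene in the view are omitted. TF nodes carry the
#' predicted activation state.
#'
#' @param view a gene-mapped `network_view`.
#' @param tf_results data.frame from [tf_state_report()].
#' @return The augmented tri-partite `network_view`.
#' @export
attach_tf_layer <- function(view, tf_results) {
  stopifnot(inherits(view, "network_view"))
  genes_in_view <- view$nodes$node_id[view$nodes$node_kind == "gene"]
  if (nrow(tf_results) == 0L || length(genes_in_view) == 0L) return(view)
  new_nodes <- list()
  new_edges <- list()
  for (i in seq_len(nrow(tf_results))) {
    tf <- tf_results$tf_id[i]
    targets <- strsplit(tf_results$overlap_genes[i], ",", fixed = TRUE)[[1]]
    hits <- sort(intersect(targets, genes_in_view))
    if (length(hits) == 0L) next
    new_nodes[[tf]] <- data.frame(
      node_id = tf, node_kind = "tf", level = NA_integer_,
      log2fc = NA_real_, predicted_state = tf_results$predicted_state[i],
      stringsAsFactors = FALSE)
    new_edges[[tf]] <- data.frame(source_id = tf, target_id = hits,
                                  edge_kind = "regulation",
                                  stringsAsFactors = FALSE)
  }
  if (length(new_nodes) == 0L) return(view)
  ord <- order(names(new_nodes))
  nodes <- rbind(view$nodes, do.call(rbind, new_nodes[ord]))
  edges <- rbind(view$edges, do.call(rbind, new_edges[ord]))
  rownames(nodes) <- rownames(edges) <- NULL
  network_view(nodes, edges)
}

#' Export a network view as node and edge tables
#'
#' Writes `<prefix>nodes.tsv` and `<prefix>edges.tsv` with deterministic row
#' order (node kind pathway/gene/tf, then id; edge kind, then endpoints), so
#' repeated exports of the same view are byte-identical.
#'
#' @param view a `network_view`.
#' @param path_prefix path prefix for the two files (e.g. `"out/run1_"`).
#' @return Invisibly, the two paths written.
#' @export
export_network <- function(view, path_prefix) {
  stopifnot(inherits(view, "network_view"))
  dir <- dirname(paste0(path_prefix, "x"))
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  kind_rank <- c(pathway = 1L, gene = 2L, tf = 3L)
  nodes <- view$nodes
  nodes <- nodes[order(kind_rank[nodes$node_kind], nodes$node_id), ,
                 drop = FALSE]
  edge_rank <- c(pathway_link = 1L, membership = 2L, regulation = 3L)
  edges <- view$edges
  edges <- edges[order(edge_rank[edges$edge_kind], edges$source_id,
                       edges$target_id), , drop = FALSE]
  node_path <- paste0(path_prefix, "nodes.tsv")
  edge_path <- paste0(path_prefix, "edges.tsv")
  write_report(nodes, node_path)
  write_report(edges, edge_path)
  invisible(c(node_path, edge_path))
}

#' Re-read an exported network view
#'
#' @param path_prefix prefix used in [export_network()].
#' @return A `network_view`.
#' @export
read_network <- function(path_prefix) {
  nodes <- utils::read.delim(paste0(path_prefix, "nodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(node_id = "character",
                                            node_kind = "character",
                                            level = "integer",
                                            log2fc = "numeric",
                                            predicted_state = "character"))
  edges <- utils::read.delim(paste0(path_prefix, "edges.tsv"), sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  network_view(nodes, edges)
}
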