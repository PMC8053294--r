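#' Construct a validated differential-expression table
#'
#' A `deg_table` holds per-gene differential-expression statistics: the gene
#' identifier, the log2 fold-change of treatment versus control, the raw
#' P-value and the FDR-adjusted P-value. The set of gene identifiers defines
#' the analysis universe against which all proportions and enrichment tests
#' are conditioned.
#'
#' Duplicate gene identifiers are collapsed by keeping the record with the
#' smallest raw P-value (ties broken by smallest absolute log2 fold-change,
#' then first occurrence); row order is otherwise preserved.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `pvalue`,
#'   `fdr`. Extra columns are dropped.
#' @param normalize_case logical; if `TRUE`, gene identifiers are upper-cased
#'   before validation (useful when matching symbol-based gene-set libraries
#'   against mixed-case tables). Default `FALSE`: matching is exact and
#'   case-sensitive.
#' @return An object of class `deg_table`: a data.frame with the four
#'   canonical columns and unique gene identifiers.
#' @examples
#' tab <- deg_table(data.frame(
#'   gene_id = c("g1", "g2"), log2fc = c(1.2, -0.4),
#'   pvalue = c(0.001, 0.4), fdr = c(0.01, 0.6)))
#' deg_universe(tab)
#' @export
deg_table <- function(records, normalize_case = FALSE) {
  required <- c("gene_id", "log2fc", "pvalue", "fdr")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("DEG table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- records[required]
  df$gene_id <- as.character(df$gene_id)
  if (isTRUE(normalize_case)) df$gene_id <- toupper(df$gene_id)
  if (any(is.na(df$gene_id) | !nzchar(df$gene_id))) {
    stop("gene_id must be non-empty for every record", call. = FALSE)
  }
  for (col in c("log2fc", "pvalue", "fdr")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing '%s' at row(s): %s", col,
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  bad_p <- which(df$pvalue <= 0 | df$pvalue > 1)
  if (length(bad_p) > 0L) {
    stop("pvalue must lie in (0, 1]; offending row(s): ",
         paste(utils::head(bad_p, 5L), collapse = ", "), call. = FALSE)
  }
  bad_f <- which(df$fdr < 0 | df$fdr > 1)
  if (length(bad_f) > 0L) {
    stop("fdr must lie in [0, 1]; offending row(s): ",
         paste(utils::head(bad_f, 5L), collapse = ", "), call. = FALSE)
  }
  # Collapse duplicates: smallest raw P, then smallest |log2fc|, then first.
  if (anyDuplicated(df$gene_id)) {
    ord <- order(df$gene_id, df$pvalue, abs(df$log2fc), seq_len(nrow(df)))
    keep_first <- !duplicated(df$gene_id[ord])
    kept_rows <- sort(ord[keep_first])
    df <- df[kept_rows, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Gene universe of a differential-expression table
#'
#' @param table a [deg_table()].
#' @return Character vector of the gene identifiers analyzed.
#' @export
deg_universe <- function(table) {
  stopifnot(inherits(table, "deg_table"))
  table$gene_id
}

#' Construct a collection of named gene sets
#'
#' A `gene_set_collection` maps set identifiers (pathways or transcription
#' factors) to their member genes. Member lists are sets: duplicates within
#' a set are collapsed.
#'
#' @param sets named list of character vectors of member gene ids; names are
#'   the set ids.
#' @param descriptions optional character vector of free-text descriptions,
#'   one per set (recycled from `""`).
#' @param library_name label for the library (e.g. a pathway catalogue or a
#'   ChIP-seq evidence library).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                library_name = "gene_sets") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a non-empty set_id (list name)", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    dup <- unique(names(sets)[duplicated(names(sets))])
    stop("duplicate set_id in collection: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    stop("descriptions must match the number of sets", call. = FALSE)
  }
  members <- lapply(sets, function(m) {
    m <- unique(as.character(m))
    if (length(m) == 0L) stop("gene set with no members", call. = FALSE)
    m
  })
  structure(
    list(sets = members,
         descriptions = stats::setNames(as.character(descriptions),
                                        names(sets)),
         library_name = library_name),
    class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s': %d sets, %d distinct genes>\n",
              x$library_name, length(x$sets),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Construct a pathway hierarchy
#'
#' Three-level organization of pathways (pathway -> subcategory -> category),
#' mirroring a KEGG-BRITE-like catalogue, used to aggregate impact and flux
#' summaries.
#'
#' @param entries data.frame with columns `pathway_id`, `pathway_name`,
#'   `subcategory`, `category`; one row per pathway.
#' @return An object of class `pathway_hierarchy`.
#' @export
pathway_hierarchy <- function(entries) {
  required <- c("pathway_id", "pathway_name", "subcategory", "category")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("hierarchy is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- entries[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$pathway_id)) {
    dup <- unique(df$pathway_id[duplicated(df$pathway_id)])
    stop("duplicate pathway_id in hierarchy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("pathway_hierarchy", "data.frame")
  df
}

#' Construct an undirected pathway-link graph
#'
#' Edges connect interconnected pathways; the graph is undirected,
#' deduplicated and loop-free. Self-loops in the input are dropped with a
#' warning.
#'
#' @param edges data.frame with columns `source_id`, `target_id` (one row per
#'   link), or NULL for an edgeless graph.
#' @param nodes optional character vector of node ids to include even when
#'   isolated; edge endpoints are always included.
#' @return An object of class `pathway_graph`: a list with `nodes`
#'   (character) and `edges` (two-column data.frame of canonically ordered
#'   pairs).
#' @export
pathway_graph <- function(edges = NULL, nodes = character()) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    ed <- data.frame(source_id = character(), target_id = character(),
                     stringsAsFactors = FALSE)
  } else {
    required <- c("source_id", "target_id")
    missing_cols <- setdiff(required, names(edges))
    if (length(missing_cols) > 0L) {
      stop("edge table is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    a <- as.character(edges$source_id)
    b <- as.character(edges$target_id)
    loops <- a == b
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from pathway graph",
              call. = FALSE)
    }
    nodes <- unique(c(nodes, a, b))
    a2 <- pmin(a[!loops], b[!loops])
    b2 <- pmax(a[!loops], b[!loops])
    keep <- !duplicated(paste(a2, b2, sep = "\r"))
    ed <- data.frame(source_id = a2[keep], target_id = b2[keep],
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$source_id, ed$target_id), , drop = FALSE]
    rownames(ed) <- NULL
  }
  structure(list(nodes = sort(nodes), edges = ed), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}
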