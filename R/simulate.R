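#' Simulation configuration
#'
#' Parameters of the synthetic differential-expression generator. Defaults
#' emulate the regime of a bulk liver RNA-seq contrast: a universe of 10,000
#' analyzed genes of which roughly 4% pass FDR <= 0.10, organized into 50
#' gene sets of 40 genes, with 5 activated and 5 inhibited planted sets.
#'
#' @param n_genes number of genes in the analysis universe.
#' @param n_sets number of gene sets in the library.
#' @param set_size set size; a single count or a length-2 range
#'   (sizes drawn uniformly per set).
#' @param n_planted_up number of sets planted with upregulated targets.
#' @param n_planted_down number of sets planted with downregulated targets.
#' @param effect_mu mean |log2 fold-change| of planted responding genes
#'   (> 0).
#' @param effect_sd standard deviation of planted effects (>= 0).
#' @param se per-gene standard error converting log2 fold-change to a
#'   z-score and two-sided normal P-value (> 0).
#' @param frac_responding fraction of a planted set's members given the
#'   effect, in (0, 1].
#' @param seed integer seed; all randomness derives from it through
#'   per-component streams (genes, sets, effects).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000L, n_sets = 50L,
                              set_size = 40L, n_planted_up = 5L,
                              n_planted_down = 5L, effect_mu = 1.5,
                              effect_sd = 0.3, se = 0.3,
                              frac_responding = 0.8, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
              set_size = as.integer(set_size),
              n_planted_up = as.integer(n_planted_up),
              n_planted_down = as.integer(n_planted_down),
              effect_mu = as.numeric(effect_mu),
              effect_sd = as.numeric(effect_sd), se = as.numeric(se),
              frac_responding = as.numeric(frac_responding),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_sets < 1L) {
    stop("n_genes and n_sets must be positive", call. = FALSE)
  }
  if (length(cfg$set_size) == 1L) cfg$set_size <- rep(cfg$set_size, 2L)
  if (length(cfg$set_size) != 2L || any(cfg$set_size < 1L) ||
      cfg$set_size[1] > cfg$set_size[2]) {
    stop("set_size must be a count or an increasing length-2 range",
         call. = FALSE)
  }
  if (cfg$set_size[2] > cfg$n_genes) {
    stop("set sizes cannot exceed n_genes", call. = FALSE)
  }
  n_planted <- cfg$n_planted_up + cfg$n_planted_down
  if (n_planted > cfg$n_sets) {
    stop("n_planted_up + n_planted_down must not exceed n_sets",
         call. = FALSE)
  }
  if (n_planted * cfg$set_size[2] > cfg$n_genes) {
    stop("planted sets (kept disjoint) cannot cover more than n_genes",
         call. = FALSE)
  }
  if (cfg$effect_mu < 0 || cfg$effect_sd < 0 || cfg$se <= 0) {
    stop("effect_mu, effect_sd must be >= 0 and se > 0", call. = FALSE)
  }
  if (cfg$frac_responding <= 0 || cfg$frac_responding > 1) {
    stop("frac_responding must lie in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Derived per-component stream seed; keeps all draws reproducible from one
# base seed while isolating the gene, set and effect streams.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

#' Simulate a differential-expression study with planted gene sets
#'
#' Generates a jointly consistent (log2 fold-change, P-value, FDR) table
#' shaped like an edgeR output, a gene-set library, a round-robin pathway
#' hierarchy, a pathway-link graph connecting sets that share genes, and the
#' ground truth of planted set directions.
#'
#' Null genes draw log2fc ~ Normal(0, se); each planted set is assigned a
#' direction and its responding members (a `frac_responding` fraction) draw
#' log2fc ~ direction * Normal(effect_mu, effect_sd). P-values are the
#' two-sided normal tail of z = log2fc / se (floored at 1e-300 so -log10 P
#' stays finite) and FDR is Benjamini-Hochberg over all genes. Planted sets
#' are pairwise disjoint; null sets are sampled freely.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, writes `deg.tsv`, `sets.gmt`,
#'   `hierarchy.tsv`, `edges.tsv` and `truth.tsv` there.
#' @return A list with elements `table` ([deg_table()]), `sets`
#'   ([gene_set_collection()]), `hierarchy` ([pathway_hierarchy()]), `graph`
#'   ([pathway_graph()]) and `truth` (data.frame `set_id`, `direction`,
#'   `responding_genes`).
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  set_ids <- sprintf("SET%03d", seq_len(cfg$n_sets))
  n_planted <- cfg$n_planted_up + cfg$n_planted_down

  # genes stream: null effects
  lfc <- with_stream(cfg$seed, 1L,
                     stats::rnorm(cfg$n_genes, mean = 0, sd = cfg$se))

  # sets stream: sizes, planted membership (disjoint), null membership
  sets <- with_stream(cfg$seed, 2L, {
    sizes <- if (cfg$set_size[1] == cfg$set_size[2]) {
      rep(cfg$set_size[1], cfg$n_sets)
    } else {
      sample(seq(cfg$set_size[1], cfg$set_size[2]), cfg$n_sets,
             replace = TRUE)
    }
    membership <- vector("list", cfg$n_sets)
    if (n_planted > 0L) {
      pool <- sample(gene_ids, sum(sizes[seq_len(n_planted)]))
      offset <- 0L
      for (i in seq_len(n_planted)) {
        membership[[i]] <- pool[(offset + 1L):(offset + sizes[i])]
        offset <- offset + sizes[i]
      }
    }
    for (i in seq.int(n_planted + 1L, length.out = cfg$n_sets - n_planted)) {
      membership[[i]] <- sample(gene_ids, sizes[i])
    }
    names(membership) <- set_ids
    membership
  })

  planted_dir <- c(rep(1L, cfg$n_planted_up), rep(-1L, cfg$n_planted_down))
  names(planted_dir) <- set_ids[seq_len(n_planted)]

  # effects stream: responding members and their planted effects
  responding <- list()
  if (n_planted > 0L) {
    draws <- with_stream(cfg$seed, 3L, {
      lapply(names(planted_dir), function(sid) {
        members <- sets[[sid]]
        n_resp <- max(1L, round(cfg$frac_responding * length(members)))
        list(resp = sort(sample(members, n_resp)),
             eff = stats::rnorm(n_resp, mean = cfg$effect_mu,
                                sd = cfg$effect_sd))
      })
    })
    names(draws) <- names(planted_dir)
    for (sid in names(draws)) {
      lfc[match(draws[[sid]]$resp, gene_ids)] <-
        planted_dir[[sid]] * draws[[sid]]$eff
      responding[[sid]] <- draws[[sid]]$resp
    }
  }

  pvalue <- pmax(2 * stats::pnorm(-abs(lfc / cfg$se)), 1e-300)
  fdr <- bh_adjust(pvalue)
  table <- deg_table(data.frame(gene_id = gene_ids, log2fc = lfc,
                                pvalue = pvalue, fdr = fdr,
                                stringsAsFactors = FALSE))
  collection <- gene_set_collection(
    sets, descriptions = sprintf("synthetic set %s", set_ids),
    library_name = "synthetic")

  n_subcat <- max(1L, ceiling(cfg$n_sets / 10))
  n_cat <- max(1L, ceiling(n_subcat / 3))
  subcat <- sprintf("SUBCAT%02d", ((seq_len(cfg$n_sets) - 1L) %% n_subcat) + 1L)
  subcat_index <- as.integer(sub("SUBCAT", "", unique(subcat)))
  cat_of_subcat <- sprintf("CAT%02d", ((subcat_index - 1L) %% n_cat) + 1L)
  names(cat_of_subcat) <- unique(subcat)
  hierarchy <- pathway_hierarchy(data.frame(
    pathway_id = set_ids,
    pathway_name = sprintf("synthetic pathway %s", set_ids),
    subcategory = subcat,
    category = cat_of_subcat[subcat],
    stringsAsFactors = FALSE))

  # link sets sharing at least one gene
  edge_rows <- list()
  for (i in seq_len(cfg$n_sets - 1L)) {
    for (j in seq.int(i + 1L, cfg$n_sets)) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
        edge_rows[[length(edge_rows) + 1L]] <-
          data.frame(source_id = set_ids[i], target_id = set_ids[j],
                     stringsAsFactors = FALSE)
      }
    }
  }
  graph <- pathway_graph(
    if (length(edge_rows) > 0L) do.call(rbind, edge_rows) else NULL,
    nodes = set_ids)

  truth <- data.frame(
    set_id = names(planted_dir),
    direction = as.integer(planted_dir),
    responding_genes = vapply(names(planted_dir), function(sid)
      paste(responding[[sid]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  bundle <- list(table = table, sets = collection, hierarchy = hierarchy,
                 graph = graph, truth = truth)
  if (!is.null(dir)) write_study(bundle, dir)
  bundle
}

#' Write a simulated (or fixture) study bundle to standard files
#'
#' @param bundle list as returned by [simulate_study()] (the `truth` element
#'   is optional).
#' @param dir output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_study <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_report(as.data.frame(bundle$table), file.path(dir, "deg.tsv"))
  gmt_lines <- vapply(names(bundle$sets), function(id)
    paste(c(id, bundle$sets$descriptions[[id]], bundle$sets$sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(gmt_lines, file.path(dir, "sets.gmt"))
  write_report(as.data.frame(bundle$hierarchy),
               file.path(dir, "hierarchy.tsv"))
  write_report(bundle$graph$edges, file.path(dir, "edges.tsv"))
  if (!is.null(bundle$truth)) {
    write_report(bundle$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Hand-built miniature study fixture
#'
#' A fixed 3-set fixture over a 10-gene universe (two additional gene ids
#' appear only in the gene-set library, outside the universe, for 12
#' distinct gene ids in total). It embeds two hand-checkable cases:
#' pathway `PWY_A` has background 5 with DEG {+2 at P 1e-4; -1 at P 1e-2},
#' giving proportion 0.4, magnitude 1.5, significance 3, impact 180,
#' direction 1/3 and flux 60; pathway `PWY_B` has background 5 overlapping
#' all 4 DEG of the 10-gene universe, the enrichment configuration
#' N=10, K=5, n=4, k=4 with exact P = 5/210. The same fixture ships as
#' plain-text files under `inst/extdata/fixture_small/`.
#'
#' @param dir optional directory to write the fixture files to.
#' @return A bundle list as in [simulate_study()], without `truth`.
#' @export
fixture_small <- function(dir = NULL) {
  genes <- sprintf("g%02d", 1:10)
  lfc <- c(2, -1, 1.2, -0.8, 0.15, -0.1, 0.05, 0.2, -0.25, 0.1)
  pv <- c(1e-4, 1e-2, 2e-3, 5e-3, 0.30, 0.40, 0.50, 0.60, 0.75, 0.90)
  table <- deg_table(data.frame(gene_id = genes, log2fc = lfc, pvalue = pv,
                                fdr = bh_adjust(pv),
                                stringsAsFactors = FALSE))
  sets <- gene_set_collection(
    list(PWY_A = c("g01", "g02", "g05", "g06", "g07"),
         PWY_B = c("g01", "g02", "g03", "g04", "g08"),
         PWY_C = c("g09", "g10", "g11", "g12")),
    descriptions = c("worked impact example", "worked enrichment example",
                     "set with members outside the universe"),
    library_name = "fixture_small")
  hierarchy <- pathway_hierarchy(data.frame(
    pathway_id = c("PWY_A", "PWY_B", "PWY_C"),
    pathway_name = c("fixture pathway A", "fixture pathway B",
                     "fixture pathway C"),
    subcategory = c("SC_metab", "SC_metab", "SC_info"),
    category = c("CAT_metab", "CAT_metab", "CAT_info"),
    stringsAsFactors = FALSE))
  graph <- pathway_graph(
    data.frame(source_id = "PWY_A", target_id = "PWY_B",
               stringsAsFactors = FALSE),
    nodes = c("PWY_A", "PWY_B", "PWY_C"))
  bundle <- list(table = table, sets = sets, hierarchy = hierarchy,
                 graph = graph, truth = NULL)
  if (!is.null(dir)) write_study(bundle, dir)
  bundle
}
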