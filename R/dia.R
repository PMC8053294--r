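#' Select differentially expressed genes at an FDR cutoff
#'
#' A gene is called differentially expressed (DEG) when its FDR-adjusted
#' P-value is at or below the cutoff; the boundary is inclusive.
#'
#' @param table a [deg_table()].
#' @param fdr_cutoff FDR threshold in (0, 1]; the study default downstream
#'   is 0.10, with 0.05 reported alongside.
#' @return Character vector of DEG identifiers, in table order.
#' @export
select_deg <- function(table, fdr_cutoff = 0.10) {
  stopifnot(inherits(table, "deg_table"))
  if (!is.numeric(fdr_cutoff) || length(fdr_cutoff) != 1L ||
      fdr_cutoff <= 0 || fdr_cutoff > 1) {
    stop("fdr_cutoff must be a single value in (0, 1]", call. = FALSE)
  }
  table$gene_id[table$fdr <= fdr_cutoff]
}

#' Count up- and downregulated genes in a DEG list
#'
#' Genes with positive log2 fold-change are counted up, negative down; genes
#' with a log2 fold-change of exactly zero fall in neither and are reported
#' separately.
#'
#' @param deg character vector of gene ids, a subset of the table universe.
#' @param table a [deg_table()].
#' @return A list with integer counts `n_up`, `n_down` and `n_zero`.
#' @export
count_by_direction <- function(deg, table) {
  stopifnot(inherits(table, "deg_table"))
  deg <- unique(as.character(deg))
  idx <- match(deg, table$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) not present in the table: ",
         paste(utils::head(deg[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  lfc <- table$log2fc[idx]
  list(n_up = sum(lfc > 0), n_down = sum(lfc < 0), n_zero = sum(lfc == 0))
}

#' Impact and flux of one gene set
#'
#' Computes the dynamic-impact style score of a gene set against a
#' differential-expression table. With background B = members intersected
#' with the analysis universe and D = DEG within B:
#'
#' * proportion  pi = |D| / |B| (0 when B is empty);
#' * magnitude   m  = mean over D of |log2fc|;
#' * significance s = mean over D of -log10(P), raw P by default;
#' * impact      I  = 100 * pi * m * s;
#' * direction   d  = sum(log2fc) / sum(|log2fc|) over D (0 when the
#'   denominator is 0), a magnitude-weighted mean sign in [-1, 1];
#' * flux        F  = I * d.
#'
#' With no DEG in the background, m = s = d = 0 and I = F = 0. The
#' construction guarantees |F| <= I, with equality exactly when the set's
#' DEG all share one sign of log2 fold-change.
#'
#' @param members character vector of the set's member gene ids (or a
#'   single-set slice of a [gene_set_collection()]).
#' @param table a [deg_table()].
#' @param fdr_cutoff DEG threshold passed to [select_deg()].
#' @param set_id identifier recorded in the result.
#' @param sig_stat which P-value feeds the significance term: `"pvalue"`
#'   (raw, default) or `"fdr"` (adjusted).
#' @param direction_method `"magnitude"` (default; d as above) or `"count"`
#'   ((n_up - n_down) / n_deg). Only the magnitude weighting guarantees
#'   |flux| <= impact.
#' @return A list of class `impact_result` with fields `set_id`,
#'   `n_background`, `n_deg`, `proportion`, `magnitude`, `significance`,
#'   `impact`, `direction`, `flux`, `deg_members`.
#' @export
compute_impact <- function(members, table, fdr_cutoff = 0.10,
                           set_id = "set",
                           sig_stat = c("pvalue", "fdr"),
                           direction_method = c("magnitude", "count")) {
  stopifnot(inherits(table, "deg_table"))
  sig_stat <- match.arg(sig_stat)
  direction_method <- match.arg(direction_method)
  members <- unique(as.character(members))
  universe <- table$gene_id
  background <- intersect(members, universe)
  deg_all <- select_deg(table, fdr_cutoff)
  deg_in <- intersect(background, deg_all)
  nb <- length(background)
  nd <- length(deg_in)
  if (nb == 0L || nd == 0L) {
    res <- list(set_id = set_id, n_background = nb, n_deg = 0L,
                proportion = 0, magnitude = 0, significance = 0,
                impact = 0, direction = 0, flux = 0,
                deg_members = character())
    class(res) <- "impact_result"
    return(res)
  }
  idx <- match(deg_in, universe)
  lfc <- table$log2fc[idx]
  pv <- if (sig_stat == "pvalue") table$pvalue[idx] else
    pmax(table$fdr[idx], .Machine$double.xmin)
  prop <- nd / nb
  mag <- mean(abs(lfc))
  sig <- mean(-log10(pv))
  impact <- 100 * prop * mag * sig
  denom <- sum(abs(lfc))
  direction <- if (direction_method == "magnitude") {
    if (denom == 0) 0 else sum(lfc) / denom
  } else {
    (sum(lfc > 0) - sum(lfc < 0)) / nd
  }
  res <- list(set_id = set_id, n_background = nb, n_deg = nd,
              proportion = prop, magnitude = mag, significance = sig,
              impact = impact, direction = direction,
              flux = impact * direction, deg_members = deg_in)
  class(res) <- "impact_result"
  res
}

impact_results_to_df <- function(results) {
  data.frame(
    set_id = vapply(results, `[[`, character(1), "set_id"),
    n_background = vapply(results, `[[`, integer(1), "n_background"),
    n_deg = vapply(results, `[[`, integer(1), "n_deg"),
    proportion = vapply(results, `[[`, numeric(1), "proportion"),
    magnitude = vapply(results, `[[`, numeric(1), "magnitude"),
    significance = vapply(results, `[[`, numeric(1), "significance"),
    impact = vapply(results, `[[`, numeric(1), "impact"),
    direction = vapply(results, `[[`, numeric(1), "direction"),
    flux = vapply(results, `[[`, numeric(1), "flux"),
    deg_members = vapply(results, function(r)
      paste(r$deg_members, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Score every set in a collection
#'
#' Applies [compute_impact()] to each set and returns one row per set in a
#' deterministic order: descending impact, ties broken lexicographically by
#' set id. The output is independent of the collection's input order.
#'
#' @param collection a [gene_set_collection()].
#' @inheritParams compute_impact
#' @return A data.frame with the `impact_result` fields, `deg_members`
#'   comma-joined.
#' @export
score_collection <- function(collection, table, fdr_cutoff = 0.10,
                             sig_stat = c("pvalue", "fdr"),
                             direction_method = c("magnitude", "count")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection) == 0L) stop("empty collection", call. = FALSE)
  sig_stat <- match.arg(sig_stat)
  direction_method <- match.arg(direction_method)
  results <- lapply(names(collection), function(id)
    compute_impact(collection$sets[[id]], table, fdr_cutoff,
                   set_id = id, sig_stat = sig_stat,
                   direction_method = direction_method))
  df <- impact_results_to_df(results)
  df <- df[order(-df$impact, df$set_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Aggregate pathway impact and flux over a hierarchy level
#'
#' Summarizes per-pathway results into subcategory or category means: for
#' each group, impact and flux are the arithmetic means over member pathways
#' with a non-empty background. Pathways absent from the hierarchy are
#' skipped with a warning; groups with no eligible pathway are omitted.
#'
#' @param results data.frame from [score_collection()].
#' @param hierarchy a [pathway_hierarchy()].
#' @param level `"subcategory"` or `"category"`.
#' @return data.frame with columns `group_id`, `level`, `impact`, `flux`,
#'   `n_pathways`, sorted by descending impact then group id.
#' @export
aggregate_hierarchy <- function(results, hierarchy,
                                level = c("subcategory", "category")) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  level <- match.arg(level)
  idx <- match(results$set_id, hierarchy$pathway_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " scored set(s) absent from the hierarchy were skipped",
            call. = FALSE)
  }
  keep <- !is.na(idx) & results$n_background > 0
  res <- results[keep, , drop = FALSE]
  grp <- hierarchy[[level]][idx[keep]]
  if (nrow(res) == 0L) {
    return(data.frame(group_id = character(), level = character(),
                      impact = numeric(), flux = numeric(),
                      n_pathways = integer(), stringsAsFactors = FALSE))
  }
  agg <- data.frame(
    group_id = tapply(res$impact, grp, mean) |> names(),
    level = level,
    impact = as.numeric(tapply(res$impact, grp, mean)),
    flux = as.numeric(tapply(res$flux, grp, mean)),
    n_pathways = as.integer(tapply(res$impact, grp, length)),
    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$impact, agg$group_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Top up- or downregulated sets by impact
#'
#' In `"up"` mode, returns the `n` highest-impact sets among those with
#' positive flux (activation); `"down"` is symmetric for negative flux.
#' Ties are broken lexicographically by set id; fewer than `n` qualifying
#' sets yields a shorter list.
#'
#' @param results data.frame from [score_collection()].
#' @param n number of sets to keep (>= 1).
#' @param mode `"up"` or `"down"`.
#' @return data.frame slice of `results`, ordered by descending impact.
#' @export
rank_top <- function(results, n = 10, mode = c("up", "down")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  keep <- if (mode == "up") results$flux > 0 else results$flux < 0
  res <- results[keep, , drop = FALSE]
  res <- res[order(-res$impact, res$set_id), , drop = FALSE]
  res <- utils::head(res, n)
  rownames(res) <- NULL
  res
}
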