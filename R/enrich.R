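#' One-sided hypergeometric over-representation P-value
#'
#' Exact upper-tail probability P(X >= k) for X ~ hypergeometric with
#' universe size N, K marked elements (the gene set's background size) and n
#' draws (the DEG list size): the chance that a random DEG list of the same
#' size overlaps the set at least as much as observed. Equivalent to a
#' one-sided Fisher exact test.
#'
#' @param k observed overlap count.
#' @param K set background size (members in the universe).
#' @param n DEG count.
#' @param N universe size.
#' @return P-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "inconsistent arguments: need k <= min(K, n) and K, n <= N (got k=%d, K=%d, n=%d, N=%d)",
      k, K, n, N), call. = FALSE)
  }
  if (k == 0) return(1)
  p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values q_(i) = min_{j >= i}(p_(j) * T / j), capped at 1
#' and returned in the input order. Controls the false discovery rate across
#' the family of all values supplied.
#'
#' @param pvalues numeric vector of raw P-values, each in (0, 1].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("all P-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation test of every set against a DEG list
#'
#' For each set: K = |members in universe|, k = |members in DEG list|,
#' N = |universe|, n = |DEG list|; the P-value is the one-sided
#' hypergeometric tail and FDR is Benjamini-Hochberg over all tested sets
#' (the whole collection, not only reported survivors). Ranks 1..T are
#' assigned by ascending P-value, ties broken lexicographically by set id.
#' Sets with no member in the universe are reported with k = 0 and P = 1.
#'
#' @param collection a [gene_set_collection()].
#' @param deg character vector of DEG ids, a subset of the table universe.
#' @param table a [deg_table()].
#' @return data.frame with columns `set_id`, `n_universe`, `n_deg`, `n_set`,
#'   `n_overlap`, `pvalue`, `fdr`, `rank`, `overlap_genes` (comma-joined),
#'   ordered by rank.
#' @export
enrich_collection <- function(collection, deg, table) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(table, "deg_table"))
  universe <- table$gene_id
  deg <- unique(as.character(deg))
  if (length(setdiff(deg, universe)) > 0L) {
    stop("DEG list contains gene(s) outside the table universe",
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(deg)
  ids <- names(collection)
  rows <- lapply(ids, function(id) {
    bg <- intersect(collection$sets[[id]], universe)
    ov <- intersect(bg, deg)
    K <- length(bg)
    k <- length(ov)
    p <- if (K == 0L) 1 else hypergeom_pvalue(k, K, n, N)
    list(set_id = id, K = K, k = k, p = p,
         overlap = paste(sort(ov), collapse = ","))
  })
  df <- data.frame(
    set_id = vapply(rows, `[[`, character(1), "set_id"),
    n_universe = N,
    n_deg = n,
    n_set = vapply(rows, `[[`, integer(1), "K"),
    n_overlap = vapply(rows, `[[`, integer(1), "k"),
    pvalue = vapply(rows, `[[`, numeric(1), "p"),
    overlap_genes = vapply(rows, `[[`, character(1), "overlap"),
    stringsAsFactors = FALSE)
  df$fdr <- bh_adjust(df$pvalue)
  df <- df[order(df$pvalue, df$set_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[c("set_id", "n_universe", "n_deg", "n_set", "n_overlap",
       "pvalue", "fdr", "rank", "overlap_genes")]
}

#' Call a regulon's activation state from its flux
#'
#' Positive flux means the regulon's differentially expressed targets are
#' predominantly upregulated (Activated); negative flux means Inhibited;
#' exactly zero flux is Indeterminate.
#'
#' @param flux numeric vector of finite flux values.
#' @return Character vector of `"Activated"`, `"Inhibited"` or
#'   `"Indeterminate"`.
#' @export
call_state <- function(flux) {
  if (length(flux) == 0L) return(character())
  if (!is.numeric(flux) || any(!is.finite(flux))) {
    stop("flux must be finite", call. = FALSE)
  }
  ifelse(flux > 0, "Activated",
         ifelse(flux < 0, "Inhibited", "Indeterminate"))
}

#' Transcription-factor state report
#'
#' End-to-end regulon analysis: select DEG at `fdr_cutoff_deg` (study
#' default 0.10), test every regulon for over-representation, keep regulons
#' with enrichment FDR at or below `fdr_cutoff_tf` (study default 0.05),
#' compute each survivor's impact and flux over its regulon, and call its
#' state from the flux sign. Output is sorted by enrichment rank.
#'
#' @param collection a [gene_set_collection()] of TF-target regulons.
#' @param table a [deg_table()].
#' @param fdr_cutoff_deg DEG selection threshold in (0, 1].
#' @param fdr_cutoff_tf regulon significance threshold in (0, 1].
#' @inheritParams compute_impact
#' @return data.frame with columns `tf_id`, `impact`, `flux`,
#'   `predicted_state`, `rank`, `pvalue`, `fdr`, `overlap_genes`.
#' @export
tf_state_report <- function(collection, table, fdr_cutoff_deg = 0.10,
                            fdr_cutoff_tf = 0.05,
                            sig_stat = c("pvalue", "fdr"),
                            direction_method = c("magnitude", "count")) {
  for (cutoff in c(fdr_cutoff_deg, fdr_cutoff_tf)) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L ||
        cutoff <= 0 || cutoff > 1) {
      stop("FDR cutoffs must be single values in (0, 1]", call. = FALSE)
    }
  }
  sig_stat <- match.arg(sig_stat)
  direction_method <- match.arg(direction_method)
  deg <- select_deg(table, fdr_cutoff_deg)
  enr <- enrich_collection(collection, deg, table)
  enr <- enr[enr$fdr <= fdr_cutoff_tf, , drop = FALSE]
  if (nrow(enr) == 0L) {
    return(data.frame(tf_id = character(), impact = numeric(),
                      flux = numeric(), predicted_state = character(),
                      rank = integer(), pvalue = numeric(), fdr = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  }
  scores <- lapply(enr$set_id, function(id)
    compute_impact(collection$sets[[id]], table, fdr_cutoff_deg,
                   set_id = id, sig_stat = sig_stat,
                   direction_method = direction_method))
  impact <- vapply(scores, `[[`, numeric(1), "impact")
  flux <- vapply(scores, `[[`, numeric(1), "flux")
  out <- data.frame(
    tf_id = enr$set_id,
    impact = impact,
    flux = flux,
    predicted_state = call_state(flux),
    rank = enr$rank,
    pvalue = enr$pvalue,
    fdr = enr$fdr,
    overlap_genes = enr$overlap_genes,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
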