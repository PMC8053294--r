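# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) equally likely draws; marked elements are 1..K.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(0L >= k))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Naive Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * T / j, capped at 1, in input order.
naive_bh <- function(p) {
  T_ <- length(p)
  o <- order(p)
  q_sorted <- numeric(T_)
  for (i in seq_len(T_)) {
    j <- i:T_
    q_sorted[i] <- min(1, min(p[o][j] * T_ / j))
  }
  q <- numeric(T_)
  q[o] <- q_sorted
  q
}

# Naive impact/flux from the definition, independent of compute_impact.
naive_impact <- function(members, table, fdr_cutoff) {
  bg <- intersect(unique(members), table$gene_id)
  deg <- table$gene_id[table$fdr <= fdr_cutoff]
  d_in <- intersect(bg, deg)
  if (length(bg) == 0L || length(d_in) == 0L) {
    return(list(impact = 0, flux = 0))
  }
  idx <- match(d_in, table$gene_id)
  lfc <- table$log2fc[idx]
  pv <- table$pvalue[idx]
  I <- 100 * (length(d_in) / length(bg)) * mean(abs(lfc)) *
    mean(-log10(pv))
  dirn <- if (sum(abs(lfc)) == 0) 0 else sum(lfc) / sum(abs(lfc))
  list(impact = I, flux = I * dirn)
}

# All-pairs shortest-path distances by Floyd-Warshall on a node/edge list.
naive_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$source_id[r]; j <- edges$target_id[r]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# A small random DEG table plus one random gene set, for property tests.
random_instance <- function(n_genes = 12L) {
  ids <- sprintf("r%02d", seq_len(n_genes))
  lfc <- round(stats::rnorm(n_genes, 0, 1.5), 3)
  # occasionally force exact zeros and single-signed sets
  zero <- stats::runif(n_genes) < 0.1
  lfc[zero] <- 0
  if (stats::runif(1) < 0.3) lfc <- abs(lfc)
  pv <- stats::runif(n_genes, 1e-6, 1)
  fdr <- stats::runif(n_genes, 0, 1)
  tab <- deg_table(data.frame(gene_id = ids, log2fc = lfc, pvalue = pv,
                              fdr = fdr, stringsAsFactors = FALSE))
  members <- sample(ids, sample.int(n_genes, 1L))
  list(table = tab, members = members)
}

write_tsv_fixture <- function(lines, path) {
  writeLines(lines, path)
  path
}
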