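#' Read a differential-expression table from TSV
#'
#' Expects a tab-separated UTF-8 file with a header naming at least
#' `gene_id`, `log2fc`, `pvalue` and `fdr` (extra columns are ignored), the
#' shape of an edgeR/limma top-table export. Validation and duplicate
#' handling follow [deg_table()].
#'
#' @inheritParams deg_table
#' @param path path to the TSV file.
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path, normalize_case = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "")
  deg_table(df, normalize_case = normalize_case)
}

#' Read gene sets from a GMT file
#'
#' Standard Gene Matrix Transposed format: one set per line, tab-separated as
#' set id, free-text description, then member gene ids. Duplicate members
#' within a line are collapsed; a duplicated set id across lines is an error.
#'
#' @param path path to the GMT file.
#' @param library_name label stored on the returned collection; defaults to
#'   the file name.
#' @param normalize_case logical; upper-case member gene ids (see
#'   [deg_table()]).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, library_name = basename(path),
                     normalize_case = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate set_id in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    if (isTRUE(normalize_case)) m <- toupper(m)
    m[nzchar(m)]
  })
  names(members) <- ids
  gene_set_collection(members, descriptions = desc,
                      library_name = library_name)
}

#' Read a pathway hierarchy from TSV
#'
#' @param path TSV file with header `pathway_id`, `pathway_name`,
#'   `subcategory`, `category`.
#' @return A [pathway_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "")
  pathway_hierarchy(df)
}

#' Read a pathway-link edge table from TSV
#'
#' @param path TSV file with header `source_id`, `target_id`; one undirected
#'   link per row. Duplicates (in either orientation) are collapsed and
#'   self-loops dropped with a warning.
#' @return A [pathway_graph()].
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "")
  required <- c("source_id", "target_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("edge table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pathway_graph(df)
}

#' Write a result table as TSV with fixed numeric formatting
#'
#' Numeric columns are written with 6 significant digits, '.' decimal mark
#' and no thousands separators, so a write/read round-trip reproduces values
#' to the formatting precision. Column order is preserved as given.
#'
#' @param results a data.frame of results (may have zero rows).
#' @param path destination path; the directory must exist.
#' @return Invisibly, the path written.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  out <- as.data.frame(results, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- formatC(signif(out[[col]], 6L), format = "g",
                            digits = 6L, decimal.mark = ".")
      out[[col]] <- trimws(out[[col]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
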