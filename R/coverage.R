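# Gene coverage: rank query genes by how many significant miRNAs target them.

#' Rank genes by the number of miRNAs targeting them
#'
#' For each gene appearing in any result's shared-gene list, counts the
#' distinct miRNAs listing it, keeps genes reaching `min_count`, and sorts
#' by count descending with alphabetical gene symbol as the tie-break (the
#' convention used for published multiplicity tables). Arm variants such as
#' `miR-124` and `miR-124-3p` count as distinct miRNAs.
#'
#' @param results Data frame with columns `mirna` and list column
#'   `shared_genes` ([run_enrichment()] output, typically pre-filtered with
#'   [filter_significant()], or a loaded enrichment table).
#' @param min_count Minimum number of targeting miRNAs to keep a gene
#'   (default 2).
#' @return A `coverage_table` data frame: `gene`, `n_mirnas`, list column
#'   `mirnas` (sorted canonical ids).
#' @examples
#' tab4 <- load_enrichment_table(cleftmir_extdata("table4_enrichment.tsv"))
#' head(gene_coverage(tab4), 3)
#' @export
gene_coverage <- function(results, min_count = 2) {
  stopifnot(min_count >= 1)
  if (!all(c("mirna", "shared_genes") %in% names(results))) {
    stopf("results must carry 'mirna' and 'shared_genes' columns")
  }
  reps <- lengths(results$shared_genes)
  pairs <- data.frame(mirna = rep(results$mirna, reps),
                      gene = unlist(results$shared_genes) %||% character(0),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  by_gene <- split(pairs$mirna, pairs$gene)
  genes <- names(by_gene)
  out <- data.frame(gene = genes,
                    n_mirnas = lengths(by_gene),
                    stringsAsFactors = FALSE)
  out$mirnas <- unname(lapply(by_gene, function(m) m[order_c(m)]))
  out <- out[out$n_mirnas >= min_count, , drop = FALSE]
  out <- out[order_c(-out$n_mirnas, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("coverage_table", "data.frame"))
}

#' Cross-table conservation audit between results and coverage
#'
#' The total of `n_mirnas` over an unfiltered coverage table
#' (`min_count = 1`) must equal the total shared-gene count `k` over the
#' results it was computed from; a corrupted duplicate gene inside one
#' result's list breaks the identity.
#'
#' @param results Data frame with `mirna`, `shared_genes` and (optionally)
#'   `k`; when `k` is absent the list lengths are used.
#' @param coverage_all Optional precomputed
#'   `gene_coverage(results, min_count = 1)`.
#' @return `TRUE` iff the two totals agree.
#' @export
coverage_conservation_check <- function(results, coverage_all = NULL) {
  coverage_all <- coverage_all %||% gene_coverage(results, min_count = 1)
  k <- if ("k" %in% names(results)) results$k else lengths(results$shared_genes)
  sum(coverage_all$n_mirnas) == sum(k)
}

#' Write a coverage table as TSV
#'
#' Dialect: `gene  n_mirnas  mirnas`, miRNAs comma-separated in canonical
#' sorted order.
#'
#' @param coverage A `coverage_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  df <- data.frame(gene = coverage$gene,
                   n_mirnas = coverage$n_mirnas,
                   mirnas = vapply(coverage$mirnas, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Load a transcribed coverage table
#'
#' Reads the `gene  n_mirnas  mirnas` dialect (comma-separated miRNA lists,
#' canonicalized on load), e.g. a published multiplicity table used as a
#' consistency fixture.
#'
#' @param path Path to the TSV file.
#' @return A `coverage_table` data frame in file order.
#' @export
load_coverage_table <- function(path) {
  df <- read_tsv_strict(path, c("gene", "n_mirnas", "mirnas"))
  out <- data.frame(gene = df$gene,
                    n_mirnas = as.integer(df$n_mirnas),
                    stringsAsFactors = FALSE)
  out$mirnas <- lapply(df$mirnas, function(x) canonicalize_mirna(split_field(x, ",")))
  structure(out, class = c("coverage_table", "data.frame"))
}
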