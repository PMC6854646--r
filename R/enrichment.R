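# Per-miRNA over-representation of a query gene set: 2x2 contingency
# construction, exact Fisher p-values in log space, Benjamini-Hochberg FDR,
# and the significance filter.

#' Build the 2x2 contingency table behind one miRNA's Fisher test
#'
#' Given a miRNA's target set T, the query set Q (e.g. the cleft-lip
#' catalog), and the background universe U, computes
#' `a = |T intersect Q|` (the shared genes), `b = |T \ Q|`, `c = |Q \ T|`,
#' `d = |U| - a - b - c`. Query genes outside the universe are dropped with
#' a message; target genes must all lie in the universe.
#'
#' @param target_set,query_set,universe Character vectors of gene symbols.
#' @return A `contingency_table` with fields `a`, `b`, `c`, `d`, `N`.
#' @examples
#' build_contingency(c("A", "B"), c("B", "C"), LETTERS[1:10])
#' @export
build_contingency <- function(target_set, query_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  target_set <- unique(target_set)
  query_set <- unique(query_set)
  if (length(setdiff(target_set, universe))) {
    stopf("target set contains gene(s) outside the universe: %s",
          paste(utils::head(setdiff(target_set, universe), 5), collapse = ", "))
  }
  dropped <- setdiff(query_set, universe)
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " query gene(s) outside the universe")
    query_set <- intersect(query_set, universe)
  }
  a <- length(intersect(target_set, query_set))
  b <- length(target_set) - a
  c_ <- length(query_set) - a
  d <- length(universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d, N = length(universe),
                 shared = sort(intersect(target_set, query_set))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 contingency (N = %d):\n", x$N))
  print(matrix(c(x$a, x$c, x$b, x$d), 2,
               dimnames = list(c("query", "not query"),
                               c("target", "not target"))))
  invisible(x)
}

as_counts_2x2 <- function(table) {
  if (inherits(table, "contingency_table")) {
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  } else {
    m <- as.matrix(table)
    if (!all(dim(m) == c(2, 2))) stopf("expected a 2x2 table")
    c(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2])
  }
}

# log point probability of the hypergeometric table with overlap x, target
# margin m, query margin k, total N -- accumulated via log binomial
# coefficients for numerical safety.
log_hyper_pmf <- function(x, m, k, N) {
  lchoose(m, x) + lchoose(N - m, k - x) - lchoose(N, k)
}

#' Exact Fisher p-value for a 2x2 table
#'
#' One-sided `"greater"` is the hypergeometric upper tail
#' `P(X >= a)` with `X ~ Hypergeom(N, a + b, a + c)` -- the standard
#' over-representation direction. `"two_sided"` follows the
#' minimum-likelihood convention: the sum over all tables with the observed
#' margins whose point probability does not exceed the observed one (with
#' relative tolerance 1e-7 on the comparison, as in classical
#' implementations). Probabilities are accumulated in log space.
#'
#' @param table A `contingency_table` from [build_contingency()] or a 2x2
#'   matrix `[[a, b], [c, d]]`.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return A p-value in `(0, 1]`.
#' @examples
#' fisher_pvalue(matrix(c(3, 1, 1, 3), 2, byrow = TRUE), "greater")  # 17/70
#' @export
fisher_pvalue <- function(table, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  ct <- as_counts_2x2(table)
  if (any(ct < 0) || any(ct != round(ct))) {
    stopf("contingency counts must be non-negative integers")
  }
  a <- ct[["a"]]; b <- ct[["b"]]; c_ <- ct[["c"]]; d <- ct[["d"]]
  N <- a + b + c_ + d
  m <- a + b   # target margin
  k <- a + c_  # query margin
  support <- max(0, m + k - N):min(m, k)
  lp <- log_hyper_pmf(support, m, k, N)
  sum_exp <- function(v) {
    if (!length(v)) return(0)
    mx <- max(v)
    exp(mx) * sum(exp(v - mx))
  }
  p <- switch(alternative,
              # at the bottom of the support the upper tail is exactly 1
              greater = if (a <= support[1]) 1 else sum_exp(lp[support >= a]),
              two_sided = {
                lp_obs <- log_hyper_pmf(a, m, k, N)
                sum_exp(lp[lp <= lp_obs + log1p(1e-7)])
              })
  min(1, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with `m` tests and ascending p-values `p_(j)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`. Ties receive equal adjusted
#' values and results are returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.005, 0.009, 0.05, 0.5))
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  desc <- order(p, decreasing = TRUE)
  back <- order(desc)
  q <- pmin(1, cummin(p[desc] * m / (m:1)))
  q[back]
}

#' Per-miRNA over-representation of a query gene set
#'
#' Runs one Fisher test per miRNA in the target map against the query set,
#' adjusts across all tested miRNAs with Benjamini-Hochberg, and flags
#' significance at a strict FDR threshold (`fdr < fdr_threshold`).
#'
#' @param map A `target_map` from [merge_sources()].
#' @param query Query gene symbols (e.g. `build_gene_union()$symbols`).
#' @param universe Optional background override (see [gene_universe()]).
#' @param alternative Sidedness of [fisher_pvalue()]; default `"greater"`.
#' @param fdr_threshold Strict FDR cut, default 0.2.
#' @return An `enrichment_results` data frame sorted by p-value (ties by
#'   miRNA id): `mirna`, `k` (shared-gene count), list column
#'   `shared_genes`, `p_value`, `fdr`, `significant`.
#' @export
run_enrichment <- function(map, query, universe = NULL,
                           alternative = c("greater", "two_sided"),
                           fdr_threshold = 0.2) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(map, "target_map"))
  if (length(map$targets) == 0) stopf("target map is empty")
  if (fdr_threshold <= 0 || fdr_threshold > 1) {
    stopf("fdr_threshold must lie in (0, 1]")
  }
  uni <- gene_universe(map, universe)
  query <- unique(query)
  if (length(intersect(query, uni)) == 0) {
    stopf("query set does not intersect the universe")
  }
  mirnas <- names(map$targets)
  tabs <- lapply(mirnas, function(mi) {
    suppressMessages(build_contingency(map$targets[[mi]], query, uni))
  })
  p <- vapply(tabs, fisher_pvalue, numeric(1), alternative = alternative)
  fdr <- bh_adjust(p)
  out <- data.frame(mirna = mirnas,
                    k = vapply(tabs, function(t) t$a, integer(1)),
                    p_value = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  out$shared_genes <- lapply(tabs, function(t) t$shared)
  ord <- order_c(out$p_value, out$mirna)
  out <- out[ord, c("mirna", "k", "shared_genes", "p_value", "fdr",
                    "significant")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_results", "data.frame"),
            fdr_threshold = fdr_threshold, alternative = alternative)
}

#' Keep rows below an FDR threshold
#'
#' Works on [run_enrichment()] output or on a loaded enrichment table whose
#' `fdr` column is treated as data (e.g. a transcribed published table).
#' The comparison is strict (`fdr < threshold`); input order is preserved.
#'
#' @param results Data frame with an `fdr` column.
#' @param threshold FDR cut.
#' @return The retained subset.
#' @export
filter_significant <- function(results, threshold = 0.2) {
  if (!"fdr" %in% names(results)) stopf("results must carry an 'fdr' column")
  out <- results[results$fdr < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a transcribed enrichment table
#'
#' Dialect: tab-separated with header `mirna  n_genes  genes  p_value  fdr`,
#' `genes` comma-separated in printed order. miRNA names are canonicalized;
#' the gene lists are parsed into a list column and `k` is taken from the
#' printed `n_genes`.
#'
#' @param path Path to the TSV file.
#' @return An `enrichment_results`-shaped data frame (no `significant`
#'   column; the stored p and FDR values are data, not recomputed).
#' @examples
#' tab4 <- load_enrichment_table(cleftmir_extdata("table4_enrichment.tsv"))
#' nrow(tab4)
#' @export
load_enrichment_table <- function(path) {
  df <- read_tsv_strict(path, c("mirna", "n_genes", "genes", "p_value", "fdr"))
  out <- data.frame(mirna = canonicalize_mirna(df$mirna),
                    k = as.integer(df$n_genes),
                    p_value = as.numeric(df$p_value),
                    fdr = as.numeric(df$fdr),
                    stringsAsFactors = FALSE)
  out$shared_genes <- lapply(df$genes, split_field, sep = ",")
  structure(out[c("mirna", "k", "shared_genes", "p_value", "fdr")],
            class = c("enrichment_results", "data.frame"))
}

#' Write enrichment results as TSV
#'
#' Mirrors the enrichment dialect (`mirna  n_genes  genes  p_value  fdr`)
#' plus a `significant` column when present. Stored values are written at
#' full precision; any display rounding is left to reports.
#'
#' @param results An `enrichment_results` data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(results, path) {
  df <- data.frame(mirna = results$mirna,
                   n_genes = results$k,
                   genes = vapply(results$shared_genes, paste,
                                  "", collapse = ","),
                   p_value = results$p_value,
                   fdr = results$fdr,
                   stringsAsFactors = FALSE)
  if ("significant" %in% names(results)) {
    df$significant <- results$significant
  }
  write_tsv_plain(df, path)
}
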