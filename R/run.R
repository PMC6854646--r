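# End-to-end pipeline: configuration, staged execution, report bundle.

#' Combine mutant-record tables
#'
#' Row-binds several `mutant_records` tables (e.g. the single-gene,
#' spontaneous and compound tables) into one validated table.
#'
#' @param ... `mutant_records` data frames.
#' @return A `mutant_records` data frame.
#' @export
bind_records <- function(...) {
  dfs <- lapply(list(...), function(d) {
    stopifnot(inherits(d, "mutant_records"))
    class(d) <- "data.frame"
    d
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  new_mutant_records(out)
}

#' Pipeline run configuration
#'
#' Collects the inputs and tuning parameters of a full analysis run:
#' catalog fixture paths, interaction resources, optional explicit
#' universe, test sidedness, the FDR threshold (default 0.2), the
#' multi-resource support filter, the coverage multiplicity cut (default 2),
#' a seed, and the output directory.
#'
#' @param catalog_dir Directory holding the three catalog TSVs (file names
#'   containing `single`, `spontaneous`, `compound`); alternative to
#'   `catalog_paths`.
#' @param catalog_paths Named character vector/list of catalog TSV paths,
#'   names among `single`, `spontaneous`, `compound`.
#' @param interactions Character vector of interaction TSV paths, one per
#'   resource.
#' @param universe Optional path to a one-gene-per-line background file.
#' @param alternative `"greater"` or `"two_sided"`.
#' @param fdr_threshold Strict FDR cut in `(0, 1]`, default 0.2.
#' @param min_sources Minimum distinct resources supporting a pair.
#' @param min_coverage Coverage multiplicity cut, default 2.
#' @param seed Integer seed for any randomness downstream.
#' @param out_dir Output directory for the report bundle (`NULL` to skip
#'   writing).
#' @param venn_totals Optional `c(n_a, n_b)` printed set totals (e.g.
#'   review and database counts) from which the Venn partition against the
#'   catalog union size is reconstructed.
#' @return A `run_config` object.
#' @export
run_config <- function(catalog_dir = NULL, catalog_paths = NULL,
                       interactions = character(),
                       universe = NULL,
                       alternative = c("greater", "two_sided"),
                       fdr_threshold = 0.2, min_sources = 1,
                       min_coverage = 2, seed = 1, out_dir = NULL,
                       venn_totals = NULL) {
  alternative <- match.arg(alternative)
  if (fdr_threshold <= 0 || fdr_threshold > 1) {
    stopf("fdr_threshold must lie in (0, 1]")
  }
  if (!is.null(catalog_dir)) {
    files <- dir(catalog_dir, pattern = "\\.tsv$", full.names = TRUE)
    catalog_paths <- catalog_paths %||% list()
    for (kind in c("single", "spontaneous", "compound")) {
      hit <- grep(kind, basename(files), value = TRUE, fixed = TRUE)
      if (length(hit) == 1 && is.null(catalog_paths[[kind]])) {
        catalog_paths[[kind]] <- file.path(catalog_dir, hit)
      }
    }
  }
  catalog_paths <- as.list(catalog_paths %||% list())
  bad <- setdiff(names(catalog_paths), c("single", "spontaneous", "compound"))
  if (length(bad)) {
    stopf("unknown catalog table kind(s): %s", paste(bad, collapse = ", "))
  }
  for (p in c(unlist(catalog_paths), interactions, universe)) {
    if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  if (!is.null(venn_totals) && length(venn_totals) != 2) {
    stopf("venn_totals must be two set sizes c(n_a, n_b)")
  }
  structure(list(catalog_paths = catalog_paths,
                 interactions = interactions,
                 universe = universe,
                 alternative = alternative,
                 fdr_threshold = fdr_threshold,
                 min_sources = min_sources,
                 min_coverage = min_coverage,
                 seed = as.integer(seed),
                 out_dir = out_dir,
                 venn_totals = venn_totals),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage[%s]: %s", stage, conditionMessage(e))
  })
}

#' Run the full catalog -> target map -> enrichment -> coverage pipeline
#'
#' Executes every stage of the analysis described by a [run_config()] and,
#' when `out_dir` is set, writes the report bundle: `catalog_summary.tsv`
#' (symbol and provenance per catalog gene), `enrichment.tsv` (all tested
#' miRNAs with a `significant` column), `coverage.tsv`, and `summary.json`
#' (union size, class contributions, Venn counts when reconstructible,
#' number of significant miRNAs, top coverage rows, and the parameters
#' used). Any stage error is re-signalled with a stage-tagged message.
#'
#' @param config A `run_config`.
#' @return The report bundle, invisibly: `records`, `catalog`,
#'   `contribution`, `venn`, `map`, `enrichment`, `significant`, `coverage`,
#'   `summary`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- with_stage("catalog", {
    if (!length(config$catalog_paths)) stopf("no catalog tables configured")
    recs <- mapply(function(path, kind) load_mutant_records(path, kind),
                   config$catalog_paths, names(config$catalog_paths),
                   SIMPLIFY = FALSE)
    do.call(bind_records, recs)
  })
  catalog <- with_stage("catalog", build_gene_union(records))
  contribution <- with_stage("catalog", class_contribution(records, catalog))
  venn <- NULL
  if (!is.null(config$venn_totals)) {
    venn <- with_stage("catalog",
                       venn_from_counts(config$venn_totals[[1]],
                                        config$venn_totals[[2]],
                                        length(catalog$symbols)))
  }
  map <- with_stage("target_map", {
    if (!length(config$interactions)) stopf("no interaction files configured")
    lists <- lapply(config$interactions, load_interactions)
    uni <- if (!is.null(config$universe)) {
      readLines(config$universe, warn = FALSE)
    }
    merge_sources(lists, min_sources = config$min_sources,
                  universe = if (!is.null(uni)) trimws(uni[nzchar(trimws(uni))]))
  })
  enrichment <- with_stage("enrichment",
                           run_enrichment(map, catalog$symbols,
                                          alternative = config$alternative,
                                          fdr_threshold = config$fdr_threshold))
  significant <- with_stage("enrichment",
                            filter_significant(enrichment,
                                               config$fdr_threshold))
  coverage <- with_stage("coverage",
                         gene_coverage(significant,
                                       min_count = config$min_coverage))
  summary <- list(
    gene_union_size = length(catalog$symbols),
    class_contribution = as.list(contribution),
    venn = if (!is.null(venn)) list(a_only = venn$a_only, both = venn$both,
                                    b_only = venn$b_only),
    n_mirnas_tested = nrow(enrichment),
    n_significant = nrow(significant),
    top_coverage = if (nrow(coverage)) {
      lapply(seq_len(min(5, nrow(coverage))), function(i) {
        list(gene = coverage$gene[i], n_mirnas = coverage$n_mirnas[i])
      })
    } else list(),
    parameters = list(alternative = config$alternative,
                      fdr_threshold = config$fdr_threshold,
                      min_sources = config$min_sources,
                      min_coverage = config$min_coverage,
                      seed = config$seed))
  if (!is.null(config$out_dir)) {
    with_stage("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      cat_df <- data.frame(
        symbol = catalog$symbols,
        provenance = vapply(catalog$provenance,
                            function(k) paste(sort(k), collapse = ";"), ""),
        stringsAsFactors = FALSE)
      write_tsv_plain(cat_df, file.path(config$out_dir, "catalog_summary.tsv"))
      write_enrichment(enrichment, file.path(config$out_dir, "enrichment.tsv"))
      write_coverage(coverage, file.path(config$out_dir, "coverage.tsv"))
      jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    })
  }
  invisible(list(records = records, catalog = catalog,
                 contribution = contribution, venn = venn, map = map,
                 enrichment = enrichment, significant = significant,
                 coverage = coverage, summary = summary))
}
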