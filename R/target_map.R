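# miRNA-target interaction collections: canonicalization, the interaction
# TSV dialect, and merging resources into a queryable target map.

#' Canonicalize a miRNA identifier
#'
#' Removes internal whitespace artifacts (e.g. `"mmu-miR-466 l"` becomes
#' `"mmu-miR-466l"`) and trims the ends. Mature-arm suffixes (`-3p`/`-5p`)
#' and cluster names are preserved verbatim, so `miR-124` and `miR-124-3p`
#' remain distinct identifiers. The species prefix (e.g. `mmu-`) is stripped
#' only on request. Idempotent.
#'
#' @param x Character vector of miRNA names.
#' @param strip_species Drop a leading three-letter species prefix
#'   (default `FALSE`).
#' @return Canonical identifiers, same length as `x`.
#' @examples
#' canonicalize_mirna("mmu-miR-466 l")
#' canonicalize_mirna("mmu-miR-124-3p", strip_species = TRUE)
#' @export
canonicalize_mirna <- function(x, strip_species = FALSE) {
  if (any(!nzchar(trimws(x)))) {
    stopf("empty miRNA identifier")
  }
  out <- gsub("[[:space:]]+", "", x)
  if (strip_species) {
    out <- sub("^[a-z]{3}-", "", out)
  }
  out
}

#' Load miRNA-target interactions from a TSV resource export
#'
#' Dialect: tab-separated with header `mirna  gene  source  score`; `score`
#' may be empty. miRNA names are canonicalized on load and exact duplicate
#' `(mirna, gene, source)` triples are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @param strip_species Passed to [canonicalize_mirna()].
#' @return A data frame of interactions (`mirna`, `gene`, `source`,
#'   numeric `score` with `NA` where absent).
#' @export
load_interactions <- function(path, strip_species = FALSE) {
  df <- read_tsv_strict(path, c("mirna", "gene", "source", "score"))
  n <- nrow(df)
  if (n == 0) {
    return(data.frame(mirna = character(0), gene = character(0),
                      source = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  bad <- which(!nzchar(trimws(df$gene)))
  if (length(bad)) {
    stopf("line %d of %s: empty gene field", bad[1] + 1L, path)
  }
  bad <- which(!nzchar(trimws(df$mirna)))
  if (length(bad)) {
    stopf("line %d of %s: empty mirna field", bad[1] + 1L, path)
  }
  out <- data.frame(mirna = canonicalize_mirna(df$mirna, strip_species),
                    gene = trimws(df$gene),
                    source = trimws(df$source),
                    score = suppressWarnings(as.numeric(df$score)),
                    stringsAsFactors = FALSE)
  key <- paste(out$mirna, out$gene, out$source, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("dropped ", sum(dup), " duplicate (mirna, gene, source) triple(s)")
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

new_target_map <- function(targets, provenance, universe) {
  structure(list(targets = targets, provenance = provenance,
                 universe = universe),
            class = "target_map")
}

#' Merge interaction resources into a target map
#'
#' Combines per-resource interaction tables into one miRNA -> target-gene-set
#' map. A `(mirna, gene)` pair is retained iff it is supported by at least
#' `min_sources` distinct resources; per-pair provenance records the
#' supporting source set. The gene universe defaults to every gene seen in
#' any input (before the support filter) and can be overridden.
#'
#' @param interaction_lists A single interaction data frame or a list of
#'   them, one per resource (as from [load_interactions()]).
#' @param min_sources Minimum number of distinct supporting sources
#'   (default 1, i.e. the union of resources).
#' @param universe Optional explicit background gene set; must contain every
#'   retained target gene.
#' @return A `target_map`: `targets` (named list of sorted gene sets),
#'   `provenance` (data frame `mirna`, `gene`, list column `sources`), and
#'   `universe`.
#' @export
merge_sources <- function(interaction_lists, min_sources = 1,
                          universe = NULL) {
  if (is.data.frame(interaction_lists)) {
    interaction_lists <- list(interaction_lists)
  }
  all_int <- do.call(rbind, interaction_lists)
  n_resources <- length(unique(all_int$source))
  if (min_sources < 1 || (nrow(all_int) > 0 && min_sources > max(1, n_resources))) {
    stopf("min_sources must be between 1 and the number of resources (%d)",
          max(1, n_resources))
  }
  if (is.null(all_int) || nrow(all_int) == 0) {
    return(new_target_map(list(), data.frame(mirna = character(0),
                                             gene = character(0)),
                          universe %||% character(0)))
  }
  seen_genes <- sort(unique(all_int$gene))
  key <- paste(all_int$mirna, all_int$gene, sep = "\r")
  src_by_pair <- lapply(split(all_int$source, key), unique)
  keep <- names(src_by_pair)[lengths(src_by_pair) >= min_sources]
  keep <- keep[order_c(keep)]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  prov <- data.frame(mirna = vapply(parts, `[`, "", 1),
                     gene = vapply(parts, `[`, "", 2),
                     stringsAsFactors = FALSE)
  prov$sources <- lapply(src_by_pair[keep], sort)
  targets <- lapply(split(prov$gene, prov$mirna), function(g) sort(unique(g)))
  uni <- universe %||% seen_genes
  mapped <- unique(prov$gene)
  missing <- setdiff(mapped, uni)
  if (length(missing)) {
    stopf("universe is missing mapped gene(s): %s",
          paste(missing, collapse = ", "))
  }
  new_target_map(targets, prov, sort(unique(uni)))
}

#' @export
print.target_map <- function(x, ...) {
  cat("Target map:", length(x$targets), "miRNAs,",
      nrow(x$provenance), "(miRNA, gene) pairs, universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Background gene universe of a target map
#'
#' Returns the explicit `override` when given (validated to cover every
#' mapped target gene), else the map's stored universe.
#'
#' @param map A `target_map`.
#' @param override Optional explicit gene set.
#' @return Character vector of gene symbols.
#' @export
gene_universe <- function(map, override = NULL) {
  stopifnot(inherits(map, "target_map"))
  if (is.null(override)) {
    return(map$universe)
  }
  mapped <- unique(unlist(map$targets, use.names = FALSE))
  missing <- setdiff(mapped, override)
  if (length(missing)) {
    stopf("override universe is missing mapped gene(s): %s",
          paste(missing, collapse = ", "))
  }
  sort(unique(override))
}

#' Write a target map (or interaction table) in the interaction TSV dialect
#'
#' A `target_map` is expanded back to one row per `(mirna, gene, source)`
#' triple, so that writing and reloading round-trips the target sets and
#' provenance.
#'
#' @param x A `target_map` or an interaction data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_interactions <- function(x, path) {
  if (inherits(x, "target_map")) {
    prov <- x$provenance
    reps <- lengths(prov$sources)
    x <- data.frame(mirna = rep(prov$mirna, reps),
                    gene = rep(prov$gene, reps),
                    source = unlist(prov$sources) %||% character(0),
                    score = NA_real_, stringsAsFactors = FALSE)
  }
  write_tsv_plain(x[c("mirna", "gene", "source", "score")], path)
}
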