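# Curated cleft-lip gene catalog: mutant-line records, alias-resolved gene
# union, class contributions, and Venn arithmetic on printed set totals.

# Phenotype tokens that may appear (alone or combined) in a cleft-type label.
CLEFT_TOKENS <- c("CLO", "CLP", "CPO", "CL", "CP", "midfacial cleft")

cleft_label_ok <- function(label) {
  nzchar(label) &
    vapply(label, function(l) {
      any(vapply(CLEFT_TOKENS, function(tok) {
        grepl(paste0("\\b", tok, "\\b"), l)
      }, logical(1)))
    }, logical(1))
}

# Parse "Sym (aka Alt1 & Alt2)" into list(symbol=, aliases=chr).
parse_aka <- function(token) {
  m <- regmatches(token, regexec("^(.*?)\\s*\\(aka\\s+([^)]*)\\)\\s*$", token))[[1]]
  if (length(m) == 3) {
    alts <- trimws(strsplit(m[3], "&", fixed = TRUE)[[1]])
    list(symbol = trimws(m[2]), aliases = alts[nzchar(alts)])
  } else {
    list(symbol = trimws(token), aliases = character(0))
  }
}

# Parse an aliases field: ";"-separated "primary=alt1|alt2" pairs.
parse_alias_field <- function(x) {
  out <- list()
  for (pair in split_field(x, ";")) {
    kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stopf("cannot parse alias annotation '%s'", pair)
    }
    alts <- trimws(strsplit(kv[2], "|", fixed = TRUE)[[1]])
    out[[trimws(kv[1])]] <- alts[nzchar(alts)]
  }
  out
}

new_mutant_records <- function(df) {
  structure(df, class = c("mutant_records", "data.frame"))
}

#' Construct mutant-line records in code
#'
#' Builds a validated `mutant_records` table from vectors, mainly for tests
#' and examples; file-based workflows use [load_mutant_records()].
#'
#' @param record_id Character vector of opaque row identifiers.
#' @param table_kind One of `"single"`, `"spontaneous"`, `"compound"`
#'   (recycled if scalar).
#' @param gene_symbols List of character vectors (0-2 primary symbols; empty
#'   only for strains with no identified gene, flagged "Not gene" in `note`).
#' @param cleft_type Character vector of phenotype labels; each must mention
#'   at least one of CLO, CLP, CPO, CL, CP, "midfacial cleft".
#' @param aliases List of named lists mapping a primary symbol to its
#'   alternate symbols.
#' @param penetrance_note,note,pmids Optional free-text / identifier fields.
#' @return A `mutant_records` data frame.
#' @examples
#' mutant_records("r1", "single", list("Wnt9b"), "CLO or CLP",
#'                aliases = list(list(Wnt9b = "Clf1")))
#' @export
mutant_records <- function(record_id, table_kind, gene_symbols, cleft_type,
                           aliases = NULL, penetrance_note = "", note = "",
                           pmids = NULL) {
  n <- length(record_id)
  if (!is.list(gene_symbols)) gene_symbols <- as.list(gene_symbols)
  aliases <- aliases %||% rep(list(list()), n)
  pmids <- pmids %||% rep(list(character(0)), n)
  df <- data.frame(record_id = record_id,
                   table_kind = rep_len(table_kind, n),
                   cleft_type = rep_len(cleft_type, n),
                   penetrance_note = rep_len(penetrance_note, n),
                   note = rep_len(note, n),
                   stringsAsFactors = FALSE)
  df$gene_symbols <- gene_symbols
  df$aliases <- aliases
  df$pmids <- pmids
  validate_mutant_records(df)
  new_mutant_records(df)
}

validate_mutant_records <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("record ", df$record_id[i]) else
      paste0("line ", lines[i])
  }
  kinds <- c("single", "spontaneous", "compound")
  for (i in seq_len(nrow(df))) {
    if (!df$table_kind[i] %in% kinds) {
      stopf("%s: unknown table_kind '%s'", where(i), df$table_kind[i])
    }
    syms <- df$gene_symbols[[i]]
    if (length(syms) == 0 && !grepl("Not gene", df$note[i], fixed = TRUE)) {
      stopf("%s: no gene symbol and note does not say 'Not gene'", where(i))
    }
    if (df$table_kind[i] == "compound" && length(syms) != 2) {
      stopf("%s: compound record must carry exactly 2 gene symbols, got %d",
            where(i), length(syms))
    }
    if (length(syms) > 2) {
      stopf("%s: at most 2 primary gene symbols per record", where(i))
    }
    if (!cleft_label_ok(df$cleft_type[i])) {
      stopf("%s: unknown cleft_type token in '%s'", where(i), df$cleft_type[i])
    }
  }
  invisible(df)
}

#' Load curated mutant-line records from a catalog TSV
#'
#' Reads one transcribed catalog table (single-gene, spontaneous, or compound
#' mutant lines) in the tab-separated catalog dialect with header
#' `record_id  table_kind  gene_symbols  aliases  cleft_type  penetrance_note
#' pmids  note`. `gene_symbols` is ";"-separated and may carry inline
#' `"(aka Alt)"` alias annotations; the `aliases` column holds additional
#' `primary=alt1|alt2` pairs (";"-separated); `pmids` is ";"-separated.
#'
#' @param path Path to the TSV file.
#' @param table_kind Optional expected kind (`"single"`, `"spontaneous"`,
#'   `"compound"`); if given, every row must match.
#' @return A `mutant_records` data frame with list columns `gene_symbols`,
#'   `aliases` and `pmids`.
#' @examples
#' recs <- load_mutant_records(cleftmir_extdata("table2_spontaneous.tsv"))
#' nrow(recs)
#' @seealso [build_gene_union()], [class_contribution()]
#' @export
load_mutant_records <- function(path, table_kind = NULL) {
  cols <- c("record_id", "table_kind", "gene_symbols", "aliases",
            "cleft_type", "penetrance_note", "pmids", "note")
  # reject ragged rows before read.delim silently pads them
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw)) {
    ntab <- lengths(regmatches(raw, gregexpr("\t", raw, fixed = TRUE)))
    bad <- which(ntab != ntab[1])
    if (length(bad)) {
      stopf("malformed row at line %d of %s: expected %d fields, found %d",
            bad[1], path, ntab[1] + 1L, ntab[bad[1]] + 1L)
    }
  }
  df <- read_tsv_strict(path, cols)
  n <- nrow(df)
  gene_symbols <- vector("list", n)
  aliases <- vector("list", n)
  pmids <- vector("list", n)
  for (i in seq_len(n)) {
    amap <- parse_alias_field(df$aliases[i])
    syms <- character(0)
    for (tok in split_field(df$gene_symbols[i], ";")) {
      parsed <- parse_aka(tok)
      syms <- c(syms, parsed$symbol)
      if (length(parsed$aliases)) {
        amap[[parsed$symbol]] <- union(amap[[parsed$symbol]] %||% character(0),
                                       parsed$aliases)
      }
    }
    gene_symbols[[i]] <- syms
    aliases[[i]] <- amap
    pmids[[i]] <- split_field(df$pmids[i], ";")
  }
  out <- df[c("record_id", "table_kind", "cleft_type", "penetrance_note",
              "note")]
  out$gene_symbols <- gene_symbols
  out$aliases <- aliases
  out$pmids <- pmids
  validate_mutant_records(out, lines = seq_len(n) + 1L)
  if (!is.null(table_kind)) {
    table_kind <- match.arg(table_kind, c("single", "spontaneous", "compound"))
    bad <- which(out$table_kind != table_kind)
    if (length(bad)) {
      stopf("line %d of %s: table_kind '%s' does not match expected '%s'",
            bad[1] + 1L, path, out$table_kind[bad[1]], table_kind)
    }
  }
  new_mutant_records(out)
}

# Collect one conflict-checked alias index (alt -> primary) across records.
build_alias_index <- function(records) {
  idx <- character(0)
  for (amap in records$aliases) {
    for (primary in names(amap)) {
      for (alt in amap[[primary]]) {
        if (alt %in% names(idx) && idx[[alt]] != primary) {
          stopf("alias conflict: '%s' assigned to both '%s' and '%s'",
                alt, idx[[alt]], primary)
        }
        idx[[alt]] <- primary
      }
    }
  }
  idx
}

resolve_symbols <- function(symbols, alias_index) {
  symbols <- trimws(symbols)
  hit <- symbols %in% names(alias_index)
  symbols[hit] <- unname(alias_index[symbols[hit]])
  symbols
}

#' Build the deduplicated, alias-resolved gene catalog
#'
#' Takes the union of primary gene symbols across mutant-line records after
#' resolving alternate symbols (e.g. `Clf1` merges into `Wnt9b`). Records
#' with no identified gene ("Not gene" strains) contribute nothing to the
#' union. Matching is case-sensitive after whitespace trimming, as mouse
#' symbols are case-meaningful.
#'
#' @param records A `mutant_records` data frame (tables may be concatenated
#'   with `rbind()`).
#' @return A `gene_catalog` object: sorted `symbols`, per-symbol `provenance`
#'   (which table kinds contributed it), and the `alias_index`
#'   (alternate -> primary).
#' @examples
#' recs <- load_mutant_records(cleftmir_extdata("table2_spontaneous.tsv"))
#' build_gene_union(recs)
#' @export
build_gene_union <- function(records) {
  stopifnot(inherits(records, "mutant_records"))
  alias_index <- build_alias_index(records)
  provenance <- list()
  for (i in seq_len(nrow(records))) {
    syms <- resolve_symbols(records$gene_symbols[[i]], alias_index)
    for (s in syms) {
      provenance[[s]] <- union(provenance[[s]] %||% character(0),
                               records$table_kind[i])
    }
  }
  symbols <- names(provenance) %||% character(0)
  clash <- intersect(symbols, names(alias_index))
  if (length(clash)) {
    stopf("symbol(s) %s appear both as primary and as alias",
          paste(clash, collapse = ", "))
  }
  ord <- order_c(symbols)
  structure(list(symbols = symbols[ord],
                 provenance = provenance[ord],
                 alias_index = alias_index),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  kinds <- sort(unique(unlist(x$provenance)))
  cat("Gene catalog:", length(x$symbols), "symbols from table kind(s):",
      paste(kinds, collapse = ", "), "\n")
  cat("  aliases resolved:", length(x$alias_index), "\n")
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) length(x$symbols)

#' Decompose the catalog into per-table-kind contributions
#'
#' Counts distinct genes contributed by single-gene mutants, then genes new
#' to the spontaneous table, then genes new to the compound table, in that
#' fixed precedence. The three components always sum to the catalog size.
#'
#' @param records The `mutant_records` the catalog was built from.
#' @param catalog Optional pre-built [build_gene_union()] result for the same
#'   records.
#' @return Named integer vector
#'   `c(single_total, spontaneous_new, compound_new)`.
#' @export
class_contribution <- function(records, catalog = NULL) {
  catalog <- catalog %||% build_gene_union(records)
  sym_of <- function(kind) {
    idx <- records$table_kind == kind
    unique(resolve_symbols(unlist(records$gene_symbols[idx]) %||% character(0),
                           catalog$alias_index))
  }
  single <- sym_of("single")
  spont <- sym_of("spontaneous")
  comp <- sym_of("compound")
  out <- c(single_total = length(single),
           spontaneous_new = length(setdiff(spont, single)),
           compound_new = length(setdiff(comp, union(single, spont))))
  stopifnot(sum(out) == length(catalog$symbols))
  out
}

#' Venn partition from printed set totals
#'
#' Recovers the two-set Venn partition (A-only, both, B-only) from the sizes
#' of two sets and of their union by inclusion-exclusion. This is how the
#' review-vs-database overlap is reconstructed when only aggregate counts,
#' not per-gene memberships, are printed.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param n_union Size of their union; must satisfy
#'   `max(n_a, n_b) <= n_union <= n_a + n_b`.
#' @return A `venn_counts` object with fields `a_only`, `both`, `b_only`.
#' @examples
#' venn_from_counts(25, 41, 55)  # -> 14 / 11 / 30
#' @export
venn_from_counts <- function(n_a, n_b, n_union) {
  stopifnot(length(n_a) == 1, length(n_b) == 1, length(n_union) == 1)
  counts <- c(n_a, n_b, n_union)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("set sizes must be non-negative integers")
  }
  if (n_union < max(n_a, n_b) || n_union > n_a + n_b) {
    stopf("counts inconsistent with any pair of sets: need max(%d, %d) <= %d <= %d",
          n_a, n_b, n_union, n_a + n_b)
  }
  both <- n_a + n_b - n_union
  structure(list(a_only = n_a - both, both = both, b_only = n_b - both),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("Venn partition: A-only %d | both %d | B-only %d (union %d)\n",
              x$a_only, x$both, x$b_only, x$a_only + x$both + x$b_only))
  invisible(x)
}

#' Filter mutant-line records by cleft-type label
#'
#' @param records A `mutant_records` data frame.
#' @param label A recognized cleft-type token (CLO, CLP, CPO, CL, CP,
#'   "midfacial cleft").
#' @param mode `"exact"` keeps records whose label equals `label` verbatim;
#'   `"contains"` keeps records whose label mentions the token (on word
#'   boundaries, so `"CL"` does not match inside `"CLP"`).
#' @return The matching subset, input order preserved.
#' @examples
#' recs <- load_mutant_records(cleftmir_extdata("table1_single_gene.tsv"))
#' nrow(filter_by_cleft_type(recs, "CLO"))
#' @export
filter_by_cleft_type <- function(records, label,
                                 mode = c("exact", "contains")) {
  stopifnot(inherits(records, "mutant_records"))
  mode <- match.arg(mode)
  if (!label %in% CLEFT_TOKENS) {
    stopf("unknown cleft_type label '%s'; recognized tokens: %s",
          label, paste(CLEFT_TOKENS, collapse = ", "))
  }
  keep <- if (mode == "exact") {
    records$cleft_type == label
  } else {
    grepl(paste0("\\b", label, "\\b"), records$cleft_type)
  }
  new_mutant_records(records[keep, , drop = FALSE])
}
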