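# Internal helpers shared across modules.

# Read a tab-separated file with a mandatory header, keeping all columns as
# character and empty fields as "".
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("malformed file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# Split a ";"-separated field, dropping empty tokens, trimming whitespace.
split_field <- function(x, sep = ";") {
  parts <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# Locale-independent ordering (C collation) so tie-breaks are reproducible.
order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
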