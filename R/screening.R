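# Systematic-review bookkeeping: screening ledger, PRISMA stage counts,
# and chance-corrected inter-screener agreement.

STAGES <- c("identified", "screened", "full_text", "included")

#' Construct a screening ledger
#'
#' One row per candidate record in a two-screener systematic review, carrying
#' each screener's binary include/exclude call and the furthest PRISMA stage
#' the record reached.
#'
#' @param record_id Character vector of record identifiers.
#' @param screenerA,screenerB Logical include decisions.
#' @param stage Furthest stage reached: one of `"identified"`, `"screened"`,
#'   `"full_text"`, `"included"`.
#' @return A `screening_ledger` data frame.
#' @export
screening_ledger <- function(record_id, screenerA, screenerB, stage) {
  bad <- setdiff(unique(stage), STAGES)
  if (length(bad)) {
    stopf("unknown stage value(s): %s", paste(bad, collapse = ", "))
  }
  df <- data.frame(record_id = record_id,
                   screenerA = as.logical(screenerA),
                   screenerB = as.logical(screenerB),
                   stage = stage, stringsAsFactors = FALSE)
  structure(df, class = c("screening_ledger", "data.frame"))
}

#' Load a screening ledger TSV
#'
#' Dialect: tab-separated with header
#' `record_id  screenerA  screenerB  stage`, stage in
#' identified/screened/full_text/included, screener columns TRUE/FALSE.
#'
#' @param path Path to the TSV file.
#' @return A `screening_ledger` data frame.
#' @export
load_screening_ledger <- function(path) {
  df <- read_tsv_strict(path, c("record_id", "screenerA", "screenerB", "stage"))
  screening_ledger(df$record_id,
                   toupper(df$screenerA) == "TRUE",
                   toupper(df$screenerB) == "TRUE",
                   df$stage)
}

#' PRISMA flow counts
#'
#' Counts the records that reached each review stage. Counts are cumulative
#' along the stage order (a record whose furthest stage is `full_text` also
#' counts as identified and screened), hence non-increasing.
#'
#' @param ledger A `screening_ledger`.
#' @return Named integer vector over
#'   `identified, screened, full_text, included`.
#' @export
prisma_flow <- function(ledger) {
  stopifnot(inherits(ledger, "screening_ledger"))
  reached <- match(ledger$stage, STAGES)
  counts <- vapply(seq_along(STAGES),
                   function(i) sum(reached >= i), integer(1))
  names(counts) <- STAGES
  stopifnot(all(diff(counts) <= 0))
  counts
}

#' Two-screener agreement table
#'
#' Cross-tabulates the two screeners' include/exclude decisions into the 2x2
#' layout `[[both_include, A_only], [B_only, both_exclude]]` expected by
#' [cohen_kappa()].
#'
#' @param ledger A `screening_ledger`.
#' @return A 2x2 integer matrix.
#' @export
agreement_table <- function(ledger) {
  stopifnot(inherits(ledger, "screening_ledger"))
  a <- ledger$screenerA
  b <- ledger$screenerB
  matrix(c(sum(a & b), sum(!a & b), sum(a & !b), sum(!a & !b)),
         nrow = 2,
         dimnames = list(A = c("include", "exclude"),
                         B = c("include", "exclude")))
}

#' Cohen's kappa for two screeners
#'
#' Unweighted kappa for a binary include/exclude decision:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal products. Returns exactly 1 for
#' perfect agreement (zero off-diagonals), including the degenerate case
#' where the marginals make `p_e = 1`. (With two categories, `p_e = 1`
#' forces both off-diagonals to zero, so the imperfect-degenerate error
#' branch is defensive only.)
#'
#' @param agreement 2x2 count matrix
#'   `[[both_include, A_only], [B_only, both_exclude]]`.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 65), 2))  # 0.625
#' @export
cohen_kappa <- function(agreement) {
  m <- as.matrix(agreement)
  if (!all(dim(m) == c(2, 2)) || any(m < 0)) {
    stopf("agreement must be a 2x2 matrix of non-negative counts")
  }
  n <- sum(m)
  if (n == 0) stopf("agreement table is empty")
  if (m[1, 2] == 0 && m[2, 1] == 0) {
    return(1)
  }
  p_o <- (m[1, 1] + m[2, 2]) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) {
    stopf("degenerate marginals: chance agreement is 1 but agreement is imperfect")
  }
  (p_o - p_e) / (1 - p_e)
}
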