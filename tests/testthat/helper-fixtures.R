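# Shared fixtures and independent oracles for the test suite.

fix_path <- function(file) cleftmir_extdata(file)

load_all_records <- function() {
  bind_records(
    load_mutant_records(fix_path("table1_single_gene.tsv"), "single"),
    load_mutant_records(fix_path("table2_spontaneous.tsv"), "spontaneous"),
    load_mutant_records(fix_path("table3_compound.tsv"), "compound"))
}

load_tab4 <- function() load_enrichment_table(fix_path("table4_enrichment.tsv"))
load_tab5 <- function() load_coverage_table(fix_path("table5_coverage.tsv"))

# Independent exact-Fisher oracle: direct enumeration of the hypergeometric
# support with ratio-of-binomials arithmetic (no log-space, no shared code
# with fisher_pvalue).
fisher_oracle <- function(a, b, c, d, alternative = "greater") {
  N <- a + b + c + d
  m <- a + b
  k <- a + c
  supp <- max(0, m + k - N):min(m, k)
  pr <- choose(m, supp) * choose(N - m, k - supp) / choose(N, k)
  if (alternative == "greater") {
    sum(pr[supp >= a])
  } else {
    p0 <- pr[supp == a]
    sum(pr[pr <= p0 * (1 + 1e-7)])
  }
}

# Small in-code interaction table builder.
make_interactions <- function(mirna, gene, source = "res1", score = NA_real_) {
  data.frame(mirna = mirna, gene = gene,
             source = rep_len(source, length(mirna)),
             score = rep_len(score, length(mirna)),
             stringsAsFactors = FALSE)
}

write_interactions_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# Overlap-with-query counts per miRNA straight from an interaction table.
overlaps_from_db <- function(db) {
  vapply(split(db$interactions$gene, db$interactions$mirna),
         function(g) length(intersect(g, db$query)), integer(1))
}
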