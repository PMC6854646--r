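# Catalog curation: record loading, alias-resolved union, class
# contributions, Venn arithmetic, cleft-type filtering.

test_that("catalog fixtures load with the expected record counts and parses", {
  t1 <- load_mutant_records(fix_path("table1_single_gene.tsv"), "single")
  t2 <- load_mutant_records(fix_path("table2_spontaneous.tsv"), "spontaneous")
  t3 <- load_mutant_records(fix_path("table3_compound.tsv"), "compound")
  expect_equal(nrow(t1), 39)
  expect_equal(nrow(t2), 9)
  expect_equal(nrow(t3), 10)

  # inline "(aka ...)" annotation
  wnt <- t2[vapply(t2$gene_symbols, function(s) "Wnt9b" %in% s, logical(1)), ]
  expect_equal(wnt$gene_symbols[[1]], "Wnt9b")
  expect_equal(wnt$aliases[[1]]$Wnt9b, "Clf1")

  # aliases-column annotation on a compound row
  mirc <- t3[t3$record_id == "T3-06", ]
  expect_equal(mirc$gene_symbols[[1]], c("Mirc1", "Mirc3"))
  expect_equal(mirc$aliases[[1]]$Mirc3, "miR-106b-25")

  # "Not gene" strains carry no symbols but remain records
  expect_equal(sum(lengths(t2$gene_symbols) == 0), 4)

  # every compound record has exactly two symbols
  expect_true(all(lengths(t3$gene_symbols) == 2))
})

test_that("loader rejects malformed input", {
  hdr <- "record_id\ttable_kind\tgene_symbols\taliases\tcleft_type\tpenetrance_note\tpmids\tnote"
  f <- tempfile(fileext = ".tsv")

  writeLines(c(hdr, "r1\tsingle\tGeneA\t\tCLO\t\t\tok\textra"), f)
  expect_error(load_mutant_records(f), "line 2")

  writeLines(c(hdr, "r1\tsingle\tGeneA\t\tWEIRD\t\t\tok"), f)
  expect_error(load_mutant_records(f), "cleft_type")

  writeLines(c(hdr, "r1\tcompound\tGeneA\t\tCLO\t\t\tok"), f)
  expect_error(load_mutant_records(f), "exactly 2")

  writeLines(c(hdr, "r1\tsingle\t\t\tCLO\t\t\tno gene named"), f)
  expect_error(load_mutant_records(f), "Not gene")

  writeLines(hdr, f)
  expect_equal(nrow(load_mutant_records(f)), 0)
})

test_that("gene union reproduces the 55-gene catalog with provenance", {
  recs <- load_all_records()
  catalog <- build_gene_union(recs)
  expect_length(catalog$symbols, 55)
  expect_false(any(names(catalog$alias_index) %in% catalog$symbols))
  expect_true(all(lengths(catalog$provenance) >= 1))
  # symbol shared across tables is counted once with both provenances
  expect_setequal(catalog$provenance$Wnt9b,
                  c("single", "spontaneous", "compound"))
  # the alias Clf1 resolves onto the catalog symbol Wnt9b
  expect_equal(unname(catalog$alias_index["Clf1"]), "Wnt9b")
})

test_that("gene union is order-independent and idempotent", {
  recs <- load_all_records()
  ref <- build_gene_union(recs)
  set.seed(11)
  for (i in 1:5) {
    perm <- recs[sample(nrow(recs)), , drop = FALSE]
    class(perm) <- c("mutant_records", "data.frame")
    expect_identical(build_gene_union(perm)$symbols, ref$symbols)
  }
  expect_identical(build_gene_union(recs)$symbols, ref$symbols)
})

test_that("alias conflicts are rejected", {
  recs <- mutant_records(c("r1", "r2"), "single", list("A", "B"), "CLO",
                         aliases = list(list(A = "X"), list(B = "X")))
  expect_error(build_gene_union(recs), "alias conflict")
})

test_that("class contributions decompose the union (39 + 4 + 12 = 55)", {
  recs <- load_all_records()
  catalog <- build_gene_union(recs)
  contrib <- class_contribution(recs, catalog)
  expect_equal(unname(contrib), c(39, 4, 12))
  expect_equal(sum(contrib), length(catalog$symbols))
})

test_that("class contributions: hand-enumerated and degenerate cases", {
  recs <- mutant_records(
    c("s1", "p1", "c1"), c("single", "spontaneous", "compound"),
    list("A", "A", c("A", "B")), "CLO")
  expect_equal(unname(class_contribution(recs)), c(1, 0, 1))

  empty <- mutant_records(character(0), character(0), list(), character(0))
  expect_equal(unname(class_contribution(empty)), c(0, 0, 0))
})

test_that("venn_from_counts recovers printed partitions and rejects impossible ones", {
  v <- venn_from_counts(25, 41, 55)
  expect_equal(c(v$a_only, v$both, v$b_only), c(14, 11, 30))
  v <- venn_from_counts(5, 5, 5)
  expect_equal(c(v$a_only, v$both, v$b_only), c(0, 5, 0))
  v <- venn_from_counts(3, 4, 7)
  expect_equal(c(v$a_only, v$both, v$b_only), c(3, 0, 4))
  expect_error(venn_from_counts(3, 4, 8), "inconsistent")
  expect_error(venn_from_counts(3, 4, 2), "inconsistent")
  expect_error(venn_from_counts(-1, 4, 4), "non-negative")
})

test_that("venn_from_counts round-trips random explicit sets", {
  set.seed(202)
  for (i in 1:1000) {
    pool <- seq_len(sample(3:40, 1))
    a <- sample(pool, sample.int(length(pool), 1))
    b <- sample(pool, sample.int(length(pool), 1))
    v <- venn_from_counts(length(a), length(b), length(union(a, b)))
    expect_identical(v$both, length(intersect(a, b)))
    expect_identical(v$a_only, length(setdiff(a, b)))
    expect_identical(v$b_only, length(setdiff(b, a)))
  }
})

test_that("cleft-type filter: exact and token-containment modes", {
  t1 <- load_mutant_records(fix_path("table1_single_gene.tsv"), "single")
  clo <- filter_by_cleft_type(t1, "CLO")
  expect_equal(sort(unlist(clo$gene_symbols)),
               c("Bmp4", "Cplane2", "Myh10", "Rpgrip1l", "Sp8"))

  cpo <- filter_by_cleft_type(t1, "CPO", mode = "contains")
  expect_true(all(grepl("CPO", cpo$cleft_type)))
  expect_gt(nrow(cpo), 0)
  # "CL" must not match inside "CLO"/"CLP"
  cl <- filter_by_cleft_type(t1, "CL", mode = "contains")
  expect_true(all(grepl("\\bCL\\b", cl$cleft_type)))

  expect_equal(nrow(filter_by_cleft_type(t1, "CP")), 0)
  expect_error(filter_by_cleft_type(t1, "XYZ"), "unknown cleft_type")
})
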