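# Enrichment: contingency construction, exact Fisher p-values, BH
# adjustment, the run wrapper, and the significance filter.

test_that("build_contingency performs the set arithmetic", {
  U <- sprintf("g%02d", 1:20)
  Q <- U[1:5]
  T_ <- c(U[4:5], U[10:15])  # |T| = 8, overlap 2? no: g04,g05 in Q -> a = 2
  ct <- build_contingency(T_, Q, U)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(2, 6, 3, 9))
  expect_equal(ct$N, 20)
  expect_equal(ct$a + ct$b, length(unique(T_)))
  expect_equal(ct$a + ct$c, length(intersect(Q, U)))

  # toy case: |U|=20, |Q|=5, |T|=8, overlap 3
  T2 <- c(U[1:3], U[10:14])
  ct2 <- build_contingency(T2, Q, U)
  expect_equal(c(ct2$a, ct2$b, ct2$c, ct2$d), c(3, 5, 2, 10))

  ct3 <- build_contingency(U, U, U)
  expect_equal(c(ct3$a, ct3$b, ct3$c, ct3$d), c(20, 0, 0, 0))

  ct4 <- build_contingency(U[6:8], U[1:5], U)
  expect_equal(ct4$a, 0)

  expect_message(build_contingency(U[1:2], c(U[1:3], "NOT_THERE"), U),
                 "dropped 1")
  expect_error(build_contingency(U[1], U[2], character(0)), "empty universe")
  expect_error(build_contingency(c(U[1], "ALIEN"), U[1:2], U), "outside")
})

test_that("fisher_pvalue matches hand enumeration on the 4,4,4,4 margins", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_pvalue(tab, "greater"), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_pvalue(tab, "two_sided"), 34 / 70, tolerance = 1e-12)
  # a = 0 upper tail is 1
  expect_equal(fisher_pvalue(matrix(c(0, 5, 3, 12), 2, byrow = TRUE),
                             "greater"), 1)
})

test_that("fisher_pvalue agrees with the enumeration oracle and fisher.test", {
  set.seed(91)
  for (i in 1:200) {
    cts <- as.list(sample(0:12, 4, replace = TRUE))
    names(cts) <- c("a", "b", "c", "d")
    if (sum(unlist(cts)) == 0) next
    tab <- matrix(c(cts$a, cts$b, cts$c, cts$d), 2, byrow = TRUE)
    expect_equal(fisher_pvalue(tab, "greater"),
                 do.call(fisher_oracle, c(cts, alternative = "greater")),
                 tolerance = 1e-9)
    expect_equal(fisher_pvalue(tab, "two_sided"),
                 stats::fisher.test(tab, alternative = "two.sided")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_pvalue(tab, "greater"),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_pvalue is in (0,1] and decreases in a with fixed margins", {
  for (margins in list(c(m = 8, k = 6, N = 25), c(m = 10, k = 10, N = 20))) {
    m <- margins[["m"]]; k <- margins[["k"]]; N <- margins[["N"]]
    supp <- max(0, m + k - N):min(m, k)
    p <- vapply(supp, function(a) {
      fisher_pvalue(matrix(c(a, m - a, k - a, N - m - k + a), 2, byrow = TRUE),
                    "greater")
    }, numeric(1))
    expect_true(all(p > 0 & p <= 1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("bh_adjust applies the step-up rule", {
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.2 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("bh_adjust properties: dominates p, monotone, permutation-equivariant, matches p.adjust", {
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # ties receive equal adjusted values
  q <- bh_adjust(c(0.02, 0.02, 0.9))
  expect_equal(q[1], q[2])
})

test_that("run_enrichment produces one flagged, sorted row per miRNA", {
  U <- sprintf("g%02d", 1:40)
  Q <- U[1:8]
  ints <- make_interactions(
    rep(c("mA", "mB", "mC"), times = c(6, 6, 6)),
    c(U[1:6],            # mA: all in query
      U[c(1, 15:19)],    # mB: 1 in query
      U[21:26]),         # mC: none
    source = "res1")
  map <- merge_sources(ints)
  res <- run_enrichment(map, Q, universe = U, fdr_threshold = 0.2)
  expect_s3_class(res, "enrichment_results")
  expect_equal(nrow(res), 3)
  expect_equal(res$mirna[1], "mA")
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(res$k, lengths(res$shared_genes))
  expect_true(all(res$fdr >= res$p_value))
  expect_equal(res$fdr, bh_adjust(res$p_value))
  expect_identical(res$significant, res$fdr < 0.2)
  # contingency self-consistency: k equals a rebuilt from sets
  for (i in seq_len(nrow(res))) {
    ct <- build_contingency(map$targets[[res$mirna[i]]], Q, U)
    expect_equal(res$k[i], ct$a)
    expect_identical(res$shared_genes[[i]], ct$shared)
  }
})

test_that("run_enrichment degenerate situations", {
  U <- sprintf("g%02d", 1:30)
  ints <- make_interactions(rep(c("m1", "m2"), each = 5),
                            c(U[1:5], U[6:10]))
  map <- merge_sources(ints, universe = U)
  # query disjoint from every target set: p = 1 everywhere
  res <- run_enrichment(map, U[21:25])
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
  # saturated query: every p = 1
  res2 <- run_enrichment(map, U)
  expect_true(all(res2$p_value == 1))
  expect_error(run_enrichment(map, "NOT_IN_UNIVERSE"), "does not intersect")
  expect_error(run_enrichment(map, U[1], fdr_threshold = 0), "fdr_threshold")
})

test_that("a planted miRNA attains the minimum p across replicates", {
  for (rep_seed in 1:20) {
    cfg <- sim_config(100, 20, 51, 10, planted = 1, odds_ratio = 40,
                      seed = 1000 + rep_seed)
    db <- generate_target_db(cfg)
    map <- merge_sources(db$interactions, universe = db$universe)
    res <- run_enrichment(map, db$query)
    expect_equal(res$mirna[1], "sim-miR-001")
  }
})

test_that("filter_significant is a strict threshold preserving order", {
  tab4 <- load_tab4()
  expect_equal(nrow(filter_significant(tab4, 0.2)), 33)
  expect_equal(nrow(filter_significant(tab4, 0)), 0)
  kept <- filter_significant(tab4, 0.07)
  expect_identical(kept$mirna, tab4$mirna[tab4$fdr < 0.07])
  # boundary: a row with fdr exactly at the threshold is dropped
  expect_equal(nrow(filter_significant(data.frame(fdr = c(0.2, 0.19)), 0.2)), 1)
  expect_error(filter_significant(data.frame(x = 1), 0.2), "fdr")
})

test_that("enrichment results round-trip through the output dialect", {
  tab4 <- load_tab4()
  f <- tempfile(fileext = ".tsv")
  write_enrichment(tab4, f)
  again <- load_enrichment_table(f)
  expect_equal(again$mirna, tab4$mirna)
  expect_equal(again$shared_genes, tab4$shared_genes)
  expect_equal(again$p_value, tab4$p_value)
  expect_equal(again$fdr, tab4$fdr)
})
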