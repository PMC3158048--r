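test_that("audic-claverie p-values behave at the boundaries and symmetries", {
  expect_equal(audic_claverie_pvalue(0, 0, 1e6, 1e6), 1)
  expect_equal(audic_claverie_pvalue(5, 20, 1e6, 1e6),
               audic_claverie_pvalue(20, 5, 1e6, 1e6))
  expect_equal(audic_claverie_pvalue(5, 20, 1e6, 3e6),
               audic_claverie_pvalue(20, 5, 3e6, 1e6))
  expect_error(audic_claverie_pvalue(-1, 3, 1e6, 1e6), "non-negative")
  expect_error(audic_claverie_pvalue(1, 3, 0, 1e6), "positive")
})

test_that("audic-claverie matches direct tail summation", {
  set.seed(7)
  for (i in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    r <- sample(c(0.3, 1, 2.5), 1)
    got <- audic_claverie_pvalue(x, y, 1e6, r * 1e6)
    want <- ac_brute(x, y, 1e6, r * 1e6)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("identical expression tables yield no significant genes", {
  e <- data.frame(gene_id = sprintf("g%d", 1:50),
                  count = rpois(50, 200), length = 1000)
  de <- diff_expression(e, e, 1e6, 1e6)
  expect_false(any(de$significant))
  expect_true(all(de$fold_change == 1))
})

test_that("the fold-change filter dominates a significant p-value", {
  e1 <- data.frame(gene_id = c("a", "b"), count = c(100, 1000), length = 1000)
  e2 <- data.frame(gene_id = c("a", "b"), count = c(250, 1000), length = 1000)
  de <- diff_expression(e1, e2, 1e6, 1e6, fold_cutoff = 3)
  a <- de[de$gene_id == "a", ]
  expect_lt(a$p_ac, 0.05)          # clearly unequal counts
  expect_false(a$significant)      # but only 2.5-fold
})

test_that("genes absent from one table count as zero there", {
  e1 <- data.frame(gene_id = c("a", "b"), count = c(500, 50), length = 1000)
  e2 <- data.frame(gene_id = "b", count = 60, length = 1000)
  de <- diff_expression(e1, e2, 1e6, 1e6)
  a <- de[de$gene_id == "a", ]
  expect_equal(a$count_2, 0)
  expect_equal(a$fold_change, 0)
  expect_true(a$significant)
  expect_equal(a$direction, "down")
})

test_that("planted fold changes are recovered with controlled FDP", {
  se <- simulate_expression_counts(2000, 100, fold = 5, seed = 13)
  de <- diff_expression(se$expr_1, se$expr_2, se$N1, se$N2)
  sens <- mean(de$significant[match(se$truth$gene_id[se$truth$changed],
                                    de$gene_id)])
  called <- de$gene_id[de$significant]
  fdp <- mean(!se$truth$changed[match(called, se$truth$gene_id)])
  expect_gte(sens, 0.9)
  expect_lte(fdp, 2 * 0.05)
  up <- se$truth$gene_id[se$truth$direction == "up"]
  expect_true(all(de$direction[de$significant &
                                 de$gene_id %in% up] == "up"))
})

test_that("differential splicing is null on identical tables and matches the hypergeometric oracle", {
  counts <- data.frame(event_id = c("a", "b"), inc_reads = c(30, 200),
                       exc_reads = c(10, 50), inc_positions = 146,
                       exc_positions = 32)
  pt <- as_psi_table(counts)
  ds <- diff_splicing(pt, pt)
  expect_equal(ds$delta_psi, c(0, 0))
  expect_equal(ds$p, c(1, 1))

  # 2x2 table (30,5 | 10,25): Fisher two-sided p by exhaustive enumeration
  c1 <- data.frame(event_id = "e", inc_reads = 30, exc_reads = 5,
                   inc_positions = 146, exc_positions = 32)
  c2 <- data.frame(event_id = "e", inc_reads = 10, exc_reads = 25,
                   inc_positions = 146, exc_positions = 32)
  ds2 <- diff_splicing(as_psi_table(c1), as_psi_table(c2))
  ks <- 0:35
  lp <- lchoose(40, ks) + lchoose(30, 35 - ks) - lchoose(70, 35)
  obs <- lp[31]
  expect_equal(ds2$p, sum(exp(lp[lp <= obs + 1e-7])), tolerance = 1e-6)
})

test_that("a pure switch event is labeled epithelial-inclusion at delta -1", {
  epi <- data.frame(event_id = "mxe", inc_reads = 500, exc_reads = 0,
                    inc_positions = 146, exc_positions = 146)
  mes <- data.frame(event_id = "mxe", inc_reads = 0, exc_reads = 480,
                    inc_positions = 146, exc_positions = 146)
  ds <- diff_splicing(as_psi_table(epi, "MXE"), as_psi_table(mes, "MXE"))
  expect_equal(ds$delta_psi, -1)
  expect_equal(ds$direction, "epithelial-inclusion")
})

test_that("swapping condition roles flips every delta sign", {
  sim <- simulate_event_counts(50, 300, psi_1 = runif(50, .2, .8),
                               psi_2 = runif(50, .2, .8), seed = 40)
  a <- as_psi_table(sim$counts_1); b <- as_psi_table(sim$counts_2)
  expect_equal(diff_splicing(a, b)$delta_psi,
               -diff_splicing(b, a)$delta_psi)
})

test_that("event filtering keeps inclusive thresholds and planted labels", {
  expect_equal(nrow(filter_events(diff_splicing(
    as_psi_table(data.frame(event_id = character(0), inc_reads = integer(0),
                            exc_reads = integer(0), inc_positions = integer(0),
                            exc_positions = integer(0))),
    as_psi_table(data.frame(event_id = character(0), inc_reads = integer(0),
                            exc_reads = integer(0), inc_positions = integer(0),
                            exc_positions = integer(0)))))), 0)
  rec <- data.frame(event_id = c("x", "y", "z"),
                    delta_psi = c(0.10, -0.0999, 0.5),
                    fdr = c(0.05, 0.01, 0.0500001))
  kept <- filter_events(rec, 0.1, 0.05)
  expect_equal(kept$event_id, "x")  # both thresholds inclusive

  set.seed(3)
  recs <- data.frame(event_id = sprintf("e%d", 1:1000),
                     delta_psi = runif(1000, -1, 1),
                     fdr = runif(1000))
  want <- recs$event_id[abs(recs$delta_psi) >= 0.2 & recs$fdr <= 0.1]
  expect_equal(filter_events(recs, 0.2, 0.1)$event_id, want)
})

test_that("gene-level fractions count tested and passing genes", {
  rec <- data.frame(event_id = c("e1", "e2", "e3"),
                    delta_psi = c(0.4, 0.01, 0.02), fdr = c(0.01, 0.9, 0.8))
  map <- c(e1 = "gA", e2 = "gA", e3 = "gB")
  expect_equal(gene_level_fraction(rec, map), 0.5)
  expect_equal(gene_level_fraction(rec[2:3, ], map), 0)
  expect_equal(gene_level_fraction(rec[1, , drop = FALSE], map), 1)
  expect_error(gene_level_fraction(rec, map[-1]), "e1")
})

test_that("benjamini-hochberg matches a textbook step-up and is order invariant", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  p <- runif(20)
  expect_equal(benjamini_hochberg(p), bh_stepup(p))
  o <- sample(20)
  expect_equal(benjamini_hochberg(p[o]), benjamini_hochberg(p)[o])
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})
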