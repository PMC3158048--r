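test_that("coherence handles identity, inversion and symmetry", {
  a <- stats::setNames(c(0.4, -0.2, 0.7, -0.5), paste0("e", 1:4))
  expect_equal(coherence(a, a)$fraction, 1)
  expect_equal(coherence(a, -a)$fraction, 0)
  b <- stats::setNames(c(0.1, 0.2, -0.3, -0.9), paste0("e", 1:4))
  expect_equal(coherence(a, b)$fraction, coherence(b, a)$fraction)
  expect_error(coherence(a, stats::setNames(1, "zz")), "shared")
  # zero changes are excluded from the comparison
  z <- a; z[1] <- 0
  expect_equal(coherence(a, z)$n_compared, 3)
})

test_that("coherence recovers planted sign-flip rates", {
  cd <- simulate_coherence_deltas(2000, 0.2, seed = 3)
  fr <- coherence(cd$a, cd$b)$fraction
  ci <- 2.576 * sqrt(0.8 * 0.2 / 2000)
  expect_lt(abs(fr - 0.8), ci + 1e-9)
})

test_that("noise-free opposite blocks cluster perfectly and label naming is irrelevant", {
  pp <- simulate_panel(n_class1 = 5, n_class2 = 5, n_events = 40,
                       effect_dpsi = 0.5, noise_sd = 0, seed = 2)
  cs <- cluster_samples(pp$panel, pp$labels)
  expect_equal(cs$misclassifications, 0)
  flipped <- ifelse(pp$labels == "class1", "B", "A")
  cs2 <- cluster_samples(pp$panel, flipped)
  expect_equal(cs2$misclassifications, cs$misclassifications)
})

test_that("degenerate clustering inputs raise informative errors", {
  m <- matrix(runif(30), nrow = 10,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  m2 <- m; m2[, 2] <- 0.5
  expect_error(cluster_samples(m2, c("a", "a", "b")), "s2")
  expect_error(cluster_samples(m[, 1:2], c("a", "b")), "3 samples")
  mna <- m; mna[1, ] <- NA; mna[2:10, 1] <- NA
  expect_error(cluster_samples(mna, c("a", "a", "b")), "missing")
})

test_that("planted two-class panels separate in almost every replicate", {
  ok <- vapply(1:20, function(s) {
    pp <- simulate_panel(12, 12, 300, effect_dpsi = 0.3, noise_sd = 0.1,
                         seed = 1000 + s)
    cluster_samples(pp$panel, pp$labels)$misclassifications == 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("randomized clustering p-values hit their bounds and reproduce", {
  pp <- simulate_panel(12, 12, 400, effect_dpsi = 0.4, noise_sd = 0.1,
                       affected_fraction = 0.05, seed = 6)
  fg <- pp$truth$event_id[pp$truth$affected]
  r1 <- randomized_cluster_pvalue(pp$panel, fg, pp$labels, n_perm = 199,
                                  seed = 9)
  r2 <- randomized_cluster_pvalue(pp$panel, fg, pp$labels, n_perm = 199,
                                  seed = 9)
  expect_identical(r1, r2)                       # bit-reproducible
  expect_gte(r1$p, 1 / 200)                      # add-one lower bound
  expect_error(randomized_cluster_pvalue(pp$panel, c(fg, "nope"), pp$labels),
               "rows")
  expect_error(randomized_cluster_pvalue(pp$panel, fg, pp$labels,
                                         n_perm = 10), "n_perm")
  # observed at the permutation maximum forces p = 1
  worst <- randomized_cluster_pvalue(pp$panel,
                                     sample(rownames(pp$panel), 50),
                                     rev(pp$labels), n_perm = 199, seed = 2)
  expect_lte(worst$p, 1)
})

test_that("reference normalization divides by the reference mean", {
  m <- matrix(c(1, 2, 4, 2, 4, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("e1", "e2"), c("r1", "s1", "s2")))
  nm <- normalize_to_reference(m, "r1")
  expect_equal(unname(nm["e1", ]), c(2, 4))
  expect_equal(unname(nm["e2", ]), c(2, 4))
  m0 <- m; m0[1, 1] <- 0
  expect_error(normalize_to_reference(m0, "r1"), "zero")
})

test_that("event correlation clustering separates planted factor groups", {
  set.seed(4)
  n_s <- 30
  factor_s <- rnorm(n_s)
  epi <- t(vapply(1:4, function(i) 0.5 + 0.3 * factor_s + rnorm(n_s, 0, 0.1),
                  numeric(n_s)))
  mes <- t(vapply(1:2, function(i) 0.5 - 0.3 * factor_s + rnorm(n_s, 0, 0.1),
                  numeric(n_s)))
  panel <- rbind(epi, mes)
  rownames(panel) <- c(paste0("epi", 1:4), paste0("mes", 1:2))
  ec <- event_correlation_cluster(panel, n_boot = 100, seed = 1)
  r <- ec$cor
  expect_true(all(r[1:4, 1:4] > 0))
  expect_true(all(r[5:6, 5:6] > 0))
  expect_true(all(r[1:4, 5:6] < 0))
  grp <- stats::cutree(ec$hclust, k = 2)
  expect_equal(length(unique(grp[1:4])), 1)
  expect_equal(length(unique(grp[5:6])), 1)
  expect_false(grp[1] == grp[5])
  # duplicated rows correlate exactly
  dup <- rbind(panel, dup1 = panel[1, ])
  ec2 <- event_correlation_cluster(dup, n_boot = 0, seed = 1)
  expect_equal(ec2$cor["epi1", "dup1"], 1)
  # constant rows are excluded with a notice
  cst <- rbind(panel, flat = rep(0.5, n_s))
  expect_message(ec3 <- event_correlation_cluster(cst, n_boot = 0, seed = 1),
                 "flat")
  expect_equal(ec3$excluded, "flat")
})

test_that("dendrograms export as parseable newick", {
  pp <- simulate_panel(6, 6, 30, seed = 3)
  cs <- cluster_samples(pp$panel, pp$labels)
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cs$hclust, f)
  tree <- ape::read.tree(f)
  expect_equal(sort(tree$tip.label), sort(colnames(pp$panel)))
})

test_that("panel TSV io round-trips with missing values", {
  pp <- simulate_panel(4, 4, 20, missing_rate = 0.1, seed = 12)
  f <- tempfile(fileext = ".tsv")
  write_panel_tsv(pp$panel, f)
  back <- read_panel_tsv(f)
  expect_equal(back, pp$panel, tolerance = 1e-12)
})
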