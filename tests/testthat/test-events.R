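test_that("a skipped exon yields the definition signatures", {
  tx <- se_toy()
  ev <- derive_events(tx)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SE")
  inc <- ev$inc_segments[[1]]
  exc <- ev$exc_segments[[1]]
  expect_setequal(
    sprintf("%s:%d-%d", inc$kind, inc$start, inc$end),
    c("exon_body:1101-1220", "junction:250-1101", "junction:1220-1371")
  )
  expect_equal(sprintf("%s:%d-%d", exc$kind, exc$start, exc$end),
               "junction:250-1371")
  expect_equal(c(ev$up_start, ev$up_end, ev$dn_start, ev$dn_end),
               c(101, 250, 1371, 1520))
})

test_that("mutually exclusive internal exons are detected once", {
  tx <- rbind(
    tx_df("g1", "t1", c(1, 301, 901), c(100, 400, 1000)),
    tx_df("g1", "t2", c(1, 601, 901), c(100, 700, 1000))
  )
  ev <- derive_events(tx)
  expect_equal(ev$type, "MXE")
  # iso1 tracks the genomically left exon
  expect_true(any(ev$inc_segments[[1]]$start == 301 &
                    ev$inc_segments[[1]]$end == 400))
  expect_true(any(ev$exc_segments[[1]]$start == 601 &
                    ev$exc_segments[[1]]$end == 700))
})

test_that("remaining event types classify per the documented rules", {
  # retained intron: one transcript's exon spans the other's two exons
  ri <- rbind(tx_df("g", "t1", 1, 700),
              tx_df("g", "t2", c(1, 501), c(200, 700)))
  expect_equal(derive_events(ri)$type, "RI")

  # alternative 5' splice site on the plus strand (shared start, longer end,
  # both spliced to one downstream exon)
  a5 <- rbind(tx_df("g", "t1", c(1, 501), c(260, 700)),
              tx_df("g", "t2", c(1, 501), c(200, 700)))
  expect_equal(derive_events(a5)$type, "A5SS")
  # the same geometry on the minus strand is an alternative 3' splice site
  a5m <- a5; a5m$strand <- "-"
  expect_equal(derive_events(a5m)$type, "A3SS")

  a3 <- rbind(tx_df("g", "t1", c(1, 441, 901), c(200, 700, 1000)),
              tx_df("g", "t2", c(1, 501, 901), c(200, 700, 1000)))
  expect_equal(derive_events(a3)$type, "A3SS")

  # alternative first exons: non-overlapping starts spliced to a shared
  # acceptor
  afe <- rbind(tx_df("g", "t1", c(1, 901), c(100, 1000)),
               tx_df("g", "t2", c(301, 901), c(400, 1000)))
  expect_equal(derive_events(afe)$type, "AFE")
  afem <- afe; afem$strand <- "-"
  expect_equal(derive_events(afem)$type, "ALE")

  ale <- rbind(tx_df("g", "t1", c(1, 301), c(100, 400)),
               tx_df("g", "t2", c(1, 601), c(100, 700)))
  expect_equal(derive_events(ale)$type, "ALE")

  # tandem 3' UTR: terminal exons share the acceptor, differ in 3' end
  tu <- rbind(tx_df("g", "t1", c(1, 301), c(100, 800)),
              tx_df("g", "t2", c(1, 301), c(100, 500)))
  evtu <- derive_events(tu)
  expect_equal(evtu$type, "TandemUTR")
  expect_equal(evtu$inc_segments[[1]]$kind, "utr_extension")
  expect_equal(c(evtu$alt_start, evtu$alt_end), c(501, 800))
})

test_that("duplicate events from multiple transcript pairs merge", {
  tx <- rbind(se_toy(),
              tx_df("g1", "g1.t3", c(101, 1101, 1371), c(250, 1220, 1600)))
  # t3 includes the same alternative exon with a longer terminal exon; the
  # SE signature relative to t2 is identical and must merge
  ev <- derive_events(tx)
  expect_equal(sum(ev$type == "SE"), 1)
})

test_that("constitutive exons equal the per-base intersection oracle", {
  single <- tx_df("g", "t1", c(1, 501), c(100, 600))
  ce <- constitutive_exons(single)
  expect_equal(ce[, c("start", "end")],
               data.frame(start = c(1L, 501L), end = c(100L, 600L)))

  ce_se <- constitutive_exons(se_toy())
  expect_equal(ce_se$start, c(101L, 1371L))
  expect_equal(ce_se$end, c(250L, 1520L))

  # random multi-transcript gene against a per-base logical-vector oracle
  set.seed(42)
  span <- 3000L
  txs <- do.call(rbind, lapply(1:5, function(i) {
    k <- sample(2:4, 1)
    s <- sort(sample(seq_len(span - 100), k))
    e <- pmin(s + sample(30:120, k, replace = TRUE), span)
    keep <- c(TRUE, s[-1] > head(e, -1) + 1)  # drop overlapping draws
    tx_df("g", paste0("t", i), s[keep], e[keep])
  }))
  ce <- constitutive_exons(txs)
  cov <- rep(TRUE, span)
  for (t in split(txs, txs$transcript_id)) {
    m <- rep(FALSE, span)
    for (j in seq_len(nrow(t))) m[t$start[j]:t$end[j]] <- TRUE
    cov <- cov & m
  }
  oracle <- rep(FALSE, span)
  if (nrow(ce) > 0) {
    for (j in seq_len(nrow(ce))) oracle[ce$start[j]:ce$end[j]] <- TRUE
  }
  expect_identical(oracle, cov)
})

test_that("catalog invariants hold on simulator output", {
  sim <- simulate_annotation(
    20, c(SE = 2, RI = 2, MXE = 2, A5SS = 2, A3SS = 2, AFE = 2, ALE = 2,
          TandemUTR = 2), seed = 31)
  ev <- derive_events(sim$transcripts)
  # planted counts recovered exactly per type
  expect_equal(as.vector(table(factor(ev$type, levels = sort(unique(ev$type))))),
               as.vector(table(sim$truth$events$type)))
  gene_span <- sim$truth$genes
  for (i in seq_len(nrow(ev))) {
    inc <- ev$inc_segments[[i]]; exc <- ev$exc_segments[[i]]
    # disjoint signatures
    expect_equal(nrow(merge(inc, exc)), 0)
    g <- gene_span[gene_span$gene_id == ev$gene_id[i], ]
    expect_true(all(c(inc$start, exc$start) >= g$start))
    expect_true(all(c(inc$end, exc$end) <= g$end))
  }
  # idempotence: the minimal inducing pair re-derives each event
  for (gid in unique(ev$gene_id)) {
    sub <- derive_events(
      sim$transcripts[sim$transcripts$gene_id == gid, , drop = FALSE])
    expect_equal(sub$event_id, ev$event_id[ev$gene_id == gid])
  }
})

test_that("annotation io sorts, round-trips, and reports malformed input", {
  tx <- se_toy()
  shuffled <- tx[c(3, 1, 5, 2, 4), ]
  f <- tempfile(fileext = ".gtf")
  write_gtf(shuffled, f)
  back <- load_annotation(f)
  expect_true(all(diff(back$start[back$transcript_id == "g1.t1"]) > 0))
  expect_equal(back[order(back$transcript_id, back$start), ],
               tx[order(tx$transcript_id, tx$start), ],
               ignore_attr = TRUE)

  bad <- tempfile(fileext = ".gtf")
  writeLines(c(readLines(f), "chr1\tonly\tthree"), bad)
  expect_error(load_annotation(bad), "line 6")

  empty_tx <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tx\ttranscript\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t.empty\";",
    readLines(f)
  ), empty_tx)
  expect_warning(load_annotation(empty_tx), "zero exons")
})

test_that("event catalog TSV and GFF3 writers round-trip/are well-formed", {
  sim <- simulate_annotation(4, c(SE = 2, MXE = 2), seed = 5)
  ev <- derive_events(sim$transcripts)
  tf <- tempfile(fileext = ".tsv")
  write_event_catalog(ev, tf)
  back <- read_event_catalog(tf)
  expect_equal(back$event_id, ev$event_id)
  expect_equal(back$inc_segments, ev$inc_segments, ignore_attr = TRUE)
  gf <- tempfile(fileext = ".gff3")
  write_events_gff3(ev, gf)
  reimported <- rtracklayer::import(gf, format = "gff3")
  expect_equal(sum(reimported$type == "region"), nrow(ev))
})
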