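test_that("flank extraction returns the four 250-nt regions at the expected coordinates", {
  tx <- se_toy()           # introns 251-1100 (850 nt) and 1221-1370 (150 nt)
  ev <- derive_events(tx)
  set.seed(2)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  fl <- extract_flanks(ev, genome, width = 250)
  sub <- function(a, b) gsub("T", "U", substr(chr, a, b))
  up <- fl[fl$region == "upstream_intron", ]
  expect_equal(up$seq[up$element == "I5"], sub(251, 500))
  expect_equal(up$seq[up$element == "I3"], sub(851, 1100))
  # 150-nt downstream intron is split 75/75 at the midpoint
  dn <- fl[fl$region == "downstream_intron", ]
  expect_equal(dn$seq[dn$element == "I5"], sub(1221, 1295))
  expect_equal(dn$seq[dn$element == "I3"], sub(1296, 1370))
  expect_error(extract_flanks(ev, Biostrings::DNAStringSet(c(chrX = "ACGT"))),
               "absent")
})

test_that("minus-strand flanks are the reverse complement of the mirrored extraction", {
  tx_plus <- se_toy()
  tx_minus <- se_toy(strand = "-")
  ev_p <- derive_events(tx_plus)
  ev_m <- derive_events(tx_minus)
  set.seed(5)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  fl_p <- extract_flanks(ev_p, genome, width = 100)
  fl_m <- extract_flanks(ev_m, genome, width = 100)
  revcomp_rna <- function(s) {
    chartr("ACGU", "UGCA",
           vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                  character(1)))
  }
  # genomic-left intron: upstream on +, downstream on -; donor flank on +
  # mirrors to acceptor flank on -
  p <- fl_p[fl_p$region == "upstream_intron" & fl_p$element == "I5", "seq"]
  m <- fl_m[fl_m$region == "downstream_intron" & fl_m$element == "I3", "seq"]
  expect_equal(m, revcomp_rna(p))
})

test_that("pentamer windows and depletion semantics are exact", {
  fg <- data.frame(event_id = "f1", region = "upstream_intron",
                   element = "I5", seq = "ACGUACGUAC")        # 6 windows
  bg <- data.frame(event_id = "b1", region = "upstream_intron",
                   element = "I5", seq = "GGGGGGGGGGGGGGN")   # N voids a window
  en <- pentamer_enrichment(fg, bg)
  cls <- en[en$region == "upstream_intron" & en$element == "I5", ]
  expect_equal(unique(cls$fg_windows), 6)
  expect_equal(unique(cls$bg_windows), 10)  # 15-nt seq, N kills 5 of 11
  # a pentamer absent from the foreground can never look enriched
  gg <- cls[cls$pentamer == "GGGGG", ]
  expect_equal(gg$fg_count, 0)
  expect_equal(gg$p_hyper, 1)
  expect_error(pentamer_enrichment(fg, fg), "share")
})

test_that("hypergeometric enrichment p equals brute-force enumeration", {
  set.seed(9)
  mk <- function(prefix, n) {
    data.frame(event_id = sprintf("%s%d", prefix, seq_len(n)),
               region = "downstream_intron", element = "I5",
               seq = vapply(seq_len(n), function(i) {
                 paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
               }, character(1)))
  }
  fg <- mk("f", 4); bg <- mk("b", 16)
  en <- pentamer_enrichment(fg, bg)
  cls <- en[en$region == "downstream_intron" & en$element == "I5" &
              en$fg_count > 0, ]
  for (i in seq_len(min(nrow(cls), 10))) {
    r <- cls[i, ]
    expect_equal(
      r$p_hyper,
      hyper_brute(r$fg_count, r$fg_count + r$bg_count,
                  r$fg_windows + r$bg_windows, r$fg_windows),
      tolerance = 1e-10
    )
  }
})

test_that("a planted motif dominates its region class", {
  fs <- simulate_flank_sets(100, 300, fg_rate = 0.5, bg_rate = 0.05, seed = 77)
  en <- pentamer_enrichment(fs$fg, fs$bg)
  cls <- en[en$region == "downstream_intron" & en$element == "I5", ]
  top <- cls[order(cls$fdr, cls$p_hyper), ][1:2, ]
  expect_setequal(top$pentamer, c("UGCAU", "GCAUG"))
  expect_true(all(top$family == "RBFOX"))
  expect_true(all(top$fdr < 0.05))
  # other region classes saw no planting and stay quiet at the top
  other <- en[!(en$region == "downstream_intron" & en$element == "I5"), ]
  expect_gt(min(other$fdr), 0.05)
})

test_that("null foreground draws show no p-value inflation", {
  fs <- simulate_flank_sets(60, 240, fg_rate = 0.05, bg_rate = 0.05,
                            seed = 123)
  en <- pentamer_enrichment(fs$fg, fs$bg)
  expect_lte(mean(en$p_hyper <= 0.05), 0.065)
  expect_lte(mean(en$p_hyper <= 0.2), 0.24)
})

test_that("motif families annotate with documented precedence", {
  expect_equal(annotate_family("GCAUG"), "RBFOX")
  expect_equal(annotate_family("UGCAU"), "RBFOX")
  expect_equal(annotate_family("GGGGA"), "hnRNP F/H")
  expect_equal(annotate_family("UGCUA"), "MBNL")
  expect_equal(annotate_family("UCUCU"), "PTB")
  expect_equal(annotate_family("ACACA"), "hnRNP L")
  expect_equal(annotate_family("AUGGA"), "ESRP")
  expect_equal(annotate_family("AAAAA"), "Other")
  expect_error(annotate_family("GCATG"), "RNA")
})

test_that("overlap enrichment matches the exact tail and handles degenerate sets", {
  u <- sprintf("e%d", 1:100)
  expect_equal(overlap_enrichment(u[1:30], u, u)$p, 1)  # flagged = universe
  p_disjoint <- overlap_enrichment(u[1:30], u[91:94], u)
  expect_equal(p_disjoint$overlap, 0)
  expect_gt(p_disjoint$p, 0.5)
  r <- overlap_enrichment(u[1:30], c(u[1:12], u[93:100]), u)
  expect_equal(r$overlap, 12)
  expect_equal(r$p, hyper_brute(12, 20, 100, 30), tolerance = 1e-12)
  expect_error(overlap_enrichment(c(u[1], "zzz"), u[1:5], u), "universe")
})

test_that("CLIP cluster overlap flags events across their regulatory span", {
  tx <- se_toy()
  ev <- derive_events(tx)
  hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1250, 1260))
  miss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
  expect_equal(clip_flagged_events(ev, hit), ev$event_id)
  expect_equal(length(clip_flagged_events(ev, miss)), 0)
  expect_equal(clip_flagged_events(ev, miss, window = 200), ev$event_id)
})
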