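EVENT_TYPES <- c("SE", "RI", "MXE", "A5SS", "A3SS", "AFE", "ALE", "TandemUTR")

# Precedence used to resolve a transcript pair whose exon geometry matches more
# than one event pattern over the same alternative region (lower wins).
EVENT_PRECEDENCE <- c(RI = 1, MXE = 2, SE = 3, A5SS = 4, A3SS = 4,
                      AFE = 5, ALE = 5, TandemUTR = 6)

segment_df <- function(kind, start, end) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

junction_seg <- function(donor, acceptor) {
  stopifnot(all(donor < acceptor))
  segment_df("junction", donor, acceptor)
}

seg_signature <- function(segs) {
  segs <- segs[order(segs$start, segs$end, segs$kind), , drop = FALSE]
  paste(sprintf("%s:%d-%d", segs$kind, segs$start, segs$end), collapse = ";")
}

junctions_of <- function(tx) {
  n <- nrow(tx)
  if (n < 2) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  data.frame(donor = tx$end[-n], acceptor = tx$start[-1])
}

overlaps_any <- function(start, end, tx) {
  any(tx$start <= end & tx$end >= start)
}

# --- per-pair detectors -----------------------------------------------------
# Each returns a list of candidates: list(type, inc, exc, alt = c(lo, hi),
# flanks = c(up_start, up_end, dn_start, dn_end) for SE, NA otherwise).

cand <- function(type, inc, exc, alt, flanks = rep(NA_integer_, 4)) {
  list(type = type, inc = inc, exc = exc,
       alt = as.integer(alt), flanks = as.integer(flanks))
}

detect_ri_dir <- function(t_ret, t_spl) {
  res <- list()
  n <- nrow(t_spl)
  if (n < 2) return(res)
  for (q in seq_len(n - 1)) {
    B <- t_spl[q, ]; C <- t_spl[q + 1, ]
    if (any(t_ret$start == B$start & t_ret$end == C$end)) {
      intr <- c(B$end + 1L, C$start - 1L)
      res[[length(res) + 1L]] <- cand(
        "RI",
        inc = segment_df("exon_body", intr[1], intr[2]),
        exc = junction_seg(B$end, C$start),
        alt = intr
      )
    }
  }
  res
}

detect_se_dir <- function(t_inc, t_exc) {
  res <- list()
  n <- nrow(t_inc)
  if (n < 3) return(res)
  jx <- junctions_of(t_exc)
  for (k in 2:(n - 1)) {
    up <- t_inc[k - 1, ]; E <- t_inc[k, ]; dn <- t_inc[k + 1, ]
    skip <- any(jx$donor == up$end & jx$acceptor == dn$start)
    if (skip && !overlaps_any(E$start, E$end, t_exc)) {
      res[[length(res) + 1L]] <- cand(
        "SE",
        inc = rbind(segment_df("exon_body", E$start, E$end),
                    junction_seg(up$end, E$start),
                    junction_seg(E$end, dn$start)),
        exc = junction_seg(up$end, dn$start),
        alt = c(E$start, E$end),
        flanks = c(up$start, up$end, dn$start, dn$end)
      )
    }
  }
  res
}

detect_mxe <- function(tA, tB) {
  res <- list()
  nA <- nrow(tA); nB <- nrow(tB)
  if (nA < 3 || nB < 3) return(res)
  for (a in 2:(nA - 1)) {
    for (b in 2:(nB - 1)) {
      X <- tA[a, ]; Y <- tB[b, ]
      if (X$start <= Y$end && X$end >= Y$start) next  # overlapping or equal
      if (tA$end[a - 1] != tB$end[b - 1]) next
      if (tA$start[a + 1] != tB$start[b + 1]) next
      if (overlaps_any(X$start, X$end, tB) || overlaps_any(Y$start, Y$end, tA)) next
      up_end <- tA$end[a - 1]; dn_start <- tA$start[a + 1]
      # canonical orientation: iso1 tracks the genomically left exon
      if (X$start > Y$start) { tmp <- X; X <- Y; Y <- tmp }
      res[[length(res) + 1L]] <- cand(
        "MXE",
        inc = rbind(segment_df("exon_body", X$start, X$end),
                    junction_seg(up_end, X$start),
                    junction_seg(X$end, dn_start)),
        exc = rbind(segment_df("exon_body", Y$start, Y$end),
                    junction_seg(up_end, Y$start),
                    junction_seg(Y$end, dn_start)),
        alt = c(min(X$start, Y$start), max(X$end, Y$end))
      )
    }
  }
  res
}

detect_altss <- function(tA, tB, strand) {
  res <- list()
  nA <- nrow(tA); nB <- nrow(tB)
  for (a in seq_len(nA)) {
    for (b in seq_len(nB)) {
      E1 <- tA[a, ]; E2 <- tB[b, ]
      if (E1$start > E2$end || E1$end < E2$start) next       # disjoint
      if (E1$start == E2$start && E1$end == E2$end) next     # identical
      if (E1$start == E2$start && E1$end != E2$end) {
        # shared left boundary, alternative right boundary; needs a shared
        # splice target to the right of both forms
        if (a == nA || b == nB) next
        S1 <- tA$start[a + 1]; S2 <- tB$start[b + 1]
        if (S1 != S2) next
        long_end <- max(E1$end, E2$end); short_end <- min(E1$end, E2$end)
        if (long_end >= S1) next
        type <- if (strand == "+") "A5SS" else "A3SS"
        res[[length(res) + 1L]] <- cand(
          type,
          inc = rbind(segment_df("exon_body", short_end + 1L, long_end),
                      junction_seg(long_end, S1)),
          exc = junction_seg(short_end, S1),
          alt = c(short_end + 1L, long_end)
        )
      } else if (E1$end == E2$end && E1$start != E2$start) {
        if (a == 1 || b == 1) next
        P1 <- tA$end[a - 1]; P2 <- tB$end[b - 1]
        if (P1 != P2) next
        long_start <- min(E1$start, E2$start)
        short_start <- max(E1$start, E2$start)
        if (long_start <= P1) next
        type <- if (strand == "+") "A3SS" else "A5SS"
        res[[length(res) + 1L]] <- cand(
          type,
          inc = rbind(segment_df("exon_body", long_start, short_start - 1L),
                      junction_seg(P1, long_start)),
          exc = junction_seg(P1, short_start),
          alt = c(long_start, short_start - 1L)
        )
      }
    }
  }
  res
}

detect_terminal <- function(tA, tB, strand) {
  res <- list()
  nA <- nrow(tA); nB <- nrow(tB)
  # genomically left terminal exons spliced to a shared acceptor
  if (nA >= 2 && nB >= 2) {
    F1 <- tA[1, ]; F2 <- tB[1, ]
    if (tA$start[2] == tB$start[2] &&
        (F1$start > F2$end || F1$end < F2$start)) {
      S <- tA$start[2]
      type <- if (strand == "+") "AFE" else "ALE"
      # iso1 = splice-site-proximal terminal exon
      if (F1$start < F2$start) { tmp <- F1; F1 <- F2; F2 <- tmp }
      res[[length(res) + 1L]] <- cand(
        type,
        inc = rbind(segment_df("exon_body", F1$start, F1$end),
                    junction_seg(F1$end, S)),
        exc = rbind(segment_df("exon_body", F2$start, F2$end),
                    junction_seg(F2$end, S)),
        alt = c(min(F1$start, F2$start), max(F1$end, F2$end))
      )
    }
    L1 <- tA[nA, ]; L2 <- tB[nB, ]
    if (tA$end[nA - 1] == tB$end[nB - 1] &&
        (L1$start > L2$end || L1$end < L2$start)) {
      P <- tA$end[nA - 1]
      type <- if (strand == "+") "ALE" else "AFE"
      if (L1$start > L2$start) { tmp <- L1; L1 <- L2; L2 <- tmp }
      res[[length(res) + 1L]] <- cand(
        type,
        inc = rbind(segment_df("exon_body", L1$start, L1$end),
                    junction_seg(P, L1$start)),
        exc = rbind(segment_df("exon_body", L2$start, L2$end),
                    junction_seg(P, L2$start)),
        alt = c(min(L1$start, L2$start), max(L1$end, L2$end))
      )
    }
  }
  res
}

detect_tandem <- function(tA, tB, strand) {
  res <- list()
  nA <- nrow(tA); nB <- nrow(tB)
  if (strand == "+") {
    U1 <- tA[nA, ]; U2 <- tB[nB, ]
    same_entry <- (nA < 2 || nB < 2) || (tA$end[nA - 1] == tB$end[nB - 1])
    if (U1$start == U2$start && U1$end != U2$end && same_entry) {
      short_end <- min(U1$end, U2$end); long_end <- max(U1$end, U2$end)
      res[[length(res) + 1L]] <- cand(
        "TandemUTR",
        inc = segment_df("utr_extension", short_end + 1L, long_end),
        exc = segment_df("exon_body", U1$start, short_end),
        alt = c(short_end + 1L, long_end)
      )
    }
  } else {
    U1 <- tA[1, ]; U2 <- tB[1, ]
    same_entry <- (nA < 2 || nB < 2) || (tA$start[2] == tB$start[2])
    if (U1$end == U2$end && U1$start != U2$start && same_entry) {
      long_start <- min(U1$start, U2$start); short_start <- max(U1$start, U2$start)
      res[[length(res) + 1L]] <- cand(
        "TandemUTR",
        inc = segment_df("utr_extension", long_start, short_start - 1L),
        exc = segment_df("exon_body", short_start, U1$end),
        alt = c(long_start, short_start - 1L)
      )
    }
  }
  res
}

pair_events <- function(tA, tB, strand) {
  cands <- c(
    detect_ri_dir(tA, tB), detect_ri_dir(tB, tA),
    detect_mxe(tA, tB),
    detect_se_dir(tA, tB), detect_se_dir(tB, tA),
    detect_altss(tA, tB, strand),
    detect_terminal(tA, tB, strand),
    detect_tandem(tA, tB, strand)
  )
  if (length(cands) < 2) return(cands)
  # resolve same-locus multi-pattern matches by precedence; candidates are
  # already ordered RI > MXE > SE > A5SS/A3SS > AFE/ALE > TandemUTR
  keep <- logical(length(cands))
  claimed <- matrix(integer(0), ncol = 2)
  for (i in seq_along(cands)) {
    alt <- cands[[i]]$alt
    clash <- nrow(claimed) > 0 &&
      any(claimed[, 1] <= alt[2] & claimed[, 2] >= alt[1])
    if (!clash) {
      keep[i] <- TRUE
      claimed <- rbind(claimed, alt)
    }
  }
  cands[keep]
}

#' Derive alternative-isoform events from transcript models
#'
#' Compares every pair of transcripts within each gene and emits the eight
#' classical alternative-isoform event types: skipped exons (SE), retained
#' introns (RI), mutually exclusive exons (MXE), alternative 5'/3' splice sites
#' (A5SS/A3SS), alternative first/last exons (AFE/ALE) and tandem 3' UTRs.
#' Each event carries two disjoint isoform signatures made of exon-body,
#' junction and UTR-extension segments: the inclusion signature holds the
#' segments unique to the included/long form (for an SE, the exon body plus its
#' two flanking junctions) and the exclusion signature the segments unique to
#' the other form (for an SE, the skipping junction).
#'
#' When one pair of transcripts matches several patterns over the same
#' alternative region, the precedence RI > MXE > SE > A5SS/A3SS > AFE/ALE >
#' TandemUTR decides; alternative terminal exons that overlap and share a
#' splice site are therefore classified as A5SS/A3SS, and AFE/ALE require
#' non-overlapping terminal exons. Events recovered from multiple transcript
#' pairs are merged on (type, chrom, strand, segment coordinates).
#'
#' @param transcripts A data frame of exons as returned by
#'   [load_annotation()]: columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @return A `splice_events` data frame with one row per event: `event_id`,
#'   `type`, `gene_id`, `chrom`, `strand`, the alternative-region bounds
#'   `alt_start`/`alt_end`, SE flanking-exon coordinates (`up_start`,
#'   `up_end`, `dn_start`, `dn_end`; `NA` for other types) and list columns
#'   `inc_segments` / `exc_segments` of segment data frames
#'   (`kind`, `start`, `end`; junctions store donor in `start` and acceptor in
#'   `end`).
#' @export
derive_events <- function(transcripts) {
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(transcripts))) {
    stop_arg("transcripts must have columns ", paste(req, collapse = ", "))
  }
  rows <- list()
  seen <- character(0)
  for (g in split(transcripts, transcripts$gene_id)) {
    txs <- lapply(split(g, g$transcript_id),
                  function(t) t[order(t$start), , drop = FALSE])
    if (length(txs) < 2) next
    strand <- g$strand[1]
    chrom <- g$chrom[1]
    for (i in seq_len(length(txs) - 1)) {
      for (j in seq(i + 1, length(txs))) {
        for (cd in pair_events(txs[[i]], txs[[j]], strand)) {
          key <- paste(cd$type, chrom, strand,
                       seg_signature(cd$inc), seg_signature(cd$exc), sep = "|")
          if (key %in% seen) next
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- data.frame(
            type = cd$type, gene_id = g$gene_id[1], chrom = chrom,
            strand = strand, alt_start = cd$alt[1], alt_end = cd$alt[2],
            up_start = cd$flanks[1], up_end = cd$flanks[2],
            dn_start = cd$flanks[3], dn_end = cd$flanks[4],
            inc_segments = I(list(cd$inc)), exc_segments = I(list(cd$exc)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    ev <- data.frame(event_id = character(0), type = character(0),
                     gene_id = character(0), chrom = character(0),
                     strand = character(0), alt_start = integer(0),
                     alt_end = integer(0), up_start = integer(0),
                     up_end = integer(0), dn_start = integer(0),
                     dn_end = integer(0),
                     inc_segments = I(list()), exc_segments = I(list()),
                     stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$chrom, ev$alt_start, ev$type), , drop = FALSE]
    id <- sprintf("%s:%s:%s:%d-%d", ev$type, ev$chrom, ev$strand,
                  ev$alt_start, ev$alt_end)
    if (anyDuplicated(id)) id <- make.unique(id, sep = "#")
    ev <- cbind(event_id = id, ev, stringsAsFactors = FALSE)
    rownames(ev) <- NULL
  }
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Constitutive exonic intervals of a gene
#'
#' Returns the maximal genomic intervals covered by every transcript of each
#' gene (per-base intersection of the transcript exon footprints, merged into
#' maximal runs). These are the regions whose read counts are used for
#' gene-level expression estimates.
#'
#' @param transcripts Exon data frame as for [derive_events()]; may contain
#'   one or many genes.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, one row per constitutive interval.
#' @export
constitutive_exons <- function(transcripts) {
  out <- lapply(split(transcripts, transcripts$gene_id), function(g) {
    if (nrow(g) == 0) return(NULL)
    per_tx <- lapply(split(g, g$transcript_id), function(t) {
      IRanges::reduce(IRanges::IRanges(t$start, t$end))
    })
    common <- Reduce(IRanges::intersect, per_tx)
    if (length(common) == 0) {
      return(NULL)
    }
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1],
               start = IRanges::start(common), end = IRanges::end(common),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Flatten event segments into one table
#'
#' @param events A `splice_events` data frame.
#' @return Data frame with one row per segment: `event` (row index of the
#'   event), `event_id`, `side` (`inc`/`exc`), `kind`, `start`, `end`,
#'   `chrom`.
#' @export
event_segment_table <- function(events) {
  n <- nrow(events)
  if (n == 0) {
    return(data.frame(event = integer(0), event_id = character(0),
                      side = character(0), kind = character(0),
                      start = integer(0), end = integer(0),
                      chrom = character(0), stringsAsFactors = FALSE))
  }
  grab <- function(side_col, side) {
    segs <- events[[side_col]]
    nseg <- vapply(segs, nrow, integer(1))
    data.frame(
      event = rep(seq_len(n), nseg),
      event_id = rep(events$event_id, nseg),
      side = side,
      do.call(rbind, segs),
      chrom = rep(events$chrom, nseg),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(grab("inc_segments", "inc"), grab("exc_segments", "exc"))
  rownames(out) <- NULL
  out
}
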