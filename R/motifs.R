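FLANK_REGIONS <- c("upstream_intron", "downstream_intron")
FLANK_ELEMENTS <- c("I5", "I3")

#' Extract flanking intronic regions of skipped exons
#'
#' For each SE event, returns the four intronic regions adjacent to the splice
#' sites of the two introns flanking the alternative exon: the first
#' `width` nt of each intron (I5, abutting the donor) and the last `width` nt
#' (I3, abutting the acceptor). `upstream`/`downstream` and I5/I3 are in
#' transcript orientation, so minus-strand events are mirrored and
#' reverse-complemented. When an intron is shorter than `2 * width` the two
#' regions are truncated at the intron midpoint so that they never overlap
#' (the acceptor side receives the middle base of an odd-length intron).
#' Sequences are reported as RNA (T as U).
#'
#' @param events A `splice_events` data frame; only SE rows are used.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param width Maximum region width in nt (default 250).
#' @return Data frame with columns `event_id`, `region`
#'   (`upstream_intron`/`downstream_intron`), `element` (`I5`/`I3`), `seq`
#'   (RNA character).
#' @export
extract_flanks <- function(events, genome, width = 250L) {
  se <- events[events$type == "SE", , drop = FALSE]
  if (nrow(se) == 0) {
    return(data.frame(event_id = character(0), region = character(0),
                      element = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  missing_chr <- setdiff(unique(se$chrom), names(genome))
  if (length(missing_chr) > 0) {
    stop_arg("chromosome(s) absent from genome: ",
             paste(missing_chr, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(se))) {
    e <- se[i, ]
    left_intron <- c(e$up_end + 1L, e$alt_start - 1L)    # genomic left
    right_intron <- c(e$alt_end + 1L, e$dn_start - 1L)   # genomic right
    for (side in c("left", "right")) {
      intr <- if (side == "left") left_intron else right_intron
      L <- intr[2] - intr[1] + 1L
      w5 <- if (L >= 2L * width) width else L %/% 2L
      w3 <- if (L >= 2L * width) width else L - w5
      # genomic-left piece and genomic-right piece of this intron
      gl <- c(intr[1], intr[1] + (if (e$strand == "+") w5 else w3) - 1L)
      gr <- c(intr[2] - (if (e$strand == "+") w3 else w5) + 1L, intr[2])
      if (e$strand == "+") {
        region <- if (side == "left") "upstream_intron" else "downstream_intron"
        pieces <- list(I5 = gl, I3 = gr)
      } else {
        region <- if (side == "left") "downstream_intron" else "upstream_intron"
        pieces <- list(I5 = gr, I3 = gl)
      }
      for (el in names(pieces)) {
        p <- pieces[[el]]
        if (p[2] < p[1]) next
        s <- Biostrings::subseq(genome[[e$chrom]], p[1], p[2])
        if (e$strand == "-") s <- Biostrings::reverseComplement(s)
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = e$event_id, region = region, element = el,
          seq = gsub("T", "U", as.character(s)), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

count_pentamers <- function(seqs) {
  if (length(seqs) == 0) {
    k <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString("AAAAA"), 5)
    return(list(counts = 0 * k, windows = 0))
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(seqs), width = 5
  )
  # rowSums count only unambiguous windows, implementing the rule that
  # N-containing windows are skipped
  list(counts = colSums(m), windows = sum(rowSums(m)))
}

#' Pentamer enrichment in flanking regions
#'
#' Counts all overlapping 5-mers (step 1) in the foreground and background
#' flank sets, separately per (region, element) class, and scores each
#' pentamer with an upper-tail hypergeometric test: the population is the
#' pooled fg+bg windows, the successes are the pooled occurrences of the
#' pentamer, the draws are the foreground windows, and the observation is the
#' foreground occurrence count. FDR is Benjamini-Hochberg within each region
#' class. Windows containing ambiguous bases are skipped on both sides.
#'
#' @param fg,bg Flank tables as produced by [extract_flanks()]; the
#'   foreground and background event sets must be disjoint.
#' @param families Motif family table for [annotate_family()]; `NULL` for the
#'   packaged default.
#' @return Data frame with one row per (region, element, pentamer):
#'   `region`, `element`, `pentamer`, `fg_count`, `fg_windows`, `fg_rate`,
#'   `bg_count`, `bg_windows`, `bg_rate`, `expected_fg`, `p_hyper`, `fdr`,
#'   `family`.
#' @export
pentamer_enrichment <- function(fg, bg, families = NULL) {
  if (nrow(fg) == 0 || nrow(bg) == 0) stop_arg("fg and bg must be non-empty")
  shared <- intersect(unique(fg$event_id), unique(bg$event_id))
  if (length(shared) > 0) {
    stop_arg("foreground and background share event(s): ",
             paste(utils::head(shared, 3), collapse = ", "))
  }
  out <- list()
  for (region in FLANK_REGIONS) {
    rows <- list()
    for (element in FLANK_ELEMENTS) {
      f <- count_pentamers(fg$seq[fg$region == region & fg$element == element])
      b <- count_pentamers(bg$seq[bg$region == region & bg$element == element])
      N <- f$windows + b$windows
      K <- f$counts + b$counts
      p <- stats::phyper(f$counts - 1, K, N - K, f$windows, lower.tail = FALSE)
      rows[[element]] <- data.frame(
        region = region, element = element, pentamer = names(f$counts),
        fg_count = as.integer(f$counts), fg_windows = f$windows,
        fg_rate = f$counts / max(f$windows, 1),
        bg_count = as.integer(b$counts), bg_windows = b$windows,
        bg_rate = b$counts / max(b$windows, 1),
        expected_fg = f$windows * b$counts / max(b$windows, 1),
        p_hyper = pmin(pmax(p, .Machine$double.xmin), 1),
        stringsAsFactors = FALSE
      )
    }
    block <- do.call(rbind, rows)
    block$fdr <- benjamini_hochberg(block$p_hyper)
    out[[region]] <- block
  }
  res <- do.call(rbind, out)
  res$family <- annotate_family(res$pentamer, families)
  rownames(res) <- NULL
  res
}

load_family_table <- function() {
  utils::read.table(
    system.file("extdata", "motif_families.tsv", package = "psikit"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = ""
  )
}

#' Assign a pentamer to a splicing-factor motif family
#'
#' Matches RNA pentamers against a versioned pattern table of known
#' splicing-factor binding motifs (RBFOX GCAUG-core, hnRNP F/H G-runs, MBNL
#' YGCY, CELF UG-rich, PTB CU-rich, hnRNP L CA-rich, ESRP UGG/GU-rich); the
#' first matching row in table order wins, unmatched pentamers are `"Other"`.
#' The table ships as data (`extdata/motif_families.tsv`) so users can extend
#' or reorder it.
#'
#' @param pentamer Character vector of 5-nt RNA words over A, C, G, U.
#' @param families Optional custom family table with columns `family` and
#'   `pattern` (regular expressions).
#' @return Character vector of family labels.
#' @export
annotate_family <- function(pentamer, families = NULL) {
  if (any(grepl("[^ACGU]", pentamer))) {
    stop_arg("pentamers must be RNA words over A, C, G, U")
  }
  fam <- families %||% load_family_table()
  out <- rep("Other", length(pentamer))
  open <- rep(TRUE, length(pentamer))
  for (i in seq_len(nrow(fam))) {
    hit <- open & grepl(fam$pattern[i], pentamer)
    out[hit] <- fam$family[i]
    open <- open & !hit
  }
  out
}

#' Overlap enrichment of an event set with flagged events
#'
#' Upper-tail hypergeometric p-value for the size of the intersection between
#' a foreground event set and a flagged set (e.g. events bearing a CLIP
#' cluster), both drawn from a common universe.
#'
#' @param fg_ids Foreground event ids (subset of `universe`).
#' @param flagged_ids Flagged event ids (subset of `universe`).
#' @param universe All eligible event ids.
#' @return List with `overlap`, `n_fg`, `n_flagged`, `n_universe`, `p`.
#' @export
overlap_enrichment <- function(fg_ids, flagged_ids, universe) {
  fg_ids <- unique(fg_ids); flagged_ids <- unique(flagged_ids)
  universe <- unique(universe)
  if (!all(fg_ids %in% universe)) stop_arg("fg_ids must lie in the universe")
  if (!all(flagged_ids %in% universe)) {
    stop_arg("flagged_ids must lie in the universe")
  }
  ov <- length(intersect(fg_ids, flagged_ids))
  p <- stats::phyper(ov - 1, length(flagged_ids),
                     length(universe) - length(flagged_ids),
                     length(fg_ids), lower.tail = FALSE)
  list(overlap = ov, n_fg = length(fg_ids), n_flagged = length(flagged_ids),
       n_universe = length(universe), p = min(max(p, 0), 1))
}

#' Flag events overlapping CLIP clusters
#'
#' Marks each SE event whose regulatory span (the two flanking introns plus
#' the alternative exon, optionally widened by `window` bp on each side)
#' overlaps at least one cluster interval.
#'
#' @param events A `splice_events` data frame (SE rows are used; other types
#'   use their alternative region).
#' @param clusters A [GenomicRanges::GRanges] of cluster intervals, e.g. from
#'   `rtracklayer::import(path, format = "bed")`.
#' @param window Extra bp added on each side of the span (default 0).
#' @return Character vector of flagged `event_id`s.
#' @export
clip_flagged_events <- function(events, clusters, window = 0L) {
  lo <- ifelse(events$type == "SE" & !is.na(events$up_start),
               events$up_end + 1L, events$alt_start)
  hi <- ifelse(events$type == "SE" & !is.na(events$dn_start),
               events$dn_start - 1L, events$alt_end)
  span <- GenomicRanges::GRanges(
    events$chrom,
    IRanges::IRanges(pmax(lo - window, 1L), hi + window)
  )
  ov <- GenomicRanges::findOverlaps(span, clusters, ignore.strand = TRUE)
  events$event_id[unique(S4Vectors::queryHits(ov))]
}
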