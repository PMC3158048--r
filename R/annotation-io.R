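#' Load transcript models from a GTF/GFF annotation
#'
#' Reads exon features from a GTF2 or GFF3 file into a flat exon table, one row
#' per exon, sorted by coordinate within each transcript. GTF attributes
#' `gene_id`/`transcript_id` (or GFF3 `Parent`/`gene` linkage) identify the
#' transcript grouping. Coordinates stay in the 1-based inclusive convention
#' shared by GTF and GenomicRanges.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param format `"gtf"` or `"gff3"`; guessed from the file extension by
#'   default.
#' @return Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @export
load_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  validate_annotation_lines(path)
  gr <- rtracklayer::import(path, format = format)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    has_tx <- as.character(gr$type) %in% c("transcript", "mRNA")
    tx_ids <- character(0)
    if (any(has_tx)) {
      tx_ids <- unique(if (format == "gff3") as.character(gr$ID[has_tx])
                       else as.character(gr$transcript_id[has_tx]))
    }
    gr <- gr[as.character(gr$type) == "exon"]
  } else {
    tx_ids <- character(0)
  }
  if (format == "gff3") {
    parent <- as.character(S4Vectors::unstrsplit(gr$Parent, sep = ","))
    gene <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
      sub("\\..*$", "", parent)
    out <- data.frame(gene_id = gene, transcript_id = parent,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene_id = as.character(gr$gene_id),
                      transcript_id = as.character(gr$transcript_id),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  }
  if (anyNA(out$gene_id) || anyNA(out$transcript_id)) {
    stop_arg("exon records without gene_id/transcript_id in ", path)
  }
  empty <- setdiff(tx_ids, unique(out$transcript_id))
  if (length(empty) > 0) {
    warning("dropping transcript(s) with zero exons: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- out[order(out$gene_id, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- which(body)[nf < 8]
  if (length(bad) > 0) {
    stop_arg("malformed annotation record at line ", bad[1], " of ", path)
  }
  invisible(TRUE)
}

#' Write an exon table as GTF
#'
#' Inverse of [load_annotation()] for the flat exon representation; emits one
#' `exon` feature per row with `gene_id`/`transcript_id` attributes.
#'
#' @param transcripts Exon data frame (see [load_annotation()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  t <- transcripts[order(transcripts$gene_id, transcripts$transcript_id,
                         transcripts$start), , drop = FALSE]
  lines <- sprintf(
    "%s\tpsikit\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    t$chrom, t$start, t$end, t$strand, t$gene_id, t$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an event catalog as TSV
#'
#' Serializes a `splice_events` table with the segment lists flattened into a
#' BED12-like block notation (`kind:start-end` segments joined by `,`).
#'
#' @param events A `splice_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(events, path) {
  flat <- function(segs) {
    vapply(segs, function(s) {
      paste(sprintf("%s:%d-%d", s$kind, s$start, s$end), collapse = ",")
    }, character(1))
  }
  out <- data.frame(
    event_id = events$event_id, type = events$type, gene_id = events$gene_id,
    chrom = events$chrom, strand = events$strand,
    alt_start = events$alt_start, alt_end = events$alt_end,
    inc_segments = flat(events$inc_segments),
    exc_segments = flat(events$exc_segments),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event catalog written by [write_event_catalog()]
#'
#' @param path TSV path.
#' @return A `splice_events` data frame (SE flanking-exon columns are `NA`;
#'   they are catalog metadata, not part of the serialized signature).
#' @export
read_event_catalog <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  parse_segs <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE), function(parts) {
      m <- regmatches(parts, regexec("^([a-z_]+):(\\d+)-(\\d+)$", parts))
      data.frame(kind = vapply(m, `[`, character(1), 2),
                 start = as.integer(vapply(m, `[`, character(1), 3)),
                 end = as.integer(vapply(m, `[`, character(1), 4)),
                 stringsAsFactors = FALSE)
    })
  }
  ev <- data.frame(
    event_id = raw$event_id, type = raw$type, gene_id = raw$gene_id,
    chrom = raw$chrom, strand = raw$strand,
    alt_start = raw$alt_start, alt_end = raw$alt_end,
    up_start = NA_integer_, up_end = NA_integer_,
    dn_start = NA_integer_, dn_end = NA_integer_,
    inc_segments = I(parse_segs(raw$inc_segments)),
    exc_segments = I(parse_segs(raw$exc_segments)),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Export an event catalog as GFF3 for genome browsers
#'
#' Each event becomes a parent feature spanning its alternative region with
#' one child feature per segment.
#'
#' @param events A `splice_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_gff3 <- function(events, path) {
  segs <- event_segment_table(events)
  parent <- GenomicRanges::GRanges(
    events$chrom,
    IRanges::IRanges(events$alt_start, events$alt_end),
    strand = events$strand, type = "region",
    ID = events$event_id, event_type = events$type
  )
  child <- GenomicRanges::GRanges(
    segs$chrom, IRanges::IRanges(segs$start, segs$end),
    strand = events$strand[segs$event], type = "match_part",
    ID = sprintf("%s.seg%d", segs$event_id, seq_len(nrow(segs))),
    Parent = segs$event_id, segment_kind = paste0(segs$side, "_", segs$kind)
  )
  rtracklayer::export(c(parent, child), path, format = "gff3")
  invisible(path)
}
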