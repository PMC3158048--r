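#' Construct a read-placement set
#'
#' A `read_placements` object stores aligned single-end reads in two flat
#' tables: one row per read and one row per aligned block (split reads have
#' one block per exonic piece). Blocks of one read are non-overlapping and
#' coordinate-sorted.
#'
#' @param reads Data frame with columns `chrom` and `strand` (use `"*"` for
#'   unstranded libraries), one row per read.
#' @param blocks Data frame with columns `read` (row index into `reads`),
#'   `start`, `end` (1-based inclusive).
#' @return A `read_placements` list with elements `reads` and `blocks`.
#' @export
read_placements <- function(reads, blocks) {
  stopifnot(all(c("chrom", "strand") %in% names(reads)),
            all(c("read", "start", "end") %in% names(blocks)))
  blocks <- blocks[order(blocks$read, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(reads = reads, blocks = blocks), class = "read_placements")
}

#' @export
print.read_placements <- function(x, ...) {
  cat(sprintf("read_placements: %d reads, %d blocks, %d split reads\n",
              nrow(x$reads), nrow(x$blocks),
              sum(duplicated(x$blocks$read))))
  invisible(x)
}

#' Number of reads in a placement set
#' @param placements A `read_placements` object.
#' @return Integer read count.
#' @export
n_reads <- function(placements) nrow(placements$reads)

#' Count inclusion/exclusion reads per event
#'
#' Assigns reads to the isoform signatures of an event catalog. A read
#' supports an exon-body (or UTR-extension) segment when its entire alignment
#' lies within the segment (for a split read no single segment can contain
#' it, so only contiguous reads qualify); it supports a junction when two
#' consecutive blocks end exactly at the donor and start exactly at the
#' acceptor with at least `min_overhang` aligned bases on each side. This
#' keeps the set of countable reads identical to the set of read-start
#' positions in the density denominators, which is what makes the
#' density-ratio PSI estimator consistent. A read is counted at most once per
#' event side. Reads are treated as unstranded; reads on other chromosomes
#' are ignored.
#'
#' Alongside the raw counts, the number of distinct mappable read-start
#' positions per side is reported, the denominator of the read-density
#' normalization: a junction contributes `read_length - 2*min_overhang + 1`
#' positions and a body segment of length L contributes
#' `max(L - read_length + 1, 1)`.
#'
#' @param events A `splice_events` data frame.
#' @param placements A `read_placements` object.
#' @param read_length Read length in bp (default 39, a typical early
#'   single-end short-read design).
#' @param min_overhang Minimum aligned bases on each side of a junction
#'   (default 4).
#' @return Data frame with one row per event: `event_id`, `inc_reads`,
#'   `exc_reads`, `inc_positions`, `exc_positions`.
#' @export
count_event_reads <- function(events, placements, read_length = 39L,
                              min_overhang = 4L) {
  if (min_overhang < 1) stop_arg("min_overhang must be >= 1")
  if (!inherits(placements, "read_placements")) {
    stop_arg("placements must be a read_placements object")
  }
  segs <- event_segment_table(events)
  blocks <- placements$blocks
  rchrom <- placements$reads$chrom

  hits <- list()

  jsegs <- segs[segs$kind == "junction", , drop = FALSE]
  if (nrow(jsegs) > 0 && nrow(blocks) > 1) {
    same <- blocks$read[-1] == blocks$read[-nrow(blocks)]
    i <- which(same)
    if (length(i) > 0) {
      w1 <- blocks$end[i] - blocks$start[i] + 1L
      w2 <- blocks$end[i + 1] - blocks$start[i + 1] + 1L
      ok <- w1 >= min_overhang & w2 >= min_overhang
      i <- i[ok]
      if (length(i) > 0) {
        pk <- paste(rchrom[blocks$read[i]], blocks$end[i],
                    blocks$start[i + 1], sep = ":")
        jk <- paste(jsegs$chrom, jsegs$start, jsegs$end, sep = ":")
        m <- merge(data.frame(read = blocks$read[i], key = pk,
                              stringsAsFactors = FALSE),
                   data.frame(key = jk, event = jsegs$event,
                              side = jsegs$side, stringsAsFactors = FALSE),
                   by = "key")
        if (nrow(m) > 0) hits[[length(hits) + 1L]] <- m[c("read", "event", "side")]
      }
    }
  }

  bsegs <- segs[segs$kind != "junction", , drop = FALSE]
  if (nrow(bsegs) > 0 && nrow(blocks) > 0) {
    # only contiguous (single-block) reads can lie entirely within a segment
    nb <- tabulate(blocks$read, nbins = nrow(placements$reads))
    contig <- blocks[nb[blocks$read] == 1L, , drop = FALSE]
    q <- GenomicRanges::GRanges(rchrom[contig$read],
                                IRanges::IRanges(contig$start, contig$end))
    s <- GenomicRanges::GRanges(bsegs$chrom,
                                IRanges::IRanges(bsegs$start, bsegs$end))
    ov <- GenomicRanges::findOverlaps(q, s, type = "within")
    if (length(ov) > 0) {
      hits[[length(hits) + 1L]] <- data.frame(
        read = contig$read[S4Vectors::queryHits(ov)],
        event = bsegs$event[S4Vectors::subjectHits(ov)],
        side = bsegs$side[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE
      )
    }
  }

  n <- nrow(events)
  inc <- integer(n); exc <- integer(n)
  if (length(hits) > 0) {
    h <- unique(do.call(rbind, hits))
    tab <- table(factor(h$event, levels = seq_len(n)), h$side)
    if ("inc" %in% colnames(tab)) inc <- as.integer(tab[, "inc"])
    if ("exc" %in% colnames(tab)) exc <- as.integer(tab[, "exc"])
  }

  pos <- segment_positions(segs, read_length, min_overhang)
  data.frame(event_id = events$event_id,
             inc_reads = inc, exc_reads = exc,
             inc_positions = pos$inc, exc_positions = pos$exc,
             stringsAsFactors = FALSE)
}

segment_positions <- function(segs, read_length, min_overhang) {
  per <- ifelse(segs$kind == "junction",
                read_length - 2L * min_overhang + 1L,
                pmax(segs$end - segs$start + 1L - read_length + 1L, 1L))
  agg <- function(side) {
    s <- segs[segs$side == side, , drop = FALSE]
    v <- tapply(per[segs$side == side], s$event, sum)
    v
  }
  n <- max(segs$event, 0)
  inc <- integer(n); exc <- integer(n)
  vi <- agg("inc"); ve <- agg("exc")
  inc[as.integer(names(vi))] <- as.integer(vi)
  exc[as.integer(names(ve))] <- as.integer(ve)
  list(inc = inc, exc = exc)
}

#' Estimate percent spliced in (PSI) from event read counts
#'
#' Converts inclusion/exclusion read counts into read densities (reads per
#' distinct mappable start position) and estimates PSI as the ratio of the
#' inclusion density to the sum of the inclusion and exclusion densities.
#' PSI is `NA` (undefined, not 0) when no read supports either isoform.
#'
#' @param counts Data frame as returned by [count_event_reads()].
#' @return The input with columns `inc_density`, `exc_density`, `psi`
#'   appended.
#' @export
estimate_psi <- function(counts) {
  if (any(counts$inc_positions <= 0) || any(counts$exc_positions <= 0)) {
    stop_arg("position counts must be positive for every event")
  }
  inc_d <- counts$inc_reads / counts$inc_positions
  exc_d <- counts$exc_reads / counts$exc_positions
  psi <- ifelse(counts$inc_reads + counts$exc_reads == 0, NA_real_,
                inc_d / (inc_d + exc_d))
  cbind(counts, inc_density = inc_d, exc_density = exc_d, psi = psi)
}

#' PSI variant for tandem 3' UTR events
#'
#' For tandem UTRs the distal (extended) isoform contains everything the
#' proximal isoform does, so PSI is estimated as the ratio of the extension
#' read density to the core read density, clamped to [0, 1]: the fraction of
#' transcripts reading through to the distal cleavage site. Undefined (`NA`)
#' when the core has no reads.
#'
#' @param core_reads,core_positions Reads and mappable positions of the shared
#'   core region.
#' @param ext_reads,ext_positions Reads and mappable positions of the distal
#'   extension region.
#' @return Numeric vector of PSI values.
#' @export
tandem_utr_psi <- function(core_reads, core_positions,
                           ext_reads, ext_positions) {
  if (any(core_positions <= 0) || any(ext_positions <= 0)) {
    stop_arg("position counts must be positive")
  }
  core_d <- core_reads / core_positions
  ext_d <- ext_reads / ext_positions
  ifelse(core_d == 0, NA_real_, pmin(pmax(ext_d / core_d, 0), 1))
}

#' Per-event PSI table dispatching on event type
#'
#' Applies [estimate_psi()] to spliced event types and the [tandem_utr_psi()]
#' variant to tandem 3' UTR events (whose inclusion signature is the UTR
#' extension and whose exclusion signature is the shared core).
#'
#' @param events A `splice_events` data frame.
#' @param counts Matching output of [count_event_reads()].
#' @return Data frame `event_id`, `type`, counts, densities and `psi`.
#' @export
psi_table <- function(events, counts) {
  stopifnot(identical(events$event_id, counts$event_id))
  out <- estimate_psi(counts)
  tu <- events$type == "TandemUTR"
  if (any(tu)) {
    out$psi[tu] <- tandem_utr_psi(counts$exc_reads[tu],
                                  counts$exc_positions[tu],
                                  counts$inc_reads[tu],
                                  counts$inc_positions[tu])
  }
  cbind(out[, "event_id", drop = FALSE], type = events$type,
        out[, setdiff(names(out), "event_id")])
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param read_count Reads assigned to the gene's constitutive exons.
#' @param constitutive_length Total constitutive exonic length in bp.
#' @param total_mapped_reads Library size (mapped reads).
#' @return RPKM values.
#' @export
compute_rpkm <- function(read_count, constitutive_length, total_mapped_reads) {
  if (any(constitutive_length <= 0)) stop_arg("constitutive_length must be > 0")
  if (any(total_mapped_reads <= 0)) stop_arg("total_mapped_reads must be > 0")
  read_count / (constitutive_length / 1e3) / (total_mapped_reads / 1e6)
}

#' Count reads on constitutive exons per gene
#'
#' A read is assigned to a gene when at least one of its blocks lies entirely
#' within one of the gene's constitutive exonic intervals; each read counts at
#' most once per gene.
#'
#' @param const_exons Output of [constitutive_exons()].
#' @param placements A `read_placements` object.
#' @return Data frame `gene_id`, `length` (total constitutive bp), `count`.
#' @export
count_gene_reads <- function(const_exons, placements) {
  genes <- unique(const_exons$gene_id)
  len <- tapply(const_exons$end - const_exons$start + 1L,
                const_exons$gene_id, sum)[genes]
  blocks <- placements$blocks
  cnt <- stats::setNames(integer(length(genes)), genes)
  if (nrow(blocks) > 0 && nrow(const_exons) > 0) {
    q <- GenomicRanges::GRanges(placements$reads$chrom[blocks$read],
                                IRanges::IRanges(blocks$start, blocks$end))
    s <- GenomicRanges::GRanges(const_exons$chrom,
                                IRanges::IRanges(const_exons$start,
                                                 const_exons$end))
    ov <- GenomicRanges::findOverlaps(q, s, type = "within")
    if (length(ov) > 0) {
      h <- unique(data.frame(
        read = blocks$read[S4Vectors::queryHits(ov)],
        gene = const_exons$gene_id[S4Vectors::subjectHits(ov)]
      ))
      tb <- table(factor(h$gene, levels = genes))
      cnt <- stats::setNames(as.integer(tb), genes)
    }
  }
  data.frame(gene_id = genes, length = as.integer(len), count = cnt,
             row.names = NULL, stringsAsFactors = FALSE)
}
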