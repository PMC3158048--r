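#' Read aligned placements from a BED12 file
#'
#' Split reads are encoded by the BED12 block fields. BED half-open 0-based
#' coordinates are converted to the 1-based inclusive internal convention by
#' rtracklayer on import.
#'
#' @param path BED12 (or BED6) file path.
#' @return A `read_placements` object.
#' @export
read_placements_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  if (!is.null(gr$blocks) && n > 0) {
    bl <- gr$blocks
    nb <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    off <- rep(GenomicRanges::start(gr), nb) - 1L
    blocks <- data.frame(read = rep(seq_len(n), nb),
                         start = IRanges::start(flat) + off,
                         end = IRanges::end(flat) + off)
  } else {
    blocks <- data.frame(read = seq_len(n),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr))
  }
  read_placements(reads, blocks)
}

#' Write placements as BED12
#'
#' @param placements A `read_placements` object.
#' @param path Output BED file path.
#' @return `path`, invisibly.
#' @export
write_placements_bed <- function(placements, path) {
  b <- placements$blocks
  n <- nrow(placements$reads)
  span_start <- tapply(b$start, b$read, min)
  span_end <- tapply(b$end, b$read, max)
  idx <- as.integer(names(span_start))
  gr <- GenomicRanges::GRanges(
    placements$reads$chrom[idx],
    IRanges::IRanges(as.integer(span_start), as.integer(span_end)),
    strand = placements$reads$strand[idx]
  )
  gr$name <- sprintf("read%d", idx)
  off <- rep(as.integer(span_start), tabulate(b$read, n)[idx])
  rel <- IRanges::IRanges(b$start - off + 1L, b$end - off + 1L)
  gr$blocks <- S4Vectors::split(rel, factor(b$read, levels = idx))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read aligned placements from a SAM/BAM file
#'
#' Consumes a coordinate-less SAM or BAM file of single-end alignments.
#' Spliced alignments are split into blocks at `N` CIGAR operations;
#' unmapped, secondary and supplementary records are skipped.
#'
#' @param path SAM or BAM file path.
#' @return A `read_placements` object.
#' @export
read_placements_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, indexDestination = FALSE,
                             overwrite = TRUE)
  }
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "cigar",
                                             "strand"))
  )[[1]]
  keep <- !is.na(res$pos) &
    bitwAnd(res$flag, 0x4L) == 0L &
    bitwAnd(res$flag, 0x100L) == 0L &
    bitwAnd(res$flag, 0x800L) == 0L
  chrom <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  cig <- res$cigar[keep]
  strand <- as.character(res$strand)[keep]
  bl <- cigar_blocks(cig, pos)
  read_placements(
    data.frame(chrom = chrom, strand = strand, stringsAsFactors = FALSE),
    bl
  )
}

#' Convert CIGAR strings to reference-space blocks
#'
#' `M`, `=`, `X` and `D` consume the reference within a block; `N` closes the
#' current block and opens the next; `I`, `S`, `H`, `P` do not consume the
#' reference.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos 1-based leftmost reference positions.
#' @return Data frame `read`, `start`, `end`.
#' @export
cigar_blocks <- function(cigar, pos) {
  out_read <- integer(0); out_start <- integer(0); out_end <- integer(0)
  for (i in seq_along(cigar)) {
    ops <- regmatches(cigar[i], gregexpr("\\d+[MIDNSHP=X]", cigar[i]))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    cur <- pos[i]
    bstart <- cur
    open <- FALSE
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X", "D")) {
        if (!open) { bstart <- cur; open <- TRUE }
        cur <- cur + len[k]
      } else if (op[k] == "N") {
        if (open) {
          out_read <- c(out_read, i)
          out_start <- c(out_start, bstart)
          out_end <- c(out_end, cur - 1L)
          open <- FALSE
        }
        cur <- cur + len[k]
      }
      # I/S/H/P: no reference consumption
    }
    if (open) {
      out_read <- c(out_read, i)
      out_start <- c(out_start, bstart)
      out_end <- c(out_end, cur - 1L)
    }
  }
  data.frame(read = out_read, start = out_start, end = out_end)
}

#' Write a PSI table as TSV
#'
#' @param psi Output of [psi_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(psi, path) {
  utils::write.table(psi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
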