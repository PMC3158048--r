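# toy exon-table builder: one transcript from paired start/end vectors
tx_df <- function(gene, tid, starts, ends, chrom = "chr1", strand = "+") {
  data.frame(gene_id = gene, transcript_id = tid, chrom = chrom,
             strand = strand, start = as.integer(starts),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

# placements from a list of block matrices (one element per read, each a
# 2-column start/end matrix)
reads_from_blocks <- function(block_list, chrom = "chr1") {
  nb <- vapply(block_list, nrow, integer(1))
  blocks <- do.call(rbind, lapply(seq_along(block_list), function(i) {
    data.frame(read = i, start = block_list[[i]][, 1],
               end = block_list[[i]][, 2])
  }))
  read_placements(
    data.frame(chrom = chrom, strand = "*", stringsAsFactors = FALSE)[
      rep(1, length(block_list)), , drop = FALSE],
    blocks
  )
}

# the canonical three-exon skipped-exon gene used across quant tests:
# flanks 101-250 and 1371-1520, alternative exon 1101-1220
se_toy <- function(strand = "+") {
  rbind(tx_df("g1", "g1.t1", c(101, 1101, 1371), c(250, 1220, 1520),
              strand = strand),
        tx_df("g1", "g1.t2", c(101, 1371), c(250, 1520), strand = strand))
}

# wrap estimate_psi output in the psi_table column layout
as_psi_table <- function(counts, type = "SE") {
  est <- estimate_psi(counts)
  est$type <- rep_len(type, nrow(est))
  est[, c("event_id", "type",
          setdiff(names(est), c("event_id", "type")))]
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# brute-force two-sided Audic-Claverie p by direct summation of the
# conditional point probabilities
ac_brute <- function(x, y, N1, N2) {
  n <- x + y
  if (n == 0) return(1)
  q <- N2 / (N1 + N2)
  lp <- vapply(0:n, function(k) {
    lchoose(n, k) + k * log(q) + (n - k) * log(1 - q)
  }, numeric(1))
  min(sum(exp(lp[lp <= lp[y + 1] + 1e-12])), 1)
}

# brute-force upper-tail hypergeometric by explicit enumeration
hyper_brute <- function(obs, K, N, n) {
  ks <- max(obs, 0):min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}
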