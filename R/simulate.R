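# Gene geometry used by the annotation simulator (bp). Flank and alternative
# exon sizes are chosen so every isoform signature is mappable with 39-bp
# reads at the default junction overhang.
SIM_FLANK_EXON <- 150L
SIM_ALT_EXON <- 120L
SIM_ALTSS_EXT <- 60L
SIM_TANDEM_CORE <- 200L
SIM_TANDEM_EXT <- 250L
SIM_TERMINAL_GAP <- 150L
SIM_GENE_GAP <- 500L

# Local (1-based, plus-strand) two-transcript layouts per event type.
# t1 is always the inclusion/long isoform.
sim_gene_layout <- function(type, introns) {
  ex <- function(s, len) c(s, s + len - 1L)
  i <- introns
  if (type == "SE") {
    A <- ex(1L, SIM_FLANK_EXON)
    E <- ex(A[2] + i[1] + 1L, SIM_ALT_EXON)
    B <- ex(E[2] + i[2] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, E, B), t2 = rbind(A, B))
  } else if (type == "MXE") {
    A <- ex(1L, SIM_FLANK_EXON)
    X <- ex(A[2] + i[1] + 1L, SIM_ALT_EXON)
    Y <- ex(X[2] + i[2] + 1L, SIM_ALT_EXON)
    B <- ex(Y[2] + i[3] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, X, B), t2 = rbind(A, Y, B))
  } else if (type == "RI") {
    A <- ex(1L, SIM_FLANK_EXON)
    B <- ex(A[2] + i[1] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(c(A[1], B[2])), t2 = rbind(A, B))
  } else if (type == "A5SS") {
    A <- ex(1L, SIM_FLANK_EXON)
    Bs <- ex(A[2] + i[1] + 1L, SIM_FLANK_EXON)
    Bl <- c(Bs[1], Bs[2] + SIM_ALTSS_EXT)
    C <- ex(Bl[2] + i[2] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, Bl, C), t2 = rbind(A, Bs, C))
  } else if (type == "A3SS") {
    A <- ex(1L, SIM_FLANK_EXON)
    Bl <- ex(A[2] + i[1] + 1L, SIM_FLANK_EXON + SIM_ALTSS_EXT)
    Bs <- c(Bl[1] + SIM_ALTSS_EXT, Bl[2])
    C <- ex(Bl[2] + i[2] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, Bl, C), t2 = rbind(A, Bs, C))
  } else if (type == "AFE") {
    Fd <- ex(1L, SIM_FLANK_EXON)
    Fp <- ex(Fd[2] + SIM_TERMINAL_GAP + 1L, SIM_FLANK_EXON)
    B <- ex(Fp[2] + i[1] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(Fp, B), t2 = rbind(Fd, B))
  } else if (type == "ALE") {
    A <- ex(1L, SIM_FLANK_EXON)
    Lp <- ex(A[2] + i[1] + 1L, SIM_FLANK_EXON)
    Ld <- ex(Lp[2] + SIM_TERMINAL_GAP + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, Lp), t2 = rbind(A, Ld))
  } else if (type == "TandemUTR") {
    A <- ex(1L, SIM_FLANK_EXON)
    Ul <- ex(A[2] + i[1] + 1L, SIM_TANDEM_CORE + SIM_TANDEM_EXT)
    Us <- c(Ul[1], Ul[1] + SIM_TANDEM_CORE - 1L)
    list(t1 = rbind(A, Ul), t2 = rbind(A, Us))
  } else if (type == "null") {
    A <- ex(1L, SIM_FLANK_EXON)
    B <- ex(A[2] + i[1] + 1L, SIM_ALT_EXON)
    C <- ex(B[2] + i[2] + 1L, SIM_FLANK_EXON)
    list(t1 = rbind(A, B, C), t2 = NULL)
  } else {
    stop_arg("unknown event type: ", type)
  }
}

reflect_exons <- function(exons, span) {
  out <- cbind(span + 1L - exons[, 2], span + 1L - exons[, 1])
  out[order(out[, 1]), , drop = FALSE]
}

#' Simulate a two-isoform gene annotation with planted events
#'
#' Generates non-overlapping genes on one synthetic chromosome (`chrS`); each
#' requested event is realized by a two-transcript gene with the minimal
#' geometry for its type (transcript `*.t1` always carries the
#' inclusion/long isoform), and remaining genes are single-isoform controls.
#' Gene strands alternate so that both orientations are exercised. A random
#' genome sequence covering the locus is generated alongside. The output is a
#' pure function of the arguments and the seed.
#'
#' @param n_genes Total genes; must be at least the number of planted events.
#' @param events_per_type Named integer vector over the event types
#'   (`SE`, `RI`, `MXE`, `A5SS`, `A3SS`, `AFE`, `ALE`, `TandemUTR`); missing
#'   names default to 0.
#' @param intron_len_range Range the intron lengths are drawn from (bp).
#' @param seed Integer seed.
#' @return List with `transcripts` (exon data frame as from
#'   [load_annotation()]), `genome` (a [Biostrings::DNAStringSet] with
#'   `chrS`), and `truth`: a list with `genes` (gene_id, type, strand, start,
#'   end) and `events` (gene_id, type for each planted event).
#' @export
simulate_annotation <- function(n_genes, events_per_type = c(SE = 10),
                                intron_len_range = c(300L, 1000L), seed = 1) {
  ept <- stats::setNames(integer(length(EVENT_TYPES)), EVENT_TYPES)
  ept[names(events_per_type)] <- as.integer(events_per_type)
  if (any(is.na(ept)) || any(ept < 0)) stop_arg("invalid events_per_type")
  if (!all(names(events_per_type) %in% EVENT_TYPES)) {
    stop_arg("unknown event type in events_per_type")
  }
  total_events <- sum(ept)
  if (n_genes < total_events) {
    stop_arg("n_genes must be >= the number of requested events")
  }
  if (intron_len_range[1] < 50) {
    stop_arg("introns shorter than 50 bp leave no room for junction flanks")
  }
  types <- c(rep(names(ept), ept), rep("null", n_genes - total_events))
  with_seed(seed, {
    offset <- 0L
    tx_rows <- list()
    gene_rows <- list()
    for (gi in seq_along(types)) {
      type <- types[gi]
      gene_id <- sprintf("g%03d", gi)
      strand <- if (gi %% 2 == 1) "+" else "-"
      introns <- sample(seq(intron_len_range[1], intron_len_range[2]), 3,
                        replace = TRUE)
      lay <- sim_gene_layout(type, introns)
      span <- max(lay$t1[, 2], if (!is.null(lay$t2)) lay$t2[, 2] else 0L)
      if (strand == "-") {
        lay$t1 <- reflect_exons(lay$t1, span)
        if (!is.null(lay$t2)) lay$t2 <- reflect_exons(lay$t2, span)
        if (type == "MXE") {
          # the derived MXE iso1 is the genomically left alternative exon;
          # keep t1 (the PSI-tracked isoform) aligned with it after mirroring
          tmp <- lay$t1; lay$t1 <- lay$t2; lay$t2 <- tmp
        }
      }
      for (tn in c("t1", "t2")) {
        exons <- lay[[tn]]
        if (is.null(exons)) next
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".", tn),
          chrom = "chrS", strand = strand,
          start = exons[, 1] + offset, end = exons[, 2] + offset,
          stringsAsFactors = FALSE
        )
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gene_id, type = type, strand = strand,
        start = offset + 1L, end = offset + span, stringsAsFactors = FALSE
      )
      offset <- offset + span + SIM_GENE_GAP
    }
    transcripts <- do.call(rbind, tx_rows)
    rownames(transcripts) <- NULL
    genes <- do.call(rbind, gene_rows)
    genome_len <- offset + SIM_GENE_GAP
    seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                 collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrS"))
    ev <- genes[genes$type != "null", c("gene_id", "type")]
    rownames(ev) <- NULL
    list(transcripts = transcripts, genome = genome,
         truth = list(genes = genes, events = ev, seed = seed))
  })
}

# map transcript-coordinate read starts onto genomic blocks
tx_read_blocks <- function(exons, starts, read_length) {
  w <- exons$end - exons$start + 1L
  cum <- cumsum(w)
  off <- c(0L, cum[-length(cum)])
  ends <- starts + read_length - 1L
  i1 <- findInterval(starts - 1L, cum) + 1L
  i2 <- findInterval(ends - 1L, cum) + 1L
  n <- length(starts)
  res_read <- integer(0); res_start <- integer(0); res_end <- integer(0)
  g1s <- exons$start[i1] + (starts - off[i1] - 1L)
  one <- i1 == i2
  if (any(one)) {
    res_read <- which(one)
    res_start <- g1s[one]
    res_end <- g1s[one] + read_length - 1L
  }
  multi <- which(!one)
  for (ri in multi) {
    idx <- i1[ri]:i2[ri]
    bs <- pmax(exons$start[idx], c(g1s[ri], exons$start[idx[-1]]))
    be <- c(exons$end[idx[-length(idx)]],
            exons$start[i2[ri]] + (ends[ri] - off[i2[ri]] - 1L))
    res_read <- c(res_read, rep(ri, length(idx)))
    res_start <- c(res_start, bs)
    res_end <- c(res_end, be)
  }
  data.frame(read = res_read, start = res_start, end = res_end)
}

#' Simulate read placements for one condition
#'
#' Draws single-end reads of length `read_length` uniformly over transcript
#' coordinates. Per-gene totals are Poisson with mean proportional to the
#' gene's expression weight; within a gene, reads are split between the
#' inclusion transcript (`*.t1`) and the exclusion transcript in proportion
#' to `psi * positions(t1)` versus `(1 - psi) * positions(t2)`, where
#' `positions` is the number of possible fragment start positions
#' (`transcript length - read_length + 1`). This mirrors real libraries, in
#' which longer isoforms contribute proportionally more fragments per
#' molecule, and makes per-position coverage proportional to molar isoform
#' concentration — the assumption behind the density-ratio PSI estimator.
#' Reads crossing splice junctions are emitted as split placements. Coverage
#' is positionally uniform (no fragmentation bias) and error-free.
#'
#' @param sim Output of [simulate_annotation()].
#' @param depth Expected total read count for the condition.
#' @param psi Named vector of true inclusion fractions per event gene
#'   (default 0.5 everywhere).
#' @param expr Named vector of positive expression weights per gene
#'   (default equal).
#' @param read_length Read length in bp (default 39).
#' @param seed Integer seed.
#' @return A `read_placements` object; the realized total read count is
#'   attached as attribute `total_reads` and the drawn truth as attribute
#'   `truth` (data frame `gene_id`, `psi`, `expr`, `n_reads`).
#' @export
simulate_reads <- function(sim, depth, psi = NULL, expr = NULL,
                           read_length = 39L, seed = 1) {
  if (depth < 0) stop_arg("depth must be >= 0")
  genes <- sim$truth$genes
  event_genes <- sim$truth$events$gene_id
  psi_full <- stats::setNames(rep(1, nrow(genes)), genes$gene_id)
  psi_full[event_genes] <- 0.5
  if (!is.null(psi)) psi_full[names(psi)] <- psi
  expr_full <- stats::setNames(rep(1, nrow(genes)), genes$gene_id)
  if (!is.null(expr)) expr_full[names(expr)] <- expr
  if (any(psi_full < 0 | psi_full > 1)) stop_arg("psi must lie in [0, 1]")
  if (any(expr_full < 0)) stop_arg("expr must be non-negative")
  txs <- lapply(split(sim$transcripts, sim$transcripts$transcript_id),
                function(t) t[order(t$start), , drop = FALSE])
  with_seed(seed, {
    lambda <- depth * expr_full / sum(expr_full)
    n_gene <- stats::rpois(length(lambda), lambda)
    blocks <- list(); chroms <- character(0)
    base <- 0L
    truth_rows <- list()
    for (gi in seq_len(nrow(genes))) {
      g <- genes$gene_id[gi]
      n <- n_gene[gi]
      truth_rows[[gi]] <- data.frame(gene_id = g, psi = psi_full[g],
                                     expr = expr_full[g], n_reads = n,
                                     stringsAsFactors = FALSE)
      if (n == 0) next
      npos <- function(tn) {
        tx <- txs[[paste0(g, ".", tn)]]
        if (is.null(tx)) return(0L)
        max(sum(tx$end - tx$start + 1L) - read_length + 1L, 0L)
      }
      w1 <- psi_full[g] * npos("t1")
      w2 <- (1 - psi_full[g]) * npos("t2")
      p1 <- if (w1 + w2 == 0) 1 else w1 / (w1 + w2)
      n1 <- stats::rbinom(1, n, p1)
      for (tn in c("t1", "t2")) {
        nt <- if (tn == "t1") n1 else n - n1
        tx <- txs[[paste0(g, ".", tn)]]
        if (nt == 0 || is.null(tx)) next
        L <- sum(tx$end - tx$start + 1L)
        if (L < read_length) next
        starts <- sample.int(L - read_length + 1L, nt, replace = TRUE)
        bl <- tx_read_blocks(tx, starts, read_length)
        bl$read <- bl$read + base
        blocks[[length(blocks) + 1L]] <- bl
        chroms <- c(chroms, rep(tx$chrom[1], nt))
        base <- base + nt
      }
    }
    pl <- read_placements(
      data.frame(chrom = if (base > 0) chroms else character(0),
                 strand = rep("*", base), stringsAsFactors = FALSE),
      if (length(blocks) > 0) do.call(rbind, blocks) else
        data.frame(read = integer(0), start = integer(0), end = integer(0))
    )
    attr(pl, "total_reads") <- base
    attr(pl, "truth") <- do.call(rbind, truth_rows)
    pl
  })
}

#' Simulate per-event inclusion/exclusion count tables
#'
#' Direct count-level simulation of the read-density model: for each event
#' and condition, inclusion reads are Poisson with mean proportional to
#' `positions * psi` and exclusion reads proportional to
#' `positions * (1 - psi)`, scaled so the expected informative reads per
#' event equal `depth`. Position counts default to the simulator's standard
#' SE geometry (120-nt exon, 39-nt reads, overhang 4).
#'
#' @param n_events Number of events.
#' @param depth Expected informative (inclusion + exclusion) reads per event.
#' @param psi_1,psi_2 True PSI per condition (scalar or length `n_events`).
#' @param inc_positions,exc_positions Mappable start positions per side.
#' @param seed Integer seed.
#' @return List with `counts_1`, `counts_2` (data frames compatible with
#'   [estimate_psi()]) and `truth` (`event_id`, `psi_1`, `psi_2`).
#' @export
simulate_event_counts <- function(n_events, depth, psi_1, psi_2 = psi_1,
                                  inc_positions = 146L, exc_positions = 32L,
                                  seed = 1) {
  psi_1 <- rep_len(psi_1, n_events)
  psi_2 <- rep_len(psi_2, n_events)
  ids <- sprintf("ev%04d", seq_len(n_events))
  draw <- function(psi) {
    mu_inc <- inc_positions * psi
    mu_exc <- exc_positions * (1 - psi)
    scale <- depth / (mu_inc + mu_exc)
    data.frame(event_id = ids,
               inc_reads = stats::rpois(n_events, scale * mu_inc),
               exc_reads = stats::rpois(n_events, scale * mu_exc),
               inc_positions = inc_positions,
               exc_positions = exc_positions,
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    list(counts_1 = draw(psi_1), counts_2 = draw(psi_2),
         truth = data.frame(event_id = ids, psi_1 = psi_1, psi_2 = psi_2,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate two-condition gene count tables with planted fold changes
#'
#' Gene concentrations are log-normal; `n_changed` genes get their
#' concentration multiplied (or divided, alternating) by `fold` in condition
#' 2. Counts are Poisson at the requested library depths.
#'
#' @param n_genes Number of genes.
#' @param n_changed Number of genes with a planted fold change.
#' @param fold Planted concentration ratio (> 1).
#' @param depth_1,depth_2 Expected library sizes.
#' @param gene_length Constitutive length assigned to every gene (bp).
#' @param seed Integer seed.
#' @return List with `expr_1`, `expr_2` (data frames `gene_id`, `count`,
#'   `length`), `N1`, `N2` (realized totals) and `truth` (`gene_id`,
#'   `changed`, `direction`).
#' @export
simulate_expression_counts <- function(n_genes, n_changed, fold = 5,
                                       depth_1 = 1e6, depth_2 = 1e6,
                                       gene_length = 1000L, seed = 1) {
  if (n_changed > n_genes) stop_arg("n_changed must be <= n_genes")
  with_seed(seed, {
    ids <- sprintf("g%05d", seq_len(n_genes))
    conc <- stats::rlnorm(n_genes, 0, 1)
    mult <- rep(1, n_genes)
    dir <- rep("none", n_genes)
    if (n_changed > 0) {
      up <- seq_len(ceiling(n_changed / 2))
      dn <- setdiff(seq_len(n_changed), up)
      mult[up] <- fold; dir[up] <- "up"
      mult[dn] <- 1 / fold; dir[dn] <- "down"
    }
    conc2 <- conc * mult
    c1 <- stats::rpois(n_genes, depth_1 * conc / sum(conc))
    c2 <- stats::rpois(n_genes, depth_2 * conc2 / sum(conc2))
    list(
      expr_1 = data.frame(gene_id = ids, count = c1, length = gene_length,
                          stringsAsFactors = FALSE),
      expr_2 = data.frame(gene_id = ids, count = c2, length = gene_length,
                          stringsAsFactors = FALSE),
      N1 = sum(c1), N2 = sum(c2),
      truth = data.frame(gene_id = ids, changed = mult != 1, direction = dir,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a two-class PSI sample panel
#'
#' Builds an events x samples inclusion matrix with two sample classes. A
#' random `affected_fraction` of the events separates the classes: their
#' class means differ by `effect_dpsi` with randomized sign; the rest share
#' one mean. Gaussian noise of sd `noise_sd` is added, values are clamped to
#' [0, 1], and entries are masked missing at `missing_rate`.
#'
#' @param n_class1,n_class2 Samples per class.
#' @param n_events Number of events (rows).
#' @param effect_dpsi Between-class PSI difference for affected events.
#' @param noise_sd Gaussian noise standard deviation.
#' @param missing_rate Fraction of entries set to `NA`.
#' @param affected_fraction Fraction of events carrying the effect
#'   (default 0.5).
#' @param seed Integer seed.
#' @return List with `panel` (matrix, rows `ev*`, columns `s*`), `labels`
#'   (`"class1"`/`"class2"`) and `truth` (`event_id`, `affected`,
#'   `mu_class1`, `mu_class2`).
#' @export
simulate_panel <- function(n_class1 = 12, n_class2 = 12, n_events = 300,
                           effect_dpsi = 0.3, noise_sd = 0.1,
                           missing_rate = 0, affected_fraction = 0.5,
                           seed = 1) {
  if (effect_dpsi < 0 || effect_dpsi > 1) stop_arg("effect_dpsi must be in [0, 1]")
  with_seed(seed, {
    ids <- sprintf("ev%04d", seq_len(n_events))
    n_aff <- round(affected_fraction * n_events)
    affected <- seq_len(n_events) %in% sample(n_events, n_aff)
    lo <- stats::runif(n_events, 0, 1 - effect_dpsi)
    hi <- lo + effect_dpsi
    flip <- stats::runif(n_events) < 0.5
    mu1 <- ifelse(affected, ifelse(flip, hi, lo), stats::runif(n_events))
    mu2 <- ifelse(affected, ifelse(flip, lo, hi), mu1)
    n_s <- n_class1 + n_class2
    mu <- cbind(matrix(rep(mu1, n_class1), ncol = n_class1),
                matrix(rep(mu2, n_class2), ncol = n_class2))
    panel <- mu + matrix(stats::rnorm(n_events * n_s, 0, noise_sd),
                         nrow = n_events)
    panel <- pmin(pmax(panel, 0), 1)
    if (missing_rate > 0) {
      panel[matrix(stats::runif(n_events * n_s) < missing_rate,
                   nrow = n_events)] <- NA
    }
    rownames(panel) <- ids
    colnames(panel) <- sprintf("s%02d", seq_len(n_s))
    list(panel = panel,
         labels = rep(c("class1", "class2"), c(n_class1, n_class2)),
         truth = data.frame(event_id = ids, affected = affected,
                            mu_class1 = mu1, mu_class2 = mu2,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate flank-region sets with a planted motif
#'
#' Generates random RNA flank sequences in the [extract_flanks()] layout for
#' disjoint foreground and background event sets, and plants a motif into a
#' chosen (region, element) class: each foreground sequence of that class
#' receives one insertion with probability `fg_rate`, each background
#' sequence with probability `bg_rate`, at a uniform position.
#'
#' @param n_fg,n_bg Number of foreground/background events.
#' @param width Flank length in nt.
#' @param motif RNA word to plant (default the RBFOX core `UGCAUG`).
#' @param region,element Flank class receiving the planted motif.
#' @param fg_rate,bg_rate Insertion probabilities per sequence.
#' @param seed Integer seed.
#' @return List with `fg` and `bg` flank tables.
#' @export
simulate_flank_sets <- function(n_fg, n_bg, width = 250L, motif = "UGCAUG",
                                region = "downstream_intron", element = "I5",
                                fg_rate = 0.5, bg_rate = 0.05, seed = 1) {
  with_seed(seed, {
    gen <- function(prefix, n, rate) {
      grid <- expand.grid(element = FLANK_ELEMENTS, region = FLANK_REGIONS,
                          i = seq_len(n), stringsAsFactors = FALSE)
      m <- nrow(grid)
      chars <- sample(c("A", "C", "G", "U"), m * width, replace = TRUE)
      seqs <- vapply(seq_len(m), function(k) {
        paste(chars[((k - 1) * width + 1):(k * width)], collapse = "")
      }, character(1))
      target <- grid$region == region & grid$element == element
      plant <- target & stats::runif(m) < rate
      if (any(plant)) {
        pos <- sample.int(width - nchar(motif) + 1L, sum(plant), replace = TRUE)
        substr(seqs[plant], pos, pos + nchar(motif) - 1L) <- motif
      }
      data.frame(event_id = sprintf("%s%04d", prefix, grid$i),
                 region = grid$region, element = grid$element, seq = seqs,
                 stringsAsFactors = FALSE)
    }
    list(fg = gen("fg", n_fg, fg_rate), bg = gen("bg", n_bg, bg_rate))
  })
}

#' Simulate paired inclusion-change datasets with sign flips
#'
#' Emulates comparing one dataset's inclusion changes with an independent
#' measurement that disagrees in direction with probability `flip_prob`.
#'
#' @param n Number of events.
#' @param flip_prob Probability that the second dataset's sign flips.
#' @param seed Integer seed.
#' @return List of two named vectors `a` and `b`.
#' @export
simulate_coherence_deltas <- function(n, flip_prob, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("ev%04d", seq_len(n))
    mag <- stats::runif(n, 0.05, 1)
    a <- mag * sample(c(-1, 1), n, replace = TRUE)
    flip <- ifelse(stats::runif(n) < flip_prob, -1, 1)
    b <- a * flip * stats::runif(n, 0.5, 1.5)
    list(a = stats::setNames(a, ids), b = stats::setNames(b, ids))
  })
}
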