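#' Audic-Claverie exact test for two read counts
#'
#' Tests whether a transcript's read counts `x` and `y`, observed in two
#' libraries of sizes `N1` and `N2`, are consistent with one common underlying
#' concentration. Under a flat prior on that concentration the
#' Audic-Claverie joint probability of `(x, y)` is proportional to
#' `choose(x+y, y) * p^x * q^y` with `p = N1/(N1+N2)`, `q = N2/(N1+N2)`;
#' conditioning on the total `n = x + y` gives `y ~ Binomial(n, q)`. The
#' two-sided p-value sums every outcome whose point probability does not
#' exceed that of the observed split, computed in log space, and is exactly
#' symmetric under exchanging `(x, N1)` with `(y, N2)`.
#'
#' @param x,y Non-negative read counts (vectors recycle).
#' @param N1,N2 Positive library sizes.
#' @return Two-sided p-values in (0, 1].
#' @export
audic_claverie_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop_arg("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop_arg("library sizes must be positive")
  m <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, m); y <- rep_len(y, m)
  N1 <- rep_len(N1, m); N2 <- rep_len(N2, m)
  vapply(seq_len(m), function(i) {
    n <- x[i] + y[i]
    if (n == 0) return(1)
    q <- N2[i] / (N1[i] + N2[i])
    lp <- stats::dbinom(0:n, n, q, log = TRUE)
    obs <- lp[y[i] + 1]
    p <- sum(exp(lp[lp <= obs + 1e-12]))
    min(max(p, exp(obs)), 1)
  }, numeric(1))
}

#' Differential gene expression between two libraries
#'
#' Combines the Audic-Claverie exact test (Benjamini-Hochberg adjusted) with
#' an RPKM fold-change filter: a gene is called significant when its adjusted
#' p-value is at most `alpha` and its RPKM ratio is at least `fold_cutoff` in
#' either direction. Genes absent from one table are treated as count 0
#' there. A gene expressed in only one library has an infinite fold change,
#' capped at 2^15 for reporting.
#'
#' @param expr_1,expr_2 Data frames with columns `gene_id`, `count`, `length`
#'   (constitutive exonic length in bp, assumed shared across conditions).
#' @param N1,N2 Total mapped reads in each library; default is the sum of the
#'   counts.
#' @param fold_cutoff Minimum RPKM fold change (default 3).
#' @param alpha FDR threshold on the adjusted Audic-Claverie p (default 0.05).
#' @return Data frame with `gene_id`, `count_1`, `count_2`, `rpkm_1`,
#'   `rpkm_2`, `fold_change` (condition 2 over condition 1), `p_ac`, `fdr`,
#'   `significant`, `direction` (`"up"`/`"down"` in condition 2, `"none"`).
#' @export
diff_expression <- function(expr_1, expr_2, N1 = sum(expr_1$count),
                            N2 = sum(expr_2$count), fold_cutoff = 3,
                            alpha = 0.05) {
  genes <- union(expr_1$gene_id, expr_2$gene_id)
  get <- function(e, col) {
    v <- e[[col]][match(genes, e$gene_id)]
    v
  }
  c1 <- get(expr_1, "count"); c2 <- get(expr_2, "count")
  c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
  len <- get(expr_1, "length")
  len2 <- get(expr_2, "length")
  len[is.na(len)] <- len2[is.na(len)]
  rpkm1 <- compute_rpkm(c1, len, N1)
  rpkm2 <- compute_rpkm(c2, len, N2)
  fold <- ifelse(rpkm1 == 0 & rpkm2 == 0, 1,
                 ifelse(rpkm1 == 0, 2^15, pmin(rpkm2 / rpkm1, 2^15)))
  p <- audic_claverie_pvalue(c1, c2, N1, N2)
  fdr <- benjamini_hochberg(p)
  sig <- fdr <= alpha & (fold >= fold_cutoff | fold <= 1 / fold_cutoff)
  dir <- ifelse(!sig, "none", ifelse(fold > 1, "up", "down"))
  data.frame(gene_id = genes, count_1 = c1, count_2 = c2,
             rpkm_1 = rpkm1, rpkm_2 = rpkm2, fold_change = fold,
             p_ac = p, fdr = fdr, significant = sig, direction = dir,
             stringsAsFactors = FALSE)
}

#' Differential splicing between two conditions
#'
#' For every event quantified in both conditions with a defined PSI, tests the
#' 2x2 table of inclusion/exclusion read counts against condition with a
#' two-sided Fisher exact test, adjusts across events by Benjamini-Hochberg,
#' and reports the PSI difference `delta_psi = psi_2 - psi_1` (condition 1 is
#' conventionally the epithelial/reference sample, condition 2 the
#' mesenchymal/treated sample, so `delta_psi < 0` marks epithelial inclusion).
#' With one library per condition, reads are the sampling units; for
#' biological inference across replicates this is anti-conservative.
#'
#' @param psi_1,psi_2 Outputs of [psi_table()] over the same event catalog.
#' @return Data frame of `DiffSpliceRecord`s: `event_id`, `type`, `psi_1`,
#'   `psi_2`, `delta_psi`, `p`, `fdr`, `direction`
#'   (`"epithelial-inclusion"` / `"mesenchymal-inclusion"` / `"none"`).
#' @export
diff_splicing <- function(psi_1, psi_2) {
  stopifnot(identical(psi_1$event_id, psi_2$event_id))
  ok <- !is.na(psi_1$psi) & !is.na(psi_2$psi)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " event(s) with undefined PSI in at least one condition dropped")
  }
  a <- psi_1[ok, , drop = FALSE]
  b <- psi_2[ok, , drop = FALSE]
  p <- vapply(seq_len(nrow(a)), function(i) {
    tab <- matrix(c(a$inc_reads[i], a$exc_reads[i],
                    b$inc_reads[i], b$exc_reads[i]), nrow = 2)
    if (sum(tab) == 0) return(NA_real_)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  zero <- is.na(p)
  if (any(zero)) message(sum(zero), " all-zero event table(s) skipped")
  a <- a[!zero, , drop = FALSE]; b <- b[!zero, , drop = FALSE]
  p <- p[!zero]
  dpsi <- b$psi - a$psi
  fdr <- benjamini_hochberg(p)
  data.frame(event_id = a$event_id, type = a$type,
             psi_1 = a$psi, psi_2 = b$psi, delta_psi = dpsi,
             p = p, fdr = fdr,
             direction = ifelse(dpsi < 0, "epithelial-inclusion",
                                ifelse(dpsi > 0, "mesenchymal-inclusion",
                                       "none")),
             stringsAsFactors = FALSE)
}

#' Filter differential splicing records by effect size and FDR
#'
#' Keeps records with `|delta_psi| >= min_abs_dpsi` and `fdr <= max_fdr`;
#' both thresholds are inclusive.
#'
#' @param records Output of [diff_splicing()].
#' @param min_abs_dpsi Minimum absolute PSI change (default 0.1).
#' @param max_fdr Maximum FDR (default 0.05).
#' @return The passing subset of `records`.
#' @export
filter_events <- function(records, min_abs_dpsi = 0.1, max_fdr = 0.05) {
  records[abs(records$delta_psi) >= min_abs_dpsi &
            records$fdr <= max_fdr, , drop = FALSE]
}

#' Fraction of genes with at least one regulated event
#'
#' The numerator counts distinct genes owning at least one record passing the
#' thresholds; the denominator counts distinct genes with at least one tested
#' record (both isoforms detected).
#'
#' @param records Output of [diff_splicing()].
#' @param gene_map Named character vector mapping `event_id` to `gene_id`.
#' @inheritParams filter_events
#' @return A single fraction in [0, 1].
#' @export
gene_level_fraction <- function(records, gene_map, min_abs_dpsi = 0.1,
                                max_fdr = 0.05) {
  unmapped <- setdiff(records$event_id, names(gene_map))
  if (length(unmapped) > 0) {
    stop_arg("event(s) missing from gene_map: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
  }
  tested <- unique(gene_map[records$event_id])
  if (length(tested) == 0) return(NaN)
  hit <- unique(gene_map[filter_events(records, min_abs_dpsi, max_fdr)$event_id])
  length(hit) / length(tested)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment controlling the false discovery rate, delegated to
#' [stats::p.adjust()] after validating the input. The result is invariant to
#' input order and monotone non-decreasing in p after sorting.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (`NA`s propagate).
#' @return Adjusted values of the same length.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop_arg("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
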