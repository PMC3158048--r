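#!/usr/bin/env Rscript
# Build the synthetic two-condition study: an annotation with ten planted
# events of each of the eight types plus single-isoform control genes, a
# random genome, planted per-event PSI and per-gene expression for an
# "epithelial" and a "mesenchymal" condition, and 39-bp read placements at
# 2e5 reads per condition. Everything downstream reads the files written
# here.

suppressPackageStartupMessages(library(psikit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

per_type <- stats::setNames(rep(10L, 8),
                            c("SE", "RI", "MXE", "A5SS", "A3SS", "AFE", "ALE",
                              "TandemUTR"))
sim <- simulate_annotation(120, per_type, seed = seed)
write_gtf(sim$transcripts, "results/sim/annotation.gtf")
Biostrings::writeXStringSet(sim$genome, "results/sim/genome.fa")

event_genes <- sim$truth$events$gene_id
set.seed(seed + 1)
psi_epi <- stats::setNames(runif(length(event_genes), 0.15, 0.85), event_genes)
changed <- sample(c(rep(TRUE, 40), rep(FALSE, length(event_genes) - 40)))
psi_mes <- pmin(pmax(psi_epi + ifelse(changed, 0.35 *
                                        sample(c(-1, 1), length(event_genes),
                                               TRUE), 0), 0.02), 0.98)
all_genes <- sim$truth$genes$gene_id
expr_epi <- stats::setNames(rlnorm(length(all_genes), 0, 0.5), all_genes)
de_genes <- sample(setdiff(all_genes, event_genes), 20)
expr_mes <- expr_epi
expr_mes[de_genes[1:10]] <- expr_mes[de_genes[1:10]] * 5
expr_mes[de_genes[11:20]] <- expr_mes[de_genes[11:20]] / 5

for (cond in c("epi", "mes")) {
  psi <- if (cond == "epi") psi_epi else psi_mes
  expr <- if (cond == "epi") expr_epi else expr_mes
  pl <- simulate_reads(sim, 2e5, psi = psi, expr = expr,
                       seed = seed + ifelse(cond == "epi", 2, 3))
  write_placements_bed(pl, sprintf("results/sim/reads_%s.bed", cond))
  message(sprintf("%s condition: %d reads", cond, n_reads(pl)))
}

truth <- data.frame(gene_id = event_genes, type = sim$truth$events$type,
                    psi_epi = psi_epi, psi_mes = psi_mes,
                    delta_psi = psi_mes - psi_epi, changed = changed)
write.table(truth, "results/sim/truth_events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = all_genes, expr_epi = expr_epi,
                       expr_mes = expr_mes,
                       de_planted = all_genes %in% de_genes),
            "results/sim/truth_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("planted ", sum(changed), " differential splicing events and ",
        length(de_genes), " 5-fold expression changes")
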