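#!/usr/bin/env Rscript
# Differential expression (Audic-Claverie + 3-fold filter) and differential
# splicing (per-event Fisher + BH FDR with |dPSI| thresholds), compared
# against the planted truth, plus the per-type summary table at both
# threshold pairs.

suppressPackageStartupMessages(library(psikit))

pt_epi <- read.table("results/psi_epi.tsv", header = TRUE, sep = "\t")
pt_mes <- read.table("results/psi_mes.tsv", header = TRUE, sep = "\t")
ds <- diff_splicing(pt_epi, pt_mes)
write.table(ds, "results/diff_splicing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- do.call(rbind, lapply(split(ds, ds$type), function(d) {
  data.frame(type = d$type[1], tested = nrow(d),
             dpsi10_fdr05 = nrow(filter_events(d, 0.1, 0.05)),
             dpsi30_fdr05 = nrow(filter_events(d, 0.3, 0.05)))
}))
write.table(summ, "results/diff_splicing_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE)

truth <- read.table("results/sim/truth_events.tsv", header = TRUE, sep = "\t")
cat_map <- read_event_catalog("results/event_catalog.tsv")
gene_map <- stats::setNames(cat_map$gene_id, cat_map$event_id)
hits <- filter_events(ds, 0.1, 0.05)
hit_genes <- unique(gene_map[hits$event_id])
sens <- mean(truth$gene_id[truth$changed] %in% hit_genes)
fdp <- if (nrow(hits)) mean(!(hit_genes %in% truth$gene_id[truth$changed])) else 0
message(sprintf("splicing: %d calls, sensitivity %.2f, FDP %.2f", nrow(hits),
                sens, fdp))
message(sprintf("gene-level fraction (|dPSI|>=0.1, FDR<=0.05): %.3f",
                gene_level_fraction(ds, gene_map, 0.1, 0.05)))

ge <- read.table("results/rpkm_epi.tsv", header = TRUE, sep = "\t")
gm <- read.table("results/rpkm_mes.tsv", header = TRUE, sep = "\t")
de <- diff_expression(ge[, c("gene_id", "count", "length")],
                      gm[, c("gene_id", "count", "length")])
write.table(de, "results/diff_expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gt <- read.table("results/sim/truth_genes.tsv", header = TRUE, sep = "\t")
message(sprintf("expression: %d significant (up %d / down %d); planted 20",
                sum(de$significant), sum(de$direction == "up"),
                sum(de$direction == "down")))
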