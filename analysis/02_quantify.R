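#!/usr/bin/env Rscript
# Derive the event catalog from the simulated annotation and quantify PSI and
# RPKM in both conditions from the BED read placements.

suppressPackageStartupMessages(library(psikit))
dir.create("results", showWarnings = FALSE)

tx <- load_annotation("results/sim/annotation.gtf")
ev <- derive_events(tx)
write_event_catalog(ev, "results/event_catalog.tsv")
write_events_gff3(ev, "results/event_catalog.gff3")
message("derived ", nrow(ev), " events: ",
        paste(sprintf("%s=%d", names(table(ev$type)), table(ev$type)),
              collapse = ", "))

ce <- constitutive_exons(tx)
for (cond in c("epi", "mes")) {
  pl <- read_placements_bed(sprintf("results/sim/reads_%s.bed", cond))
  pt <- psi_table(ev, count_event_reads(ev, pl))
  write_psi_table(pt, sprintf("results/psi_%s.tsv", cond))
  gc <- count_gene_reads(ce, pl)
  gc$rpkm <- compute_rpkm(gc$count, gc$length, n_reads(pl))
  write.table(gc, sprintf("results/rpkm_%s.tsv", cond), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d/%d events with defined PSI, median gene RPKM %.0f",
                  cond, sum(!is.na(pt$psi)), nrow(pt), median(gc$rpkm)))
}
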