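#!/usr/bin/env Rscript
# Flanking-region motif analysis: extract the four 250-nt intronic flanks of
# the skipped exons from the synthetic genome, then demonstrate pentamer
# enrichment and CLIP-style overlap statistics on flank sets with a planted
# RBFOX motif (the random genome itself carries no biological motifs).

suppressPackageStartupMessages(library(psikit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

tx <- load_annotation("results/sim/annotation.gtf")
# re-derive rather than read the catalog TSV: flank extraction needs the SE
# flanking-exon coordinates, which are catalog metadata not in the signature
ev <- derive_events(tx)
genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
names(genome) <- sub(" .*", "", names(genome))
fl <- extract_flanks(ev, genome)
write.table(fl, "results/se_flanks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("extracted ", nrow(fl), " flank regions from ",
        length(unique(fl$event_id)), " SE events")

fs <- simulate_flank_sets(100, 300, fg_rate = 0.5, bg_rate = 0.05,
                          seed = seed + 10)
en <- pentamer_enrichment(fs$fg, fs$bg)
write.table(en[order(en$region, en$element, en$fdr), ],
            "results/pentamer_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cls <- en[en$region == "downstream_intron" & en$element == "I5", ]
top <- cls[order(cls$fdr), ][1:5, c("pentamer", "fg_count", "bg_count",
                                    "p_hyper", "fdr", "family")]
message("top pentamers in the planted class (downstream intron, I5):")
print(top, row.names = FALSE)

ds <- read.table("results/diff_splicing.tsv", header = TRUE, sep = "\t")
truth <- read.table("results/sim/truth_events.tsv", header = TRUE, sep = "\t")
gene_map <- stats::setNames(ev$gene_id, ev$event_id)
universe <- ds$event_id
set.seed(seed + 11)
truly <- universe[gene_map[universe] %in% truth$gene_id[truth$changed]]
flagged <- union(truly[runif(length(truly)) < 0.6],
                 sample(setdiff(universe, truly),
                        ceiling(0.1 * length(universe))))
fg <- filter_events(ds, 0.1, 0.05)$event_id
ovr <- overlap_enrichment(fg, flagged, universe)
message(sprintf(
  "CLIP-style overlap: %d/%d regulated events flagged (universe %d), p = %.3g",
  ovr$overlap, ovr$n_fg, ovr$n_universe, ovr$p))
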