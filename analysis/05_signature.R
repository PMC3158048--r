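#!/usr/bin/env Rscript
# Signature analyses: two-class panel clustering with permutation
# significance, cross-dataset coherence, and event-level correlation
# clustering with bootstrap branch support.

suppressPackageStartupMessages(library(psikit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

pp <- simulate_panel(12, 12, 300, effect_dpsi = 0.3, noise_sd = 0.1,
                     seed = seed + 20)
write_panel_tsv(pp$panel, "results/panel.tsv")
cs <- cluster_samples(pp$panel, pp$labels)
write_dendrogram_newick(cs$hclust, "results/panel_dendrogram.nwk")
message("two-class panel: ", cs$misclassifications,
        " misclassified of ", ncol(pp$panel), " samples")

big <- simulate_panel(12, 12, 5000, effect_dpsi = 0.3, noise_sd = 0.1,
                      affected_fraction = 30 / 5000, seed = seed + 21)
fg <- big$truth$event_id[big$truth$affected]
rp <- randomized_cluster_pvalue(big$panel, fg, big$labels, n_perm = 999,
                                seed = seed + 22)
message(sprintf(
  "randomized clustering: observed %d misclassifications, p = %.4g",
  rp$observed, rp$p))

cd <- simulate_coherence_deltas(2000, 0.2, seed = seed + 23)
co <- coherence(cd$a, cd$b)
message(sprintf("coherence with 20%% sign flips: %d/%d = %.3f",
                co$n_coherent, co$n_compared, co$fraction))

# small clinical-style panel: 4 epithelial events on a shared latent factor,
# 2 anti-correlated mesenchymal events, 40 tumors + 6 reference samples
set.seed(seed + 24)
n_t <- 40
f <- rnorm(n_t)
panel6 <- rbind(
  t(vapply(1:4, function(i) pmax(0.5 + 0.25 * f + rnorm(n_t, 0, 0.12), 0.01),
           numeric(n_t))),
  t(vapply(1:2, function(i) pmax(0.5 - 0.25 * f + rnorm(n_t, 0, 0.12), 0.01),
           numeric(n_t)))
)
rownames(panel6) <- c("ENAH_like", "SLC37A2_like", "FLNB_like", "MBNL1_like",
                      "MLPH_like", "ARHGEF11_like")
colnames(panel6) <- sprintf("IDC%02d", seq_len(n_t))
ref <- matrix(pmax(0.5 + rnorm(6 * 6, 0, 0.12), 0.01), nrow = 6,
              dimnames = list(rownames(panel6), sprintf("FA%d", 1:6)))
norm <- normalize_to_reference(cbind(ref, panel6), colnames(ref))
ec <- event_correlation_cluster(norm, n_boot = 1000, seed = seed + 25)
write.table(round(ec$cor, 3), "results/event_correlation.tsv", sep = "\t",
            quote = FALSE)
write_dendrogram_newick(ec$phylo, "results/event_dendrogram.nwk")
grp <- stats::cutree(ec$hclust, k = 2)
message("event clusters: ",
        paste(sprintf("%s=%d", names(grp), grp), collapse = " "))
message("bootstrap branch support: ",
        paste(sprintf("%.2f", ec$support), collapse = " "))
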