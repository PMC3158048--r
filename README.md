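# psikit

Alternative-splicing programs — coordinated changes in exon inclusion across
hundreds of genes — distinguish cell states such as the epithelial and
mesenchymal phenotypes of breast cancer, and can classify tumors and cell
lines where expression markers are ambiguous. `psikit` is an R package and
analysis workflow for measuring such a program from two-condition RNA-seq:
it derives the eight classical alternative-isoform event types from a
transcript annotation, quantifies exon inclusion from read placements,
tests differential expression and differential splicing, scores regulatory
motif and CLIP-cluster enrichment around regulated exons, and evaluates the
resulting splicing signature as a sample classifier. A seeded synthetic-data
generator with planted ground truth makes every stage testable end to end
without any external download.

## The statistics at the core

**Percent spliced in.** For an event with inclusion/exclusion isoform
signatures, inclusion is estimated from read densities,

Ψ̂ = d_inc / (d_inc + d_exc),  d = (supporting reads) / (mappable read-start positions),

where a junction offers `r − 2·overhang + 1` start positions (r = read
length, default 39 nt, overhang 4 nt) and an exon body of length L offers
`max(L − r + 1, 1)`. Tandem 3′ UTRs use the variant
Ψ̂ = d_extension / d_core, clamped to [0, 1].

**Differential expression.** Per gene, the Audic–Claverie exact test
compares counts (x, y) at library sizes (N₁, N₂): conditional on n = x + y,
y ~ Binomial(n, N₂/(N₁+N₂)); the two-sided p sums all outcomes no more
probable than the observed one. Significance requires BH-adjusted p ≤ 0.05
and an RPKM fold change ≥ 3.

**Differential splicing.** Per event, a two-sided Fisher exact test on the
2×2 inclusion/exclusion × condition count table, BH-adjusted across events;
regulated sets use |ΔΨ| ≥ 0.1 (or 0.3) at FDR ≤ 0.05, with
ΔΨ = Ψ(condition 2) − Ψ(condition 1).

**Motifs and signatures.** Pentamer enrichment in the four 250-nt intronic
flanks of regulated skipped exons is scored by an upper-tail hypergeometric
test over pooled sequence windows (BH within region class) and annotated
with splicing-factor families (RBFOX, ESRP, MBNL, CELF, hnRNP F/H, PTB,
hnRNP L). Sample classification uses average-linkage clustering on
1 − Pearson with a randomization p-value; event structure uses pairwise
Pearson correlation with ordinary-bootstrap branch support.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads the previous one's outputs from `results/`.

```sh
Rscript analysis/01_simulate.R 1      # annotation + genome + reads, planted truth
Rscript analysis/02_quantify.R        # event catalog, PSI and RPKM tables
Rscript analysis/03_differential.R    # splicing + expression tests vs truth
Rscript analysis/04_motifs.R 1        # flank extraction, pentamer + overlap enrichment
Rscript analysis/05_signature.R 1     # clustering, permutation p, coherence
```

With seed 1 the workflow prints, among other things:

```
derived 80 events: A3SS=10, A5SS=10, AFE=10, ALE=10, MXE=10, RI=10, SE=10, TandemUTR=10
epi: 80/80 events with defined PSI, median gene RPKM 17691
splicing: 38 calls, sensitivity 0.95, FDP 0.00
expression: 20 significant (up 10 / down 10); planted 20
 pentamer fg_count bg_count      p_hyper          fdr family
    UGCAU       73       90 3.117874e-08 6.385407e-05  RBFOX
    GCAUG       73       94 1.043066e-07 1.068099e-04  RBFOX
two-class panel: 0 misclassified of 24 samples
randomized clustering: observed 0 misclassifications, p = 0.003
coherence with 20% sign flips: 1602/2000 = 0.801
```

Reading this: all 80 planted events (ten per type) are re-derived exactly
from the simulated GTF; 38 of the 40 planted ΔΨ = ±0.35 events pass the
|ΔΨ| ≥ 0.1, FDR ≤ 0.05 filter with no false calls; all 20 planted 5-fold
expression changes are recovered with correct direction; the two pentamers
contained in the planted RBFOX motif UGCAUG dominate the planted flank
class; the planted 24-sample panel classifies perfectly and its signature is
significant against 999 random event sets; and a 20% sign-flip rate yields
the expected 80% cross-dataset coherence.

## Layout

```
R/                  package implementation (events, quant, diff, motifs,
                    signature, simulate, I/O)
analysis/           numbered workflow drivers (thin, narrative)
scripts/acceptance.R  end-to-end recomputation, JSON output
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, assumptions, design choices
inst/extdata/       motif family pattern table (editable data)
```
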