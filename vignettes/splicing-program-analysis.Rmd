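---
title: "Quantifying an alternative-splicing program from two-condition RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying an alternative-splicing program from two-condition RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

psikit implements the computational core of a classical two-condition
alternative-splicing study — for example an epithelial cell population before
and after an induced epithelial-to-mesenchymal transition (EMT), profiled by
single-end short-read RNA-seq with one library per condition. This vignette
explains the models and procedures, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the problem left the design open.

## The event catalog

Eight classical alternative-isoform event types are derived from transcript
annotation by exhaustive pairwise comparison of each gene's transcripts:
skipped exons (SE), retained introns (RI), mutually exclusive exons (MXE),
alternative 5' and 3' splice sites (A5SS/A3SS), alternative first and last
exons (AFE/ALE), and tandem 3' UTRs. Every event carries two *isoform
signatures* — sets of segments unique to each isoform. A segment is an exon
body, a splice junction (donor/acceptor coordinate pair) or a UTR extension.
For an SE event the inclusion signature is the alternative exon body plus its
two flanking junctions, and the exclusion signature is the single skipping
junction; the other types are handled uniformly through the same segment
abstraction.

Two design points were genuinely open:

* **Classification precedence.** One transcript pair can match several
  patterns over one locus. The catalog resolves these per pair in the order
  RI > MXE > SE > A5SS/A3SS > AFE/ALE > TandemUTR. A consequence worth
  knowing: alternative terminal exons that overlap and share a splice site
  are classified A5SS/A3SS, and AFE/ALE require non-overlapping terminal
  exons; terminal exons that share their splice-proximal boundary but differ
  in 3' length are tandem UTRs.
* **De-duplication.** Events induced by multiple transcript pairs are merged
  on (type, chromosome, strand, exact segment coordinates). Events are *not*
  merged across genes.

Coordinates are 1-based inclusive throughout, the GTF/GenomicRanges
convention; BED input and output convert at the boundary. All
"upstream/downstream" and "5'/3'" vocabulary is transcript-oriented, so
minus-strand events mirror genomic order.

## PSI from read densities

The fraction of a gene's transcripts including the alternative element —
percent spliced in, $\Psi$ — is estimated from *read densities*:

$$\hat\Psi = \frac{d_{inc}}{d_{inc} + d_{exc}},\qquad
  d = \frac{\#\text{reads supporting the signature}}
           {\#\text{distinct mappable read-start positions}}$$

A junction with read length $r$ and minimum overhang $o$ (default 4 nt)
offers $r - 2o + 1$ start positions; an exon-body segment of length $L$
offers $\max(L - r + 1,\,1)$. A read supports a junction when two consecutive
blocks end/start exactly at the donor/acceptor with at least $o$ bases on
each side; it supports a body segment when the whole read lies inside the
segment. The whole-read rule matters: counting any block that falls inside a
body segment would also capture junction-straddling reads whose anchor is
shorter than the overhang, reads that the position denominator excludes, and
the estimator would be biased upward. With the whole-read rule the set of
countable reads is exactly the set of enumerated start positions (the test
suite verifies this by exhaustively tiling every transcript position), and
$\hat\Psi$ is consistent.

Tandem 3' UTRs use a variant: the distal (long) isoform contains everything
the proximal isoform does, so the shared core cannot be an exclusive
signature. Instead $\hat\Psi = d_{ext}/d_{core}$, clamped to $[0,1]$ — the
fraction of transcripts reading through to the distal site.

$\Psi$ is *undefined* (`NA`), not zero, when no read supports either
isoform; undefined events are dropped from downstream testing rather than
shrunk toward an arbitrary value.

Gene expression uses RPKM over each gene's constitutive exons (the per-base
intersection of its transcript footprints):
$\mathrm{RPKM} = c / (L/10^3) / (N/10^6)$ for $c$ reads on $L$ constitutive
bases in a library of $N$ mapped reads.

## Differential tests

**Expression.** Two libraries, one per condition, are compared per gene with
the Audic–Claverie exact statistic. Under a flat prior on the common
concentration, the joint probability of counts $(x, y)$ at library sizes
$(N_1, N_2)$ is proportional to $\binom{x+y}{y} p^x q^y$ with
$p = N_1/(N_1+N_2)$; conditioning on the total $n = x+y$ gives
$y \sim \mathrm{Binomial}(n, q)$. The two-sided p-value sums all outcomes
whose point probability does not exceed the observed one, computed in log
space, and is exactly symmetric under exchanging the two libraries. A gene is
called differentially expressed when its Benjamini–Hochberg-adjusted p is at
most $\alpha = 0.05$ **and** its RPKM ratio is at least 3-fold in either
direction. Fold changes against a zero denominator are capped at $2^{15}$ for
reporting.

**Splicing.** Per event, the 2x2 table of inclusion/exclusion read counts
against condition is tested with a two-sided Fisher exact test, followed by
Benjamini–Hochberg adjustment across events; regulated sets are
$|\Delta\Psi| \ge 0.1$ (or 0.3) at FDR $\le 0.05$, both thresholds
inclusive, with $\Delta\Psi = \Psi_{cond2} - \Psi_{cond1}$ and the sign
giving the direction label (condition-1/epithelial inclusion when negative).
With a single library per condition the reads are the sampling units; this
is exact for the sequencing noise but anti-conservative for biological
inference across replicates, and is documented as such.

## Motif and overlap enrichment

For regulated skipped exons the four 250-nt intronic regions flanking the
alternative exon (donor-proximal I5 and acceptor-proximal I3 of the upstream
and downstream introns, transcript-oriented) are extracted; introns shorter
than 500 nt are split at the midpoint so I5 and I3 never overlap (the
acceptor side receives the middle base of an odd-length intron). All
overlapping pentamers are counted with step 1; windows containing ambiguous
bases are skipped. Enrichment of each pentamer in a foreground set (regulated
exons) over a background set (unchanged exons: FDR > 0.5 and
$|\Delta\Psi| < 0.05$ with both isoforms detected, configurable) is scored
with an upper-tail hypergeometric test whose population pools foreground and
background windows; FDR is controlled within each region class. Pooling
windows into one hypergeometric population (rather than treating the
background rate as a fixed binomial rate) was an open choice; the pooled
form is exact under the null that foreground status is unrelated to pentamer
occurrence.

Pentamers are annotated with splicing-factor families from a pattern table
shipped as data (`extdata/motif_families.tsv`): RBFOX (GCAUG core), hnRNP
F/H (G runs), MBNL (YGCY), CELF (UG/GU), PTB (CU-rich), hnRNP L (CA-rich),
ESRP (UGG/GU-rich), first match in table order, otherwise "Other". G-runs
precede the ESRP pattern so that GGGG-containing words annotate as hnRNP
F/H. The table is data precisely so users can reorder or extend it.

Overlap of a regulated event set with an annotated set (e.g. events bearing
CLIP clusters of a splicing factor, computed over the event's two introns
plus alternative exon, optionally widened) uses the same upper-tail
hypergeometric form over event counts.

## Signature analyses

Samples are clustered on the correlation distance $1 - r$ (Pearson) with
average (UPGMA) linkage — the linkage was unstated in the source material
and UPGMA is the conventional choice for correlation matrices — and cut into
two groups at the top split. Misclassification against two-class labels is
minimized over the two label-to-cluster mappings. Significance of a
signature's classification uses a randomization procedure: random event sets
of the same size are drawn without replacement from the full panel,
clustered, and scored; the add-one estimator
$p = (1 + \#\{perm \le obs\})/(n_{perm}+1)$ never returns zero. Because the
misclassification count is a small discrete statistic with heavy ties, this
p-value is super-uniform (conservative) under the null — its null mean is
well above 0.5 — which is the safe side of calibration; the tests check
validity one-sidedly.

A point that matters when designing such a check: the randomization draws
come from the full panel, signature rows included. If the separating events
make up a large share of the panel, random draws separate the classes too
and the p-value is honestly large. The significance analyses therefore plant
the signature as a small minority (30 events in a 5,000-event universe,
~0.6%), which is the regime the procedure is meant for — a few hundred
signature events against a many-thousand-event background.

Cross-dataset *coherence* is the fraction of shared events whose inclusion
change agrees in sign between two datasets (zero changes excluded).
Event-level structure in clinical-style panels uses pairwise-complete
Pearson correlation between events (pairs with fewer than three complete
observations are dropped), after normalizing each event to the mean of
designated reference samples; branch confidence is the ordinary bootstrap
proportion over resampled samples (via `ape`). This is a deliberate
simplification relative to multiscale-bootstrap AU p-values: ordinary
bootstrap support is biased low for deep branches but requires no scaling
machinery and is directly interpretable.

## The synthetic-data generator

Every stage is exercised by seeded generators, pure functions of their
arguments:

* `simulate_annotation()` builds non-overlapping two-transcript genes on one
  synthetic chromosome, each realizing one event type with minimal geometry
  (150-nt flanking exons, 120-nt alternative exons, 60-nt alternative
  splice-site extensions, 200+250-nt tandem UTR core/extension, introns
  drawn from 300–1000 nt), plus single-isoform control genes; strands
  alternate. The standard study fixture uses 80 event genes (ten per type)
  plus 40 controls at 2e5 reads per condition, which puts roughly 200+
  informative reads on each event and a PSI sampling error near 0.03.
* `simulate_reads()` draws 39-nt single-end reads uniformly over transcript
  positions, Poisson totals per gene, isoform choice proportional to
  $\Psi \times$ (fragment positions) so that per-position coverage is
  proportional to molar isoform concentration — the assumption behind the
  density estimator. Weighting by $\Psi$ alone would under-cover the longer
  isoform and bias $\hat\Psi$; the generator emulates what real libraries
  do, namely yield fragments in proportion to transcript length.
* `simulate_event_counts()` simulates at the count level (Poisson per side)
  for statistical calibration studies at depths where full read simulation
  adds nothing; `simulate_panel()`, `simulate_flank_sets()`,
  `simulate_expression_counts()` and `simulate_coherence_deltas()` plant
  panel structure, motifs, fold changes and sign-flips with recorded truth.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: sequencing errors and mismatch handling,
mappability variation, positional/fragmentation bias, overdispersion across
biological replicates (counts are Poisson; a single library per condition
was the study design), incomplete or wrong annotation, and overlapping
genes. Conclusions about estimator consistency and test calibration are
conditional on uniform coverage and a correct catalog.

## Numerical and degenerate-input choices

* $\Psi$ undefined (`NA`) when both signatures have zero reads; such events
  are dropped from differential testing with a notice, never imputed.
* All-zero 2x2 tables are skipped; identical tables give $p = 1$ exactly.
* Fold changes are computed on RPKM with no pseudocount; infinite ratios are
  capped at $2^{15}$.
* Flank truncation at the intron midpoint guarantees I5 and I3 never
  overlap; panel values are clamped to $[0,1]$ after noise.
* Constant sample or event profiles make Pearson correlation undefined;
  samples raise an error naming the sample, events are excluded with a
  notice.
* Hypergeometric p-values are floored at the smallest positive double and
  capped at 1; permutation p-values use the add-one estimator.
* Problem sizes used by the acceptance analyses: 200 events at 1e4
  informative reads for PSI recovery; the full (x, y) grid with x+y <= 50 at
  three library-size ratios for the exact-test oracle; 2,000 events for null
  calibration; 100 replicates for motif and classification recovery; 999
  permutations for the randomization p. These sizes give the property checks
  stable margins while keeping the full suite in the minutes range on one
  CPU.

## Known limitations

* One library per condition means the splicing test quantifies sequencing
  noise only; replicate-aware dispersion modeling is out of scope.
* The catalog derives events only from annotated transcripts; novel
  junctions are not discovered from reads.
* Bootstrap branch support is not an AU p-value; deep branches are
  under-supported.
* The motif family table is a coarse substring classifier, intended for
  labeling enrichment output, not for binding-site prediction.
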