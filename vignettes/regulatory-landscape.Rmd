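---
title: "Mapping a regulatory landscape from ATAC fragments and histone marks"
author: "regland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a regulatory landscape from ATAC fragments and histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

## The problem

In organisms where several phenotypes arise from one genome — the motivating
case is an insect brain with three adult morphs (labelled Q, W and D
throughout) — phenotype identity is maintained largely by *cis*-regulatory
elements: promoters, enhancers and insulators whose accessibility and
chromatin state differ between morphs. `regland` reconstructs that
regulatory landscape from four data types:

1. **ATAC-seq fragments** — paired-end sequencing of transposase-accessible
   chromatin. Fragment length carries structure: sub-nucleosomal fragments
   (0–100 bp) come from nucleosome-free regions (NFRs), while ~200 bp and
   ~400 bp fragments wrap one and two nucleosomes.
2. **Histone-PTM ChIP peaks** for H3K4me1, H3K4me3, H3K27ac and H3K27me3,
   whose combinations ("chromatin states") distinguish active promoters,
   enhancers and repressed chromatin.
3. **A gene annotation** (GFF3) supplying gene models, TSSs and the derived
   feature sets (promoter, UTRs, exons, introns, intergenic).
4. **Gene-level expression counts** to link accessibility to transcription.

The pipeline proceeds: fragment-size classification → NFR peak calling →
replicate consensus → chromatin-state decomposition → TSS/non-TSS element
classification → TF footprinting → differential occupancy → a directed
TF–TF network.

## Fragment classes and NFR peak calling

Fragments are partitioned by length into `nfr` (0–100 bp inclusive), `mono`
(150–247 bp), `di` (315–473 bp) and `unassigned` (the gaps and everything
above 473 bp). The gaps are deliberate: lengths between the modes are
ambiguous and are left out rather than force-assigned.

NFR peaks are called from the `nfr` class with a windowed scan (window 200
bp, step 50 bp). Each window's fragment-midpoint count is tested against a
Poisson null whose rate is the maximum of the genome-wide rate and local
rates estimated in 1 kb and 10 kb windows centred on the window — the local
background idea of MACS-family callers, restated in closed form so that it
is exactly checkable against a brute-force per-window enumeration.
Benjamini–Hochberg correction is applied over all windows; touching
significant windows merge into peaks, and the summit is the bp of maximal
fragment coverage. This caller is deliberately *not* a port of any external
tool: it is a transparent statistical reimplementation whose behaviour is
fully specified here, so numerical parity with external callers is not a
goal. For real data the effective genome size (2.7×10⁸ bp for the honey-bee
genome) replaces the summed chromosome lengths in the genome-wide rate.

Replicate consensus keeps peaks overlapping (≥1 bp) a peak in the other
replicate and merges each overlap group into its union span. Differential
accessibility between phenotypes uses median-of-ratios normalization and a
per-peak two-sided z-test on log2 normalized counts with a pooled-variance
floor of 0.01. The floor keeps the test defined at two replicates per group
and makes results deterministic; a full negative-binomial GLM would add
power at high replication but is deliberately out of scope.

## Chromatin states

The four consensus mark sets are cut at every peak boundary into disjoint
segments, each labelled with the exact subset of covering marks — the
bp-resolved analogue of an UpSet decomposition. Per-state percentages are
reported both over segment counts and over bp, because the two conventions
answer different questions and the choice is not obvious a priori; both are
emitted. Feature enrichment is
`log2((state bp in feature / state bp) / (feature bp / genome bp))` with a
1 bp pseudocount.

Elements are classified `tss` when they overlap the ±200 bp window around
any annotated TSS and `non_tss` otherwise; the same 200 bp defines the
promoter feature, so the two definitions cannot drift apart (both are
configurable through one parameter). Each NFR is assigned the mark subset
covering its summit (midpoint when the caller recorded none): a point
lookup guarantees a unique state per NFR where an any-overlap rule would
not. Mark co-occurrence (e.g. H3K4me3 with H3K27ac) is tested with a
two-sided Fisher exact test computed by hypergeometric enumeration, with
the sample odds ratio `(n11·n00)/(n10·n01)`.

## Footprinting

TF binding sites are found by scanning NFR regions on both strands with
log2-odds PWMs (`log2(((count + 0.8·bg)/(col total + 0.8))/bg)`, the JASPAR
pseudocount convention) at a threshold of 0.8 × the motif's maximum
attainable bits. Overlapping same-motif hits keep the best score.

Cut sites (fragment ends shifted +4/−5, the standard Tn5 offsets; the study
data leave them unstated) are corrected for sequence bias with a k-mer
model (k = 6): each position's expected relative cut rate is the cut count
on its k-mer divided by the k-mer's genomic frequency, normalized to
frequency-weighted mean 1; the corrected track is observed/(expected +
0.01). The footprint score of a site is

FS = log2((mean corrected signal over two 20 bp flanks + 0.1) /
(mean over the motif core + 0.1)),

positive when cuts are depleted inside the core — the signature of a bound
factor. This flank-vs-core log-ratio with k-mer correction is this
package's own transparent formulation; published footprinting tools are
cited in the field without printed formulas, so no parity claim is made.
Sites are called bound at a threshold chosen by Otsu's between-class
variance criterion on the FS distribution (the bound/unbound mixture is
strongly bimodal on data with real footprints), with a quantile rule and a
manual override as alternatives. Occupancy of a motif is the percentage of
its sites bound, restricted to sites inside NFR peaks; whether "occupancy"
should instead mean the fraction of NFRs containing a bound site is
ambiguous in the field, so that quantity is emitted as an optional column.

Differential occupancy between phenotypes compares mean FS per motif over a
shared site set. The null is built from 100 motif-blind random subsets of
the same size drawn across all shared sites, giving a z-score and a
two-sided normal p, BH-corrected across motifs. This background-subset
construction is calibrated: under null simulations the type-I error at
α = 0.05 is within Monte-Carlo error of nominal (the acceptance suite
verifies this over 500 runs).

## The TF–TF network

An edge A→B is created when a bound site of motif A lies in the gene
encoding TF B or in its promoter window, defined for network purposes as
−2 kb to +200 bp around the TSS (strand-oriented). This window is a
distinct named constant from the 200 bp element-classification window —
the two definitions serve different purposes and must not collide. Edges
are classed `tss` (all supporting sites in the window), `non_tss` (all
within the gene body) or `both`, rather than forcing a promoter-only
definition, because element-level evidence supports both kinds of
regulation. Paralogous motifs mapping to one gene merge into a single node
with concatenated ids. Root-anchored subnetworks are extracted by
breadth-first closure with a visited set (cycles terminate) and
deterministic ordering.

## The synthetic-data generator

`generate_genome()` plus the three simulators build a miniature dataset
with planted ground truth, written alongside a manifest that downstream
tests read back. The defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 2 Mb over 4 chromosomes | small enough for minutes-scale runs, large enough for stable k-mer statistics (4⁶ k-mers are each seen ~500×) |
| genes | 200 (3 exons, 2 introns, 150 bp UTRs) | intron placement mirrors the intron-dominated element landscape of the motivating system |
| fragments/replicate | 4×10⁵ | gives NFR-class coverage ≈ 5 cuts/bp over planted NFRs, comparable per-bp depth to a deeply sequenced ATAC library after downscaling |
| length mixture | N(55,18) >0 / N(200,25) / N(400,35), weights 0.50/0.35/0.15 | reproduces the tri-modal fragment-size shape with nucleosome periodicity without modelling the full decay |
| planted NFRs | 150; 40% at TSSs; 72% of the rest intronic | echoes the observed predominance of intronic elements (>60% of non-TSS elements intronic by construction) |
| phenotype specificity | 20% of NFRs and 2 motifs phenotype-specific | gives the differential stages true positives of known identity |
| footprint depletion | cut rate ×0.25 over bound cores | the minimal mechanism a flank/core score detects; unbound planted sites receive no depletion and serve as negatives |
| ChIP noise | boundary jitter ≤20 bp; ~8 replicate-private false peaks | jitter is small relative to state width (400–1200 bp); false peaks are placed in replicate-private zones so consensus provably removes them |
| expression | NB, dispersion 0.1; +1 log2 for NFR genes | a clearly detectable but not degenerate link between accessibility and expression |

Motif instances are embedded into the genome sequence at the planted sites
(consensus bases, either strand), so the scanner genuinely rediscovers them;
the planted TF–TF edges are derived at generation time by a brute-force
(site × gene) double loop — independent of the package's network builder,
which is tested against it.

What the generator does **not** emulate: sequencing error and read-level
artefacts, mappability structure, copy-number and allelic effects,
Tn5 sequence preference (the bias model is validated against *synthetic*
bias, not a measured insertion profile), correlated replicate noise, and
any realistic motif information-content distribution. Passing the planted-
truth tests therefore demonstrates internal correctness of the inference
chain under a known generative model, not performance on real libraries.

## Numerical choices and degenerate inputs

- Coordinates are uniformly 0-based half-open; GFF3 (1-based inclusive) and
  `GRanges` conversions happen only at the I/O boundary.
- narrowPeak −log10 p/q columns become linear probabilities on read; `-1`
  sentinels become 1/`NA`.
- Zero fragments → an empty peak list (not an error); an all-equal
  footprint-score vector → an explicit error (no threshold exists); empty
  expression groups and all-zero samples are errors.
- Mann–Whitney p-values are exact by enumeration when both groups have ≤8
  tie-free values, otherwise normal approximation with continuity
  correction. The statistic reported is the U of the NFR group (pairs where
  the NFR gene exceeds the other).
- Otsu's threshold uses a 256-bin histogram; ties in motif-hit dedup break
  by score, then leftmost coordinate, then strand.
- All randomness flows from one root seed through named per-stage
  substreams (`seed_for`), so skipping a stage does not shift another
  stage's draws, and reruns are byte-identical.

## Problem sizes used by the checks

The test suite and acceptance script run the generator at its default
2 Mb / 4×10⁵-fragment conditions for single-run recovery, 100 seeded runs
for the occupancy and differential-occupancy rankings, 500 reduced-size
runs for the two calibration checks, and exhaustive oracles (brute-force
window enumeration on ≤50 kb, per-bp state labelling, all-window motif
scoring, hypergeometric and rank enumeration) for exactness checks. These
sizes were chosen so the full validation completes in minutes on one core
while leaving every statistical check adequately powered.

## Known limitations

- The peak caller has no control-library subtraction and no shifting-model;
  it is tuned for sharp sub-nucleosomal peaks.
- The differential accessibility z-test underestimates biological
  dispersion with many replicates; swap in a count GLM when replication
  allows.
- The bias model is blind to k-mers absent from the genome and to
  palindromic strand effects.
- Network edges are evidence of binding within a target gene's extent, not
  of regulation sign or causality.
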