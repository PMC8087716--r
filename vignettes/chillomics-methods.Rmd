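---
title: "Methods: multi-omic integration of chilling-stress responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic integration of chilling-stress responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillomics)
```

`chillomics` integrates three assays measured on the same two-condition
plant experiment — ATAC-seq for chromatin accessibility, RNA-seq for
transcript abundance, Ribo-seq for ribosome occupancy — into a joint
description of the chilling-stress response. This vignette explains the
statistical procedures, the choices behind them, and what the packaged
synthetic data can and cannot tell you about real data.

## Quantification and the differential kernel

Abundance is expressed as FPKM: `count * 1e9 / (length_nt *
library_size)`. For descriptive FPKM (`compute_fpkm()`) the library size
is the within-table column sum, which makes tables self-contained but can
differ from aligner-reported mapped-read totals; external totals can be
supplied. Translational efficiency is the ratio of condition-mean Ribo
FPKM to condition-mean RNA FPKM; it is *undefined* (never infinite) when
the RNA mean is below 1 FPKM, a filter that removes ratio blow-ups at
negligible expression.

Differential calling at each level (`diff_expression()`) uses a
deliberately transparent kernel: a two-sample Welch t-test on
`log2(FPKM + 1)` across the three replicates per condition, BH-FDR across
genes, and DEG thresholds of |fold change| ≥ 2 (boundary inclusive) with
FDR < 0.05. The fold change carries a pseudocount of 1 on both condition
means. A pooled-variance (classical Student) variant is available via
`equal_var = TRUE`; Welch is the default because equal variances across
conditions is an assumption we cannot check at n = 3.

Two points deserve emphasis:

- **Normalization.** Before the t-test, samples are scaled by
  median-of-ratios size factors (`estimate_size_factors()`) rather than
  raw column sums. When a large fraction of genes shifts — exactly the
  regime the synthetic benchmarks probe, with up to 80% of genes carrying
  ±3 log2 units — column-sum scaling transfers the shift into every null
  gene's fold change (8× up and 8× down do not cancel on the linear
  scale). The median across genes is robust as long as shifts are
  sign-balanced or affect a minority of genes. `normalization =
  "column_sums"` restores the naive behaviour.
- **Power at n = 3.** A per-gene Welch test at three replicates has few
  degrees of freedom; variance estimates are noisy and genuinely shifted
  genes can escape the FDR threshold when most of the transcriptome is
  null. Methods that share dispersion information across genes (NB GLMs,
  moderated t) are more powerful; the kernel here is pluggable precisely
  so the integration logic — the five-group partition, TE classes, target
  cross-checks — is independent of that choice.

The five-group partition (`classify_five_groups()`) is a deterministic
function of the two DEG calls: significant only at RNA → *transcription*;
only at Ribo → *translation*; both with the same sign →
*homodirectional*; both with opposite signs → *opposite*; neither →
*unchanged*. The partition is exhaustive and mutually exclusive by
construction. TE change classes use a plain two-fold rule on the TE ratio
(inclusive boundaries); no significance test is attached because the TE
ratio of ratios at n = 3 does not support a stable one.

## Ribosome footprints

Footprints are assigned to transcript categories (5′ UTR / CDS / 3′ UTR /
intron) by a P-site proxy: the 5′ end plus a fixed 12-nt offset along the
gene's strand (`assign_reads_to_features()`). Twelve nt is the
conventional offset for ~32-nt plant footprints; it is a parameter. Reads
outside annotated transcripts are dropped and counted separately, so
category fractions always sum to 1 over assigned reads. Footprint length
histograms report the mode with ties broken toward the smaller length.

## uORF discovery and characterization

`find_uorfs()` scans the spliced 5′ UTR (transcript orientation) for
every ATG in all three frames and extends each to the first in-frame stop
within the UTR. Candidates must span 60–450 nt *including* the stop
codon; the bounds are inclusive. ORFs without an in-frame stop before the
UTR end are discarded — overlap into the main ORF is deliberately out of
scope since only UTR sequence is scanned. Nested ATGs sharing a stop are
separate candidates. The scanner is validated against a brute-force
enumeration oracle on random UTRs.

A uORF is *translated* in a condition when its footprint FPKM (P-site
counts within the uORF, uORF length as feature length, total footprints
as library size), averaged over replicates, is at least 1 — the boundary
is inclusive. Calling is per condition; uORF TE divides the uORF's
footprint FPKM by the host gene's RNA FPKM.

Sequence stability is summarized as NMFE: folding energy divided by
sequence length. The default folding backend maximizes nested
Watson–Crick + GU pairs with hairpin loops of at least 3 nt (Nussinov
dynamic program in C++); its "energy" is minus the pair count, so NMFE
lies in [−0.5, 0] and is comparable *within* a run but not numerically
equal to thermodynamic energies. A ViennaRNA backend (`backend =
"rnafold"`) provides kcal/mol energies under the same sign contract when
the binary is available. The base-pair-maximization default was chosen
because it is deterministic, dependency-free and exactly testable against
exhaustive structure enumeration.

Normalized positional features divide by the UTR length: distance to the
CDS start is `(UTR_length − uORF_end) / UTR_length`, distance to the TSS
is `uORF_start / UTR_length`; both lie in [0, 1]. Class comparisons use
Welch t for scalar features and two-sample KS (asymptotic p) for TE
distributions across genes with no / one / multiple translated uORFs.

## THS analysis

A reproducible THS is the union of a connected chain of replicate peaks
containing at least one position covered by *every* replicate — a strict
reproducibility rule that discards anything supported by a subset of
replicates. The implementation (GenomicRanges coverage intersection) is
checked against a position-sweep oracle on random replicate
configurations.

Annotation classifies each THS by its midpoint with priority promoter >
exon > intron > distal intergenic, where the promoter is the 2-kb window
upstream of a TSS in the gene's orientation. The priority order resolves
midpoints that fall both in one gene's body and another's promoter; the
midpoint convention avoids fractional-overlap ambiguity for wide sites.
"Distal" means distal intergenic — outside every gene body and promoter
window; no additional distance cutoff is imposed because the 2-kb
promoter bound is the only proximal definition in play.

A cold-induced THS must (a) lack any ≥1 bp overlap with a CK reproducible
THS, (b) show |log2 FC| ≥ 1 in normalized counts (pseudocount 1), and
(c) reach p < 0.05 in a Welch t-test on log2-normalized counts across the
six samples. Counts are scaled by median-of-ratios factors for the same
composition-robustness reason as the expression kernel (plain totals are
the fallback for tables too small to estimate medians). In the packaged
pipeline the distal THSs are set aside before cold-induced testing and
analyzed separately — distal sites get target genes, proximal cold sites
feed the network — which mirrors treating long-range and proximal
regulation as distinct questions.

Distal targets follow the closest-downstream-gene rule: among genes whose
TSS lies downstream of the THS midpoint in the gene's own orientation,
the nearest by midpoint-to-TSS distance wins, with lexicographic gene-id
tie-breaks for determinism; if no downstream gene exists on the
chromosome the nearest gene by absolute TSS distance is the fallback. The
responsive fraction of targets is the share whose five-group label is not
*unchanged*. Set enrichment for target genes is a generic hypergeometric
upper-tail engine over user-supplied term maps; no pathway database ships
with the package.

## Motif scanning and the network

PWM scanning follows the FIMO model: probabilities floored at 1e-3 and
renormalized, log2 odds against a 0-order background (uniform by
default), both strands scanned. The p-value of a window score is the
*exact* tail of the score distribution over i.i.d. background sequence,
computed by dynamic programming on a score lattice with 0.005-bit bins —
window scores are integerized on the same lattice, so DP tails match
exhaustive window enumeration exactly, and the lattice is fine enough
that real-score tails agree within one bin per motif position. The
default hit threshold is p ≤ 1e-4. Note that under a uniform background
a motif shorter than 7 nt cannot reach 1e-4 (the best window has
probability 4^−L), so the packaged consensus motifs are 8-mers.

Motif enrichment in distal THSs uses Fisher's exact test on
sequences-with-hit counts (foreground vs background), two-sided by the
standard minimum-likelihood rule (sum of hypergeometric probabilities no
larger than the observed table's), BH-corrected across motifs. The
network layer emits one TF → target edge per (motif, THS) pair with a hit
and an assigned target, deduplicated to the best-scoring hit; exports are
edge-list TSV and GraphML with node types.

## The synthetic-data generator

The generator emulates the study design: three replicates in each of CK
and LT; negative-binomial counts with `Var = μ + μ²α`, α = 0.1 by
default; five response groups in the proportions observed in the
motivating data (11.06 / 6.88 / 5.87 / 0.70 / 75.49%), each affected gene
carrying ±3 log2 units; transcription-group genes shift RNA only (the
Ribo coupling of that group is 0 — the generative transcription→
translation relationship is unknown, so it is exposed as a choice rather
than asserted), translation-group genes shift Ribo only, homodirectional
and opposite genes shift both. Genes carrying a translated uORF have
their Ribo mean halved, encoding the repressive effect of uORF
translation on main-ORF output, and translated-uORF footprint rates
double under LT (enhanced uORF translation in the cold).

Baseline expression is parameterized directly as mean counts
(log-normal, median 200); at a few hundred genes per toy genome the
implied FPKM values run far above genome-scale values, which only makes
detection easier and leaves every threshold rule unchanged. Planted uORFs
are proper ORFs whose interior codons exclude ATG and stops, so the
scanner recovers exactly the planted candidate; background UTR sequence
is rejection-sampled (capped at 1000 attempts, then the UTR is shortened)
to contain no accidental candidate, which makes "no uORFs planted → none
found" exact. Background 5′-UTR footprints avoid all planted uORF
intervals, so untranslated uORFs receive no reads by construction — real
data has scanning ribosomes and noise there, so translated/untranslated
separation in real data is harder than in these benchmarks.

ATAC sites are planted with jittered boundaries in every replicate of
their condition (decoys appear in a strict subset and are kept clear of
planted sites), cold-induced sites are LT-only with an 8× count fold
change, and motif consensus strings are inserted into cold-induced site
sequences with probability 0.8. Distal sites are placed outside all gene
bodies and promoter windows. Default problem sizes (400 genes over 3
chromosomes, 50 000 footprints per sample, ~100 peaks per condition) keep
a full run in tens of seconds; benchmark configurations in the test suite
scale individual stages up (e.g. 1000 genes for group recovery, 10 000
genes for null calibration) or down as the property under test requires.

What passing these benchmarks shows: the pipeline's rules implement their
definitions exactly, planted structure at large effect sizes is recovered
with the stated sensitivity, and the null is controlled. What it does not
show: performance on real libraries with sequencing noise, isoform
complexity, mappability artifacts, or dispersion trends — none of which
the generator models.

## Numerical and edge-case conventions

- All internal coordinates are 0-based half-open; GFF3 (1-based closed)
  is converted at the boundary, BED passes through unchanged. TSSs are
  strand-aware single positions.
- Degenerate t-tests (zero variance in both groups) return p = 1 at equal
  means and p = 0 otherwise, so constant data never produces NaN.
- Zero-variance correlations are NA with a warning, never an error.
- Tie-breaks are always deterministic and documented: smaller footprint
  length for histogram modes, lexicographic gene ids for equidistant
  targets.
- Every stage of the generator draws from an RNG stream derived from the
  single config seed, so one seed fixes every emitted byte; the pipeline
  writes files with deterministic formatters to keep reruns
  byte-identical.

## Limitations

The differential kernel trades power for transparency (see above); the
TE-change rule is a fold-change rule, not a test; footprint P-site
assignment uses a fixed offset rather than per-read-length calibration;
uORF detection is ATG-only and excludes uORFs overlapping the main ORF;
the motif background is 0-order; and TF-family annotation of motifs is
user-supplied. The THS Venn counts overlap at ≥1 bp, with no reciprocal
fraction requirement.
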