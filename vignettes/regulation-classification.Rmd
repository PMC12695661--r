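---
title: "Classifying transcriptional regulation from nascent RNA labeling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional regulation from nascent RNA labeling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eureg)
```

## The measurement model

EU-seq profiles transcription by pulse-labeling nascent RNA (5-ethynyl
uridine, ~20 min), capturing labeled molecules and sequencing them. Unlike
steady-state RNA-seq, the signal reflects transcription during the labeling
window, so acute perturbations (degron depletion of an architectural
factor, coactivator inhibition) can be read out within hours, before
secondary effects accumulate.

Two features of such experiments shape the whole pipeline:

1. **Effects are subtle.** Acute depletion of a looping factor changes most
   target genes by 1.3–3-fold. Count-model significance tests at usual
   thresholds call almost nothing; a fold-change taxonomy with explicit
   reproducibility filtering is the workable alternative.
2. **Nascent signal extends only as far as Pol II travels.** A gene body
   accumulates labeled signal from the TSS outward at the elongation rate
   (roughly 1–2 kb/min). Counting the full annotation of a long gene would
   dilute the treated-window signal with unreachable sequence, so counting
   windows are capped at 30 kb, 90 kb and 240 kb for 30-, 60- and 120-min
   treatments and use the full gene otherwise. The cap is selected by the
   treatment duration alone; the labeling pulse is part of the rationale,
   not a separate parameter.

## Reference and windows

One representative transcript per gene is selected in two steps: isoforms
that are expressed in steady-state RNA (TPM > 2) *and* have an
active-promoter mark peak within 1 kb of their TSS are candidates, with the
longest candidate winning (a single promoter peak shared by several
isoforms resolves to the longest); genes without any supported isoform fall
back to their longest isoform, so every gene retains exactly one model.
Length ties break by lexicographically smallest transcript id — an
arbitrary but deterministic rule. "Within 1 kb" is measured summit-to-TSS,
because a summit is the one position every peak format guarantees; treating
it as any-overlap of the peak interval is a config-level variation left to
the caller by passing adjusted `peak_distance`.

Internally all intervals are 1-based closed `GRanges` (the Bioconductor
convention); BED input/output converts at the I/O boundary via rtracklayer.
The upstream antisense (uasTrx) window is −1.7 kb to −200 bp from the TSS
in gene-strand coordinates, on the opposite strand: close enough to capture
divergent initiation, far enough (−200 bp gap) to avoid the sense
promoter's own signal.

## Counting and filters

A fragment counts for a window when it overlaps by at least 1 bp, matches
the required strand, and touches no exclusion region (rRNA/tRNA). The 1-bp
rule is the least surprising default for ~100 bp fragments against
multi-kb windows, and is the easiest to reason about when validating
against the brute-force oracle; it is not configurable per-fraction because
no analysis here is sensitive to boundary fragments.

Two filters with different jobs:

* **Low-count exclusion** (mean raw count ≤ 20 in *both* conditions):
  removes genes whose fold change would be numerically meaningless. The
  mean is taken over raw, unscaled counts.
* **Expression** (mean of condition-mean TPM > 15): defines the set over
  which the asymmetry median is computed and to which classes are
  assigned. TPM uses the counting-window length, not the annotated
  transcript length, because window counts are proportional to window
  length — using transcript length would bias capped long genes.

The antisense filter threshold is 10 rather than 20: antisense signal is
intrinsically weaker, and the downstream call (>2-fold up) is deliberately
conservative.

## Normalization and the asymmetry correction

Size factors are median-of-ratios against a geometric-mean
pseudo-reference. When a perturbation regulates many genes in one
direction, the median ratio itself absorbs part of the effect and pushes
apparent fold changes of unchanged genes in the opposite direction. The
correction subtracts the median log2 fold change over expressed genes, so
the bulk of the transcriptome is re-centered at zero by construction — the
package asserts `median(adjusted) == 0` to 1e-9 on every run. This assumes
regulated genes are a minority; if most expressed genes were truly
regulated, the correction would remove real signal (a known limitation of
any bulk-anchored normalization).

Fold changes are plain ratios of means of normalized counts, with no
shrinkage: the class taxonomy acts on observed fold changes, and a
moderated estimator would shift genes across class boundaries by an amount
that depends on expression level. Means rather than sums keep the estimate
invariant to replicate count. Genes with a zero condition mean get `NA`
(absent, not zero), preventing class inflation from undefined ratios.
Medians of even-sized sets are midpoints of the central pair throughout.

Per-replicate fold changes (for reproducibility analysis) re-center each
control/treatment pair by that pair's own median over expressed genes; the
source description does not say whether the centering median is pooled or
per pair, and the per-pair form is used because it makes each pair a
self-contained measurement.

## The class taxonomy

On linear fold change *f* (treatment/control), up classes are HU (*f* ≥ 2),
IU [1.5, 2), SU [1.3, 1.5); down classes are stated in fold-down *d* = 1/*f*
terms: SD (1.3, 1.5], ID (1.5, 2], HD (> 2); NC is (1/1.2, 1.2). The
slivers between 1.2- and 1.3-fold in either direction are `Others` —
deliberately unclassified territory rather than forced membership.
Boundary inclusivity follows the stated rules verbatim (≥ on up-class
outer edges, > on down-class inner edges); where alternative phrasings
conflict, the Methods-style definitions win and exact boundary points
(d = 1.3, 1.5, 2) land in the milder class or `Others` accordingly. The
alternative scheme for a strong reference perturbation (ND ≤ 1.2-fold
down, ID (1.5, 2], HD1 (2, 4], HD2 > 4) has a deliberate gap at
(1.2, 1.5]-fold down; genes there are returned `NA` with the gap size
reported, not silently binned.

Small classes (n < 10) merge with their neighbor toward NC on the same
side, iterating until every group reaches the minimum or the side collapses
into one group; a small mildest class has no neighbor toward NC on its side
and merges outward instead. NC and `Others` never participate. Merged
groups keep joint names ("HU + IU") so downstream tables remain
self-describing.

Two-time-point experiments classify by the arithmetic mean of the two
fold-downs, gated on > 1.3-fold down at *both* time points — a gene must be
convincingly down throughout, not on average.

## Reproducibility filtering

A gene's initial call (|FC| ≥ 1.3) is confirmed when the same-direction
change of ≥ 1.3-fold recurs in at least half of the additional replicate
pairs — `ceiling(0.5 × n)` for odd counts, since "at least half" must be
attainable by whole replicates. The per-replicate threshold is not stated
independently anywhere; it defaults to the same 1.3-fold as the initial
gate and is configurable. `NA` replicate values (zero counts) count as
failures, which is conservative.

## Set statistics

Overlap enrichment uses the sample odds ratio (a·d)/(b·c) — not the
conditional-MLE OR that `fisher.test` reports, which differs for extreme
tables — and a two-sided Fisher p computed by direct hypergeometric
summation of all tables no more probable than observed (with a 1e-7
relative tolerance for floating-point ties, the convention standard
software uses). Tests verify exact agreement with `stats::fisher.test` on
a thousand random tables. Zero cells flag the OR as degenerate (0 or ∞)
rather than applying a silent continuity correction.

Class-distribution comparisons are two-sided Mann–Whitney U tests against
a reference class, BH-corrected across the family in one call; the exact
small-sample path is verified against complete permutation enumeration.
Proximity enrichment compares the mean feature count near a gene set with
equal-size random draws from the expressed universe; controls match set
size only — expression- or length-matching requires covariates the caller
must supply, and silently pretending otherwise would overstate the
control's strength.

## Promoter annotation and anchored normalization

Peak-to-gene geometry is summit-based and gene-strand-signed (negative =
upstream). Nearest-summit selection breaks ties toward the upstream peak;
window flags (±200 bp ⊂ ±400 bp ⊂ ±2 kb) consider all peaks, so nesting
holds by construction. "Peak height" is the narrowPeak `signalValue`
column; formats differ in what they store there, so the reader errors on
summit-less records instead of guessing. Motif orientation scans both
strands of summit ± 100 bp with a PWM at 80% of the maximal score (the
usual default when a database matrix ships without a threshold) and reports
orientation relative to the gene's direction of transcription — the
quantity that correlates with activation — with `both`/`none` as honest
outcomes. The built-in matrix is a synthetic CTCF-like consensus for
simulation and testing; real analyses should supply a database matrix via
`read_jaspar_pwm()`.

ChIP libraries have no internal scale, so Pol II quantification anchors on
biology: gene-body signal of transcription-unchanged (NC) genes is assumed
constant, and treatment counts are rescaled so that set's median body
change is zero. The factor is `2^median(log2 ratios)` rather than the
median ratio: the two coincide at odd set sizes, but only the log-scale
median makes the anchored median *exactly* zero at even sizes, which is the
invariant the method promises. ATAC peaks are scaled by median-of-ratios
across peaks (peak-level counts are the only given), split
promoter/distal at ±200 bp summit-to-TSS, and stratified into CTCF-height
quartiles within each stratum by rank with id tie-breaks, so the partition
is deterministic and balanced to ±1.

## What the simulator emulates — and what it does not

The generator states a small world with the structure the analysis
assumes: genes on both strands with lengths straddling the counting caps;
negative-binomial counts with a shared dispersion; per-sample library size
factors; an optional global treatment-scale confounder
(`global_asymmetry_fc`); a class spectrum with mass concentrated in NC and
weak down classes (the observed signature of architectural perturbations;
the effect-size distribution of regulated genes is nowhere stated, so this
spectrum is a modeling choice); CTCF peaks with summits ~79 bp upstream of
the TSS, log-uniform heights, planted motif orientations; upstream
antisense signal at a 5% subset; Pol II counts with a 2× library
confounder; ATAC losses at 6.4% of peaks.

Defaults worth justifying:

* `nb_dispersion = 0.02` (NB size 50): typical of DESeq2-fitted dispersions
  for well-expressed genes in isogenic cultured-cell replicate designs —
  the setting emulated here. Heterogeneous tissue data would need 0.05 or
  more, and the null-calibration properties quoted below are specific to
  this noise level.
* Fragment length fixed at 100 bp, uniform placement: enough to exercise
  interval arithmetic and strand logic; deliberately not a model of Pol II
  kinetics, fragment-length distributions or sequence bias.
* Motif instances are the PWM consensus: guarantees scanner recovery, so
  orientation tests measure the annotation logic, not PWM sensitivity.
* Ground-truth class labels are produced by calling `assign_class()` on the
  planted fold changes — thresholds live in exactly one place.

Consequently, a green parameter-recovery test establishes that the
pipeline recovers planted effects under NB noise at the stated depth and
replication; it does not establish robustness to mappability artifacts,
3'-bias, overlapping transcription, or dispersion misspecification, none
of which the simulator generates.

## Numerical choices and degenerate inputs

* Fisher p: hypergeometric summation with 1e-7 relative tolerance on
  probability ties; p capped at 1.
* Mann–Whitney: exact for small tie-free samples, midrank normal
  approximation with continuity correction otherwise (`wilcox.test`
  behavior); identical constant groups return p = 1 with a degenerate
  flag instead of `NaN`.
* Size factors require at least one gene positive in all samples; the
  error suggests pseudo-count preprocessing rather than applying one
  silently.
* All-zero TPM columns, empty gene sets, unpaired replicates, summit-less
  peaks, non-strand-specific antisense input: hard errors naming the
  offending record, because each would otherwise corrupt a downstream
  stage quietly.
* Every stochastic stage derives its seed from the config seed
  (`seed + stage offset`), making whole-dataset generation byte-identical
  across runs.

## Known limitations

Classification operates on unmoderated fold changes, so very low-count
genes near the filter boundary have noisy class assignments — the
reproducibility filter, not shrinkage, is the guard. The asymmetry
correction assumes a majority-unchanged transcriptome. The uasTrx caller
emits candidates only; distinguishing genuine divergent initiation from
overlapping-transcript artifacts requires inspection that is explicitly
not automated. Upstream read processing (trimming, alignment, quality
filtering, duplicate marking) is out of scope: the package consumes
aligned fragments or count tables.
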