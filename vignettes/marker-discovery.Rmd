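---
title: "Methods: genic SSR and SNP marker discovery from transcriptome assemblies"
author: "TranscriptMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genic SSR and SNP marker discovery from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(TranscriptMarkers)
  library(GenomicRanges)
})
```

TranscriptMarkers implements the desk-side half of a molecular-marker
development study for a non-model plant: given assembled transcript contigs,
it mines microsatellites (SSRs), positions features relative to each
transcript's coding region, characterizes single-nucleotide variants, scores
germplasm diversity from marker band patterns, classifies differential
expression, and genotypes high-resolution-melting (HRM) curves. The wet-lab
and heavy-compute halves (sequencing, assembly, read mapping, variant
calling, primer synthesis, PCR) are out of scope; the package consumes their
standard outputs (FASTA, VCF, count tables, fluorescence traces) and, for
testing, simulates all of them with known planted truth.

## SSR mining

An SSR locus is a maximal perfect tandem repeat of a 2--6 bp unit. The
search criteria are unit-length-specific minimum repeat counts, by default
6, 5, 4, 4 and 3 contiguous units for di- through hexa-nucleotide motifs;
mononucleotide runs are excluded. These thresholds mirror common
transcriptome SSR-survey practice: shorter units must repeat more often
before a run is scored, so that expected random occurrences are rare at
transcriptome scale.

Conventions the detector commits to, where surveys are often silent:

* **Maximality and phase.** A periodic region is reported once, with the
  repeat placed leftmost; the repeat count is the number of whole units in
  the maximal run. A run is never extendable by one unit in either
  direction.
* **Irreducibility.** The motif must not be a power of a shorter unit
  (`ATAT` is not a tetramer motif); reducible runs are handled at their
  primitive period.
* **Overlap resolution.** Each base belongs to at most one locus: the
  longest run wins, ties go to the smaller unit length, then the leftmost
  start. Compound or interrupted SSRs are not merged or detected.
* **Canonical motif classes.** Survey tables label repeat classes up to
  cyclic rotation and reverse complement (`GAA`, `AAG` and `TTC` are one
  class). The class representative is the lexicographically smallest string
  among all rotations of the motif and of its reverse complement, printed
  as `"AAG/CTT"`. This makes the label invariant under rotation, strand
  flip, and their compositions.
* **N handling.** Any non-ACGT base terminates a run.
* **Coordinates.** 1-based inclusive throughout, the R/Bioconductor
  convention; loci are returned as `GRanges`.

The summarizer reports loci per unit length/class/region, the number of
SSR-bearing transcripts, and marker density as kilobases of surveyed
sequence per locus. Percentages are rounded to one decimal at report time
only; all internal computation is full precision.

Flank adequacy for primer design (`checkFlanks`) declares a locus designable
when both flanks are at least `minFlank` (default 50 bp) long and some
amplicon within `productRange` (default 100--250 bp, matching the SNP-assay
product sizes used in the study design this emulates) can contain
flank + locus + flank. Primer design itself is delegated; the package only
emits Boulder-IO records for a downstream tool.

## ORF annotation and region classes

The coding region of a transcript is the longest ATG-initiated open reading
frame (ORF) across the three forward frames and the three frames of the
reverse complement, stop codon included. Ties prefer the forward
orientation, then the smaller start. Two knobs matter:

* `minLenNt` (default 90 nt = 30 codons). Longest-ORF selection with no
  floor would assign a "CDS" to almost any sequence; a small floor
  suppresses spurious two-codon ORFs while keeping nearly all genuine coding
  transcripts.
* `requireStop` (default `TRUE`). Candidates running off the 3' end are
  rejected by default. Assembled contigs are often 3'-truncated, so the
  permissive behaviour is available, but the strict default keeps the
  planted-truth recovery exact.

Features are classified relative to the ORF in ORF orientation: entirely
5' of the CDS is `FIVE_UTR`, entirely 3' is `THREE_UTR`, and **any**
overlap with the CDS makes the feature `CDS`. The overlap rule is a design
choice: published survey tables assign each feature to exactly one of three
classes without defining boundary behaviour, and counting boundary-spanning
features as CDS keeps the three classes a partition for point features.
Transcripts without an accepted ORF give `UNCLASSIFIED`.

## SNP characterization

Variant records (from a VCF produced upstream by a read-mapping pipeline)
are filtered on read depth and mapping quality with thresholds 20 (minimum
depth), 200 (maximum depth) and 10 (minimum MQ). All three boundaries are
treated as **inclusive** — the source conventions state values, not
open/closed bounds — and every rejection carries a reason code so the
boundary convention is auditable. Multi-allelic lines contribute their
first ALT only; indels and multi-nucleotide variants are skipped with
reason codes, since the analysis concerns biallelic single-base
substitutions.

The spectrum reports the 12 directional substitution types, the
transition/transversion split (transitions are A&harr;G and C&harr;T), the
Ts/Tv ratio (flagged undefined when no transversions are present), zygosity
tallies (from the VCF genotype field), HRM classes, and the ORF-relative
positional distribution via the region classifier above. HRM SNP classes
follow the standard melting taxonomy: class I, C/T and G/A; class II, C/A
and G/T; class III, C/G; class IV, A/T — a function of the unordered base
pair only.

## Diversity statistics

Markers are scored on a germplasm panel as band presence (1) / absence (0)
per (locus, allele). Three statistics are computed from one matrix:

* **PIC** per locus, `1 - sum(p_j^2)`. Allele frequencies are estimated as
  band presences divided by total band presences at the locus; genotypes
  showing no band (null alleles) drop out of the denominator rather than
  forming an allele class. This estimation rule is the package's own
  choice — band-score surveys typically do not define one.
* **Jaccard similarity** between genotype profiles, shared bands over the
  band union. Two all-zero profiles are defined as similarity 1 (identical
  absence patterns); the dendrogram is built on distance 1 − J.
* **UPGMA** clustering: iteratively merge the closest pair at node height
  distance/2; distances to a merged cluster are size-weighted arithmetic
  averages. Ties are broken deterministically by the lexicographically
  smallest member-label pair (legacy phenetics software does not document
  its tie-breaking). The tree is ultrametric by construction and is
  returned as an ape `phylo` object.

## Expression classification

FPKM is computed from the printed formula `1e9 * C / (N * L)` (C mapped
reads on the transcript, N total mappable reads, L transcript length in
bp), and differential expression is classified purely by the sign of
`FC = log2(treated/control)`: positive is up-regulated, negative
down-regulated. No significance testing is applied — the classification
rule under study is sign-only — though an optional `|FC|` threshold exists
(default 0). When the control FPKM is 0 and the treated is not, the ratio
is undefined and the transcript is flagged `UNDEFINED` rather than patched
with a pseudocount; an explicit `pseudocount` argument is available for
users who want the conventional fix.

## HRM genotyping

Melt curves pass quality control when Ct &le; 30 and amplification
efficiency &gt; 1.4 (Ct inclusive, efficiency strict, following the stated
operators of the assay protocol this models). Curves are then normalized to
a percent scale between linear baselines fitted on a pre-melt and a
post-melt window (defaults: first and last 2 °C of the grid — instrument
software windows are never published, so these are package defaults,
overridable). Melt domains are the local maxima of the smoothed negative
derivative that exceed 10% of the global maximum and are at least 0.5 °C
apart; peak temperatures are refined by quadratic interpolation around the
grid maximum, giving sub-grid Tm estimates. One melt domain calls a
homozygote, two or more a heterozygote (heteroduplex mixture), zero or a QC
failure a no-call.

Numerical choices: derivatives use central finite differences; smoothing is
a moving average of 11 grid points (1.1 °C at the 0.1 °C default grid).
The window was chosen to suppress noise-induced shoulder maxima on the
melt transition — at 0.5% amplitude noise the transition shoulder sits just
below the 10% prominence threshold, and lighter smoothing lets noise
wiggles there masquerade as second melt domains — while staying well below
the ~1.5 °C homo/heteroduplex separation so genuine domains never merge.
On noiseless curves with grid step &le; 0.1 °C the Tm estimator bias is
below 0.05 °C (asserted in the test suite).

Pairwise comparisons of homozygous calls report |ΔTm| and, when the SNP
bases are known, whether the difference falls inside the reported per-class
ranges (I: 0.15--0.51, II: 0.03--0.41, III: 0.18--0.35, IV: 0.02--0.12 °C).
This is an annotation only; calls are never altered by it.

## The synthetic-data generators

Every input has a generator with a planted-truth ledger, so each stage can
be scored for exact recovery. All generators are pure functions of their
parameters including the seed; a single pipeline seed fans out to
per-generator substreams by stable string hashing, so adding a stage never
shifts another stage's stream.

* **Transcripts** (`generateTranscripts`): contig lengths from a truncated
  lognormal within 280--6445 bp (the contig-length range of the
  transcriptome this emulates), GC 45% (a typical plant transcriptome
  value; the source does not state one), and 96.4% of transcripts carrying
  a planted forward-strand ATG ORF of &ge; 300 nt. Construction is
  verified by rejection sampling: a candidate is accepted only when the
  package's own ORF finder returns exactly the planted interval, making
  the truth table exact by construction rather than by hope.
* **SSR planting** (`plantSSRs`): same-length window replacement with guard
  bases chosen so the run is maximal; placement windows respect the
  requested UTR/CDS region; every edit is re-verified to leave the ORF
  annotation unchanged, and background SSRs are first disrupted by point
  mutation so recall *and* precision can be scored at 1.0. Note that a
  motif whose cyclic reading contains a stop codon (e.g. `AAAT`) can never
  be planted in a CDS — with unit lengths coprime to 3 every rotation
  appears as a codon — and such requests fail with an explicit error.
* **SNP planting** (`plantSNPs`): transition with probability 0.61 (the
  transition share the emulated study reports), heterozygous with
  probability 0.0092 (17 of 1844), depth uniform on [10, 250] and MQ
  uniform on [0, 60] so the 20/200/10 filter has bite in both directions.
  Output is a VCF v4.2 document whose REF column is asserted against the
  reference transcripts.
* **Counts** (`simulateCounts`): negative binomial with mean/dispersion
  parameterisation (the emulated study states no count noise model;
  NB is the field default), lognormal baseline means, planted up/down
  genes at `2^log2fc`, library-size scaling.
* **Melt curves** (`simulateMeltCurve`): two-state logistic melting under
  linear sloped baselines plus Gaussian noise. Homozygotes are one duplex
  species; heterozygotes are two homoduplex plus two heteroduplex species
  at weights 0.25 each, heteroduplexes depressed 1.5 °C (and 1.8 °C for
  the second) below the less stable homoduplex. Auto-assigned homoduplex
  Tms follow the nearest-neighbour stability order A/A &lt; T/T &lt; C/C
  &lt; G/G in 0.4 °C steps from 80 °C. Published melt figures are not
  parameterised, so the noise level and transition width here are
  placeholders, not inferences.
* **Band matrices** (`simulateAlleleMatrix`): default panel dimensions 31
  loci × 27 genotypes; alleles per locus 1--5 with mean ≈ 2.9 (matching
  the panel this emulates), frequencies uniform on the simplex unless
  given, one band per genotype per locus (a self-pollinating panel is
  predominantly homozygous, and scoring is dominant), optional null-allele
  rate.

What the generators deliberately do **not** emulate: read-level error and
coverage structure (no FASTQ), assembly artifacts (chimeras, fragmented
isoforms), alignment biases behind the VCF, linkage between markers, and
instrument-specific melt-curve artifacts. Passing recovery tests on this
synthetic data therefore demonstrates the correctness of the *analysis*
logic under the stated models, not robustness to real-data pathologies.

## Reported scales and known inconsistencies

Percentages are rounded to one decimal (or whole numbers where the
convention prints them so) only at report time. Ts/Tv ratios are printed to
two decimals. Published tallies of this kind are not always internally
consistent (e.g. a SNP total quoted as both 1844 and 1845 alongside a
1129 + 716 split, or a panel table whose allele counts do not sum to the
quoted total); the package always carries its own raw counts, and the test
suite checks printed-percentage examples against the denominators their
sources actually used.

## Problem sizes in the test suite

The suite validates the miner against a brute-force enumerator on 1,000
random 1-kb sequences; planted-SSR recall/precision on a 500-transcript
synthetic transcriptome; UPGMA against an exhaustive reference on 200
random 6-taxon matrices; the variant filter against a per-record oracle on
10,000 records with the planted transition share checked at n = 1845
inside the exact binomial 99% interval; DEG sign recovery on 200 planted
4-fold genes at high depth; and HRM zygosity recovery on 1,000 curves per
genotype class at 0.5% amplitude noise. These sizes keep the whole suite
around a minute on one core while leaving the stochastic checks
well-powered.

## A small worked run

```{r pipeline, eval = FALSE}
cfg <- list(
  seed = 1,
  simulate = list(
    transcripts = list(nTranscripts = 60),
    ssrs = list(motifMix = list(GAA = 6, AG = 4)),
    snps = list(n = 150),
    counts = list(nUp = 5, nDown = 5),
    melt = list(genotypes = c("A/A", "G/G", "A/G"), noiseSd = 0.005)))
report <- runPipeline(cfg)
report
```

The report object carries the SSR summary, substitution spectrum,
diversity panel, DEG counts and HRM call table, together with every planted
truth ledger and a provenance block (seed, config hash, package version);
`writeReport()` serialises all per-record tables plus a human-readable
summary, applying rounding only at that point.
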