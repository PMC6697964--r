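# TranscriptMarkers

Marker development from de novo transcriptome assemblies of non-model
plants — the analysis layer that turns assembled transcript contigs into
genic-SSR and SNP marker resources, scores them on a germplasm panel, and
validates SNP genotypes from high-resolution-melting (HRM) curves.

Sequencing, assembly, read mapping, variant calling and primer design are
upstream of this package; it consumes their standard outputs (FASTA, VCF,
count tables, melt-curve TSVs). A synthetic-data module generates all of
those inputs with known planted truth, so the entire pipeline is testable
end to end without any sequencing data.

## What it computes

* **SSR mining** — every maximal perfect tandem repeat of a 2–6 bp unit,
  with unit-length-specific minimum repeat counts (di ≥ 6, tri ≥ 5,
  tetra ≥ 4, penta ≥ 4, hexa ≥ 3 units; mononucleotides excluded).
  Motifs are reported by canonical class: the lexicographically smallest
  string `M` over all cyclic rotations of the motif and its reverse
  complement, labelled `M/revcomp(M)` (so `GAA`, `AAG` and `TTC` are all
  `AAG/CTT`). Summaries report composition shares and density as kb of
  sequence per SSR; `checkFlanks()` assesses primer-design feasibility.
* **ORF annotation** — the longest ATG-initiated ORF over six frames
  (`ATG…stop`, stop included), partitioning each transcript into
  5'UTR / CDS / 3'UTR for positional classification of SSRs and SNPs.
* **SNP characterization** — depth/MQ filtering (keep iff
  20 ≤ DP ≤ 200 and MQ ≥ 10, boundaries inclusive), the 12-type
  directional substitution spectrum, transition/transversion split and
  Ts/Tv ratio, zygosity tallies, HRM SNP classes (I: C/T & G/A,
  II: C/A & G/T, III: C/G, IV: A/T) and ORF-relative position.
* **Diversity** — per-locus polymorphic information content
  `PIC = 1 − Σ pⱼ²`, pairwise Jaccard similarity of band profiles, and an
  UPGMA dendrogram (size-weighted average linkage, node height =
  merge distance / 2, ultrametric by construction) returned as an ape
  `phylo`.
* **Expression** — `FPKM = 10⁹·C/(N·L)` and `FC = log₂(treated/control)`;
  transcripts with FC > 0 are up-regulated, FC < 0 down-regulated.
* **HRM genotyping** — QC (Ct ≤ 30, efficiency > 1.4), baseline
  normalization to a percent scale, melt-domain detection on the smoothed
  negative derivative with sub-grid Tm refinement; one melt domain calls a
  homozygote, several a heterozygote; pairwise |ΔTm| with per-class range
  annotation.

See `vignettes/marker-discovery.Rmd` for the models, parameter choices and
their rationale.

## Worked example

Mining a planted `(GAA)₁₀` repeat:

```r
library(TranscriptMarkers)
findSSRs(c(contig1 = paste0("ACGTC", strrep("GAA", 10), "CCTGA")))
#> GRanges object with 1 range and 4 metadata columns:
#>       seqnames    ranges strand |       motif  motifClass repeatCount       region
#>   [1]  contig1      6-35      * |         GAA     AAG/CTT          10 UNCLASSIFIED
```

The repeat is found at positions 6–35 with 10 units, and its class label
`AAG/CTT` is the rotation/complement-invariant name
(`canonicalClass("TTC")` gives the same). Single statistics work the same
way: `fpkm(10, 1e6, 1000)` is `10`, and `picValue(c(0.5, 0.3, 0.2))` is
`0.62` — the probability two random alleles at that locus differ.

A full synthetic run, from one seed:

```r
cfg <- list(seed = 1,
            simulate = list(transcripts = list(nTranscripts = 60),
                            ssrs = list(motifMix = list(GAA = 6, AG = 4)),
                            snps = list(n = 150),
                            counts = list(nUp = 5, nDown = 5)))
report <- runPipeline(cfg)
report
#> RunReport (seed 1, config d9af882a)
#> SSR summary: 10 loci in 10 transcript(s)
#>   density: one SSR per 3 kb
#>   by unit length (%): 2=4 (40%), 3=6 (60%)
#>   top motif classes: AAG/CTT=6, AG/CT=4
#> Substitution spectrum: 91 SNVs
#>   Ts 47 (51.6%), Tv 44 (48.4%), Ts/Tv 1.07
#>   zygosity: 90 HOM, 1 HET
#>   HRM classes: I=47, II=20, III=14, IV=10
#>   regions: FIVE_UTR=15 (16.5%), CDS=60 (65.9%), THREE_UTR=14 (15.4%), UNCLASSIFIED=2 (2.2%)
#> Diversity panel: 27 genotypes, 31 loci, 96 alleles
#>   alleles/locus mean 3.1; PIC 0.00-0.75, mean 0.42
#> DEGs: 29 up, 31 down, 0 unchanged, 0 undefined
#> HRM calls:
#>  sampleId     zygosity nMeltDomains      tm1      tm2 qcPass
#>    S01_AA   HOMOZYGOUS            1 80.00073       NA   TRUE
#>    S02_GG   HOMOZYGOUS            1 81.25705       NA   TRUE
#>    S03_AG HETEROZYGOUS            4 78.47984 80.48525   TRUE
```

All 10 planted SSRs are mined back; the 91 retained SNVs (of 150 planted)
are the ones surviving the 20/200/10 filter; the A/A and G/G homozygote
curves each show one melt domain with the G/G Tm above the A/A Tm (duplex
stability order A/A < T/T < C/C < G/G), while the A/G heterozygote shows
multiple domains from its heteroduplex species. With only 91 variants the
Ts share (51.6%) sits a couple of binomial standard deviations from the
planted 61% — at the study scale (n = 1845) the suite checks it inside the
exact binomial 99% interval. `writeReport(report, "out/")` serialises every
per-record table plus a human-readable summary.

A thin command-line wrapper over the same functions is included at
`inst/scripts/markerpipe.R`
(`Rscript markerpipe.R mine-ssr in.fasta out.tsv`, `… run config.yaml`,
etc.).

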