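# retroclip

Transposable elements (TEs) make up nearly half the human genome and are
transcribed into mRNAs and lncRNAs, where RNA binding proteins (RBPs) can
bind them. Deciding whether CLIP-Seq reads over a TE family reflect real
binding is hard: TE-derived reads multi-map, families differ in
mappability, and host transcripts span orders of magnitude in abundance.
`retroclip` is an R package implementing a TE-aware CLIP-Seq analysis
pipeline built around a matched null model, for computational biologists
studying RBP-TE interactions at desk scale.

The core quantities:

* **Family x orientation enrichment.** With weighted read counts
  `c_f` (CLIP) and `n_f` (null) overlapping family *f* and library sizes
  `C`, `N`, the enrichment is `log2((c_f/C) / (n_f/N))`, where the null is
  simulated uniformly along transcripts from abundances estimated on the
  CLIP library itself (compatibility EM over isoforms augmented with
  unspliced pre-RNAs) and *mapped back through the same aligner and
  duplicate cap* as the data. A two-sided binomial test with BH adjustment
  flags significant families.
* **TE-specific motifs (TESMs).** Aligned coverage is projected onto TE
  consensus coordinates; maximal runs where the CLIP/null ratio exceeds
  3 become 9-column PWMs anchored at the maximum-coverage position.
  Motifs are compared with an information-coverage-weighted Euclidean
  distance, collapsed by average-linkage clustering at height 0.15, and
  ranked by enrichment.
* **Exact motif scanning.** PWM log-odds scores are discretised and scanned
  over the transcriptome with *exact* p-values from a dynamic-programming
  convolution of per-column score distributions (threshold 1e-5).
* **Peak calling.** A Poisson scan statistic over stranded 30-nt windows,
  with the window rate `lambda = sum_i mass_i * 30 / length_i` over
  overlapping isoforms, BH-corrected and merged; peaks in low-mappability
  regions (20-mers occurring >20 times) are removed.
* **Knockdown attribution.** Genes are classed by binding-site location
  (TE/nonrepetitive x exon/intron, optionally Alu split out); knockdown
  differential-expression statistics are compared between classes
  (Mann-Whitney) and regressed on `log2(1 + n_sites)` per class with 95%
  confidence intervals.

An adapter-ignorant iterative prefix aligner (align the first 20 nt, grow
ambiguous prefixes one base at a time, fall back one step when the adapter
is hit) and a fully seeded synthetic-data generator (toy genomes with TE
insertions, multi-isoform genes, planted binding signal, PCR duplicates,
multi-mapping reads, conservation tracks, knockdown tables) make every
stage testable without external data.

## Worked example

The bundled toy configuration simulates a 100 kb genome with three TE
families -- one of them (`AluP`) carrying a planted 9-mer bound at 10x --
and runs the full pipeline:

```r
library(retroclip)
library(data.table)

pc <- read_pipeline_config(system.file("extdata", "toy_config.yaml",
                                       package = "retroclip"))
res <- run_pipeline(pc$config, "toy_run", params = pc$params,
                    families = "AluP")

fread("toy_run/enrichment.tsv")[stratum == "all" & family == "AluP"]
#>    family orientation stratum clip_weight null_weight clip_total null_total
#> 1:   AluP   antisense     all      41.200          37   6541.592   6239.714
#> 2:   AluP       sense     all     258.867         179   6541.592   6239.714
#>    log2_ratio      p_value      q_value
#> 1: 0.08695717 6.870167e-01 8.244200e-01
#> 2: 0.46408950 5.403889e-07 1.621167e-06
```

The planted motif sits only in reads whose RNA carries it, so the sense
orientation of `AluP` is significantly enriched (log2 ratio 0.46,
q = 1.6e-06) while the antisense orientation is not. The sense TESM
recovers the planted probe (`ACCGTTAGC`) inside its 9-nt window:

```r
fread("toy_run/tesms_top.tsv")[orientation == "sense",
                               .(tesm_id, anchor, enrichment, consensus)]
#>          tesm_id anchor enrichment consensus
#> 1: AluP_sens_151    151   4.012704 CCGTTAGCG
```

The consensus profile peaks 4-fold over the null around consensus position
151, next to where the probe was planted (positions 146-154); the window
consensus carries the probe with the one-to-two nucleotide anchor jitter
inherent to coverage-argmax anchoring at this toy depth. Peak calling and
knockdown attribution complete the run:

```r
pk <- read_peaks_bed("toy_run/peaks.bed")
nrow(pk)                               # 13 peaks
sum(pk$site_class != "nonrepetitive")  # 4 inside TE copies
fread("toy_run/regression.tsv")
#>             term   estimate      ci_lo     ci_hi
#> 1:   (Intercept)  0.3662721 -0.1777268 0.9102710
#> 2:       TE_exon -0.1635642 -2.4715559 2.1444276
#> 3:     TE_intron  1.1574022 -0.2471968 2.5620013
#> 4:   nonrep_exon  1.3767567  0.2356551 2.5178584
#> 5: nonrep_intron -0.5020221 -1.7484801 0.7444359
```

Every stage writes plain text (SAM-like alignments, TSV, BED6+, MEME-style
PWMs) plus a JSON manifest with parameter fingerprints and checksums;
re-running an unchanged configuration skips all stages, and two runs with
the same seed are byte-identical.

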