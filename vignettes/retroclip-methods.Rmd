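---
title: "Methods: TE-aware analysis of CLIP-Seq data with retroclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-aware analysis of CLIP-Seq data with retroclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retroclip studies how RNA binding proteins (RBPs) interact with
transposable-element (TE) derived RNA in CLIP-Seq data. The central
difficulty is that TE-derived reads are repetitive: they multi-map, their
families differ in mappability, and host-transcript abundance varies over
orders of magnitude, so raw read counts over TE families are meaningless.
The package's answer, throughout, is a *matched null model*: reads are
simulated uniformly along transcripts from abundances estimated on the CLIP
library itself, pushed through exactly the same aligner, weighting and
duplicate handling as the data, and every TE-level quantity is a ratio of
the two libraries. This vignette explains each stage, its assumptions, and
the design decisions a maintainer would want recorded.

## Coordinates and data structures

All genomic intervals inside the package are **1-based and closed**, the
R/IRanges convention; BED and bedGraph inputs and outputs are converted at
the format boundary (so are RepeatMasker-style consensus columns, which are
1-based inclusive natively). A single internal convention removes the
off-by-one drift that creeps in when modules disagree; we chose the
convention native to R rather than the 0-based one common in Python
tooling, because every R primitive the code leans on (`substr`,
`findInterval`, `seq_len`) is 1-based.

Alignments are plain tables with one row per placement: a read aligned at
`n` loci appears `n` times, each with weight `1/n`, so weights of one read
always sum to one. Placements carry genomic blocks (`start:len,...`), which
makes spliced alignments first-class without a BAM dependency; the SAM-like
text serialisation writes M/N CIGARs and the `NH` tag.

## The iterative prefix aligner

CLIP libraries use small-RNA protocols that leave a 3' sequencing adapter
of unknown sequence on most reads. Instead of guessing adapters, the
aligner tries the first 20 nt of each read; a unique hit is reported at
once, an ambiguous read is retried with one more base, and when a read that
aligned at length L-1 loses all hits at length L, the L-1 hits are reported
-- the adapter has presumably begun. Reads with no hit at 20 nt are
discarded. Matching is exact: the synthetic reads copy the reference
verbatim, and the contract being implemented is the iterative-prefix
policy, not a mismatch-tolerant aligner. Splice awareness comes from
indexing spliced transcript sequences alongside the genome and projecting
transcript hits through the exon chain; hits identical at the genomic level
are deduplicated, keeping the longer (spliced) extension.

The known failure mode is documented rather than patched: when the bases
after the true insert happen to match another locus (for example, another
copy of the same TE followed by a base equal to the adapter's first base),
the read is assigned uniquely to the wrong copy. Family-level analyses are
insensitive to which copy of a family a read lands in, and measured
unique-placement accuracy on synthetic adapter-bearing reads is above 99%.

Reads with more than 20 placements are downsampled to 20 with a fixed seed;
at most 2 alignments are kept per (chromosome, position, strand) --
lexicographic read-id retention makes reruns identical -- and datasets with
fewer than 200,000 distinct aligned reads are flagged as too shallow.

## Abundance estimation and the null model

Isoform abundances are estimated by a standard compatibility EM: each
placement's weight is distributed over the isoforms it is compatible with
(all blocks exonic, contiguous in transcript coordinates) in proportion to
`mass/length`, and masses are re-estimated until the relative change drops
below 1e-6 (at most 100 iterations). The annotation is first augmented with
one unspliced *pre-RNA* isoform per gene spanning the locus, so intronic
reads -- plentiful in CLIP -- have a compatible transcript. Any consistent
estimator would do here, because abundances are used only to parameterise
the null; the EM is the canonical choice.

The null library draws reads with probability proportional to isoform
mass, uniform along the transcript, projects them through the exon chain,
**and then maps them back through the same aligner and duplicate cap as the
data**. This last step matters: the null's purpose is to absorb
mappability and saturation artefacts, and it can only do that if it
experiences them. In particular, wherever the positional duplicate cap
truncates the data, it truncates the null identically, keeping ratios
calibrated.

## TE enrichment and consensus profiles

Family-by-orientation enrichment is the log2 ratio of library-normalised
weighted counts of alignments overlapping (any base) the family's
instances, split by read strand versus TE strand. A pseudo-weight of 1 is
added to both counts when either is zero. A read overlapping two instances
contributes once to each family involved -- the null is treated
identically, so family-level proportions remain comparable. Significance
uses a two-sided exact binomial test of the clip count against the null
proportion with BH adjustment across family-orientation pairs; the choice
of test is ours (the procedure behind "significant enrichment" in this
literature is rarely stated) and is flagged as such.

Consensus profiles project every aligned base inside an instance onto the
family consensus through the instance's recorded consensus span
(RepeatMasker-style `repStart`/`repEnd`), with linear interpolation when
the copy carries indels. This annotation-based projection replaces
profile-HMM realignment of reads to the consensus; it serves the same
intent (a per-consensus-position pileup) at desk scale, and systematic
projection bias cancels in the clip/null ratio. The normalised ratio is
`(clip + 0.5) / (null + 0.5)` times the library-size correction; the 0.5
smoothing keeps zero-coverage consensus positions from producing spurious
infinities.

TE-specific motifs (TESMs) are maximal runs of consensus positions with
ratio above 3, represented as 9-column PWMs anchored at the
maximum-coverage position of the run (leftmost on ties; windows clipped by
a consensus edge are discarded). Column frequencies are the weighted
nucleotide frequencies of the covering read bases plus a 0.01 pseudocount,
read 5'->3' along the bound RNA -- for the antisense orientation the
columns run along decreasing consensus positions with complemented bases.
Because reads are at least 24 nt and motifs 9 nt, coverage across a bound
9-mer is nearly flat and the anchor position carries a nucleotide or two of
sampling jitter; the 9-nt window is wide enough to keep the motif inside it,
which is also why this motif width (rather than the shorter core many RBPs
recognise) is used.

## Motif scanning, distance and clustering

Scanning uses integer-binned log-odds scores (1e-3 bins) against a 0-order
background estimated from the scanned sequence space, with **exact**
p-values obtained by dynamic-programming convolution of the per-column
score distributions over the same bins. The binning is shared between the
scanner and the tail distribution, so a reported p-value is exactly the
probability of the reported score under the background -- verified in the
tests against exhaustive enumeration of all 262,144 9-mers. Occurrences at
p <= 1e-5 are kept, flagged when inside a TE, and annotated with precedence
CDS > 3'UTR > lncRNA > intron (the synthetic annotation marks CDS
explicitly; non-CDS mRNA exon sequence is treated as 3' UTR since 5' UTRs
are not modelled).

The motif distance is the information-coverage-weighted Euclidean distance:
information coverage of a column is `1 - H/2` (bits), zero for uniform and
one for point-mass columns; over all ungapped offsets with at least five
aligned columns the distance is the weighted mean of column distances with
weights `sqrt(ic_a * ic_b)`, minimised over offsets. The geometric-mean
combination is one of several defensible variants; `min` and `product` are
available behind an argument. Motifs are collapsed by average-linkage
clustering cut at height 0.15, each cluster represented by its
highest-enrichment member, and representatives ranked by enrichment with
the top 300 retained.

## Peak calling

Binding sites are called with a Poisson scan statistic over stranded 30-nt
windows stepped by 5 nt across expressed gene spans. Each window's expected
weighted count sums `mass * 30 / length` over isoforms whose exons overlap
the window; pre-RNA isoforms make introns testable. Weighted counts are
rounded up (conservative), upper tails come from the regularized incomplete
gamma function, and BH across windows at q <= 0.01 defines enriched
windows, merged when overlapping or book-ended (the merged peak keeps the
minimum window q). The window step and BH threshold are our choices -- the
scan-statistic literature motivates overlapping windows, and BH is simpler
than a family-wise scan correction at no practical cost in the calibration
tests. Peaks with at least half their bases flagged by the mappability
track (k-mers occurring more than 20 times genome-wide, mirroring the
20-placement cap) are removed; the summit's TE instance determines the
site class, and overlap with any spliced exon decides exon versus intron.

## Knockdown attribution

Genes are summarised by binding-site counts per class (TE or
nonrepetitive, exon or intron, optionally splitting Alu from other TEs)
and an exclusive class (bound only in TEs, only outside, only in Alu,
mixed, unbound). Distribution shifts of the knockdown
differential-expression statistic between classes use two-sided
Mann-Whitney tests with median shifts (the CDF figures this mirrors never
name a test); site-count dose response is summarised by binned medians and
interquartile ranges; and an OLS regression with intercept predicts the
statistic from `log2(1 + n_sites)` per class, with normal-theory 95%
intervals. The `+1` offset is required by zero-count classes in mixed
genes; predictors are not standardised, so coefficients stay in statistic
units per log2 site count. Splicing analyses apply the same machinery to
`-log10` of the splicing p-value.

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions for every downstream test. It emulates: a toy genome with TE
copies inserted on random strands (5'-truncated at per-family rates, with
the cut uniform on the consensus, and per-copy substitution rates);
multi-exon genes tiling the genome with 2-4 exons, 1-2 spliced isoforms, a
CDS/3'UTR split on mRNAs and a lncRNA fraction; lognormal isoform
abundances (meanlog 0, sdlog 1.5, about four orders of magnitude) with
pre-RNA at 15% of a fresh draw; 36-nt reads with inserts uniform between
24 and 36 nt, the 3' adapter plus random fill on short inserts; PCR
duplicates at 15%; and a conservation track that is N(0,1) baseline with
+1 added at planted motif occurrences outside TEs.

Binding signal has two channels. The *motif channel* upweights, by the
motif's multiplier, reads that cover the centre of an exact RNA-sense
occurrence of a planted 9-mer (insert lengths are drawn before positions so
the covering condition is exact); expected coverage therefore rises in a
triangle peaking at the occurrence centre, a deliberate emulation of
crosslink-style pile-ups that gives the coverage-argmax anchor a
well-defined target. The *family channel* upweights all read starts within
instances of a named family, which makes family-level enrichment equal the
multiplier up to a factor `1/(1 + (e-1) m)` with `m` the family's small
global mass share. Weights are renormalised globally, not per transcript:
an immunoprecipitation pulls down more fragments from bound transcripts,
and per-transcript renormalisation would provably attenuate family-level
enrichment by the family's share of its host transcript (far from
negligible for Alu-sized elements in gene-sized transcripts).

Because signal is planted at *RNA-sense* occurrences found in the actual
transcript sequences, orientation bookkeeping is automatic: an
antisense-inserted copy presents the reverse complement and receives no
signal unless the motif is self-complementary. Overlapping occurrences --
a poly-U tract matches a poly-U 9-mer at several offsets -- are collapsed
to one site anchored at the central match, reflecting that a tract is one
binding site.

The acceptance-scale configuration uses a 2 Mb genome with 300 genes and
100,000 reads, chosen so that weighted read-start density stays near 0.05
per transcript position -- the sparse regime real CLIP libraries occupy, in
which the duplicate cap removes PCR stacks rather than true pile-ups --
while leaving each planted site enough coverage for its pile-up apex to
stand above duplicate-level noise. The
planted probe family is a young SINE-like family (50 full-length copies,
2% divergence, as for a recently expanded Alu subfamily) whose consensus
carries a central 17-nt poly-U tract, with the planted 9-mer being poly-U:
this is the dominant motif class reported for TE-binding RBPs, and a
homopolymer tract keeps the recovered 9-mer within Hamming distance 1 of
the probe under the residual +-2-3 nt anchor jitter that coverage-argmax
anchoring cannot avoid with >= 24-nt reads.

What the generator does *not* model -- sequencing errors, indels,
fragment-length biases, crosslinking sequence bias, paired ends, true
transcriptional noise -- bounds what green tests mean: they validate the
statistical machinery and its calibration under the stated generative
assumptions, not performance on any particular real library.

For the family-enrichment recovery analysis the geometry is pushed further
towards the human situation: a 4 Mb genome of ~85 genes with 12-20 kb
introns, TE insertions excluded from exons (purifying selection), no PCR
duplicates, and SINE carrier families at moderate copy number. Two residual
attenuations are intrinsic to the paper's procedure and bounded by this
geometry rather than removed: the bound families' extra reads shrink every
other family's share of the fixed-size library (a few percent), and
abundance estimation on the signal-bearing library folds a share
`(e-1) * window / transcript_length` of each planted enrichment into the
null. The recovery analysis also draws the null five times deeper than the
data: the null is a Monte-Carlo estimate of an expectation, proportions are
library-size-normalised, and the size-matching convention only matters for
the zero-count pseudo-weight, which these deep categories never reach.

Calibration analyses that compare a pseudo-CLIP library drawn from the
null model against a second null draw also use a 5x-deep reference null:
the binomial significance test conditions on the reference proportion, so
leaving comparable sampling noise in it would inflate the test statistic by
sqrt(2) even under a true null.

## Numerical and reproducibility choices

Every stochastic step takes an explicit seed and restores the caller's RNG
state; the pipeline derives stage seeds from the configuration seed, writes
plain-text outputs only, and records a JSON manifest of parameter
fingerprints and md5 checksums per stage. A rerun with unchanged
parameters and intact outputs skips every stage; a corrupted intermediate
raises a checksum error naming the file. Two runs with the same
configuration produce byte-identical outputs, which the test suite
verifies file by file.

Degenerate inputs are handled explicitly: empty alignment sets yield empty
(not failing) results; an all-zero abundance model is rejected for null
simulation; zero-coverage profile positions are smoothed; all-uniform PWM
columns get zero weight in the motif distance, and distances between two
uninformative motifs fall back to an unweighted mean with a flag;
regression classes without sites are dropped with a warning rather than
producing a singular fit.

## Known limitations

* The aligner is exact-match by design; real reads with sequencing errors
  near the 5' end would be lost rather than rescued.
* Consensus projection trusts the instance annotation; large internal
  deletions are linearly interpolated rather than realigned.
* The anchor of a TESM is a coverage argmax and carries nucleotide-scale
  jitter; downstream consumers should treat TESM windows as motif-bearing
  neighbourhoods, not exact motif boundaries.
* Peak significance is not recomputed after window merging (the minimum
  window q is kept), and replicate-level reproducibility (IDR-style) is out
  of scope.
* The duplicate cap interacts with deep local coverage; at depths far
  above the acceptance-scale density the cap saturates both libraries and
  attenuates ratios even though the null matching keeps them calibrated.
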