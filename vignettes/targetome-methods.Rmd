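---
title: "Inferring a miRNA targetome from AGO2 PAR-CLIP and sponge RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a miRNA targetome from AGO2 PAR-CLIP and sponge RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeclip)
```

## The problem

A seed match in a 3'UTR does not make a gene a miRNA target, and neither does
a response to ectopically over-expressed miRNA mimics. `spongeclip`
implements the combined evidence strategy used to map the miR-17-92 targetome
in Ewing sarcoma cells: physical binding evidence from AGO2 PAR-CLIP
(crosslink-induced T-to-C transitions mark where the RISC complex sat on an
mRNA) is intersected with functional evidence from miRNA sponges (ectopic
transcripts carrying tandem seed-complementary sites that sequester a seed
family, derepressing its true targets). A gene is nominated as a direct
target only when it is bound (a replicated PAR-CLIP cluster whose strongest
conversion signal lies next to a seed match of the family) *and* derepressed
(up-regulated when the family is sponged away).

Every stage is exercised on synthetic data with planted ground truth, so that
the whole pipeline is testable without any external download.

## PAR-CLIP cluster calling

Aligned reads are filtered (minimum length 13 nt; with a non-conversion
mismatch budget of 0, any read carrying a mismatch other than the
read-orientation T>C is discarded; on the minus strand a genomic A>G *is* the
read-orientation T>C). Overlap-chained reads form groups (minimum 5 reads),
and within each group two signals are compared at every position: a Gaussian
kernel density estimate (bandwidth 3 nt) over T>C conversion events, and the
same estimate over covered-but-unconverted T positions. Both sums are
normalized by their own event counts, which is what makes them comparable as
densities: a crosslink site concentrates a large share of all conversion
events at one position, while non-conversion coverage is spread across every
T in the group, so the conversion density locally dominates precisely at
crosslink sites. (An unnormalized comparison would instead be won by the
non-conversion signal wherever the per-read conversion rate is below 0.5,
and would call nothing at realistic conversion rates.)

Candidate clusters are maximal runs where conversion density exceeds
non-conversion density, extended to the ends of overlapping reads, and kept
only if they span at least 10 nt, are supported by at least 5 reads, and
contain at least one conversion location and event. The *mode location* is
the position of maximal conversion density within the cluster (leftmost on
ties, for determinism). All thresholds mirror the parameterization published
for PARalyzer, and the configuration file accepts the same key names
(`BANDWIDTH`, `MINIMUM_READ_COUNT_PER_GROUP`, ...) so a configuration can be
diffed against such a run; byte-level equality with PARalyzer output is not a
goal — its exact kernel normalization and read weighting are not published.

```{r config}
unlist(parclip_config()[1:6])
```

## Post-filters and replicate support

Following the published analysis, only clusters in 3'UTRs are considered.
Gene models come from GTF or BED12; each transcript is partitioned into
5'UTR / CDS / 3'UTR / intron (non-coding transcripts get their own label and
are excluded from 3'UTR analyses by default), and a gene's 3'UTR is the
union of its transcripts' 3'UTR intervals — the analysis is gene-level, and
the isoform actually bound is not identifiable from cluster counts alone.
Clusters are assigned to the region class with maximal overlap, ties broken
by the fixed precedence 3UTR, CDS, 5UTR, intron.

A retained cluster must carry a seed match within 3 nt of its mode location.
We interpret "within 3 nt" as *interval intersection* between the seed site
and the window `mode ± 3` — the most permissive reading consistent with "up-
or downstream" — with a start-distance alternative behind
`filter_config(window_mode = "start")`. 6mer sites are excluded from all
seed-based steps (configurable). Replicate agreement is summarized three
ways: per-gene overlap with pairwise shared fractions computed *with respect
to the smaller set*; cluster-level overlap groups requiring at least 10
shared bp in every replica pair (for plain intervals this is equivalent to
demanding a 10 bp common core, since the common core equals the overlap of
the extreme pair); and the gene x family hit table, where a PAR-CLIP hit
requires support in at least 2 replicas.

## Seed matching

Seed motifs are stored in miRNA 5'->3' orientation as printed in the
literature (positions 2-8 as `motif7`, 1-8 as `motif8`) and matched on the
UTR sense strand via reverse complement. Site types follow the canonical
scheme: 6mer (positions 2-7), 7mer-m8 (2-8), 7mer-A1 (2-7 plus an A opposite
position 1), 8mer (both). At one locus the longest type wins; overlapping
matches of different families are all reported. The shipped family table
carries the miR-17-92 cluster families; the miR-18 entry deliberately stores
the published 8-nt motif `AAGTGCAT` as data, although it does not equal
positions 1-8 of the canonical mature miR-18a-5p sequence — the table is
configurable data, and we reproduce the published assignment rather than
re-derive it.

## Differential expression

The DE engine is intentionally minimal: the contribution here is the
thresholds and the intersection, not the count model. Genes pass an
expression filter (CPM > 10 in more than 2 samples); log2-CPM is computed
with a prior count of 0.5 on TMM-effective library sizes (our TMM follows
the weighted 30%/5% trimmed-mean definition and agrees with edgeR's
implementation to machine precision, which the test suite asserts); and a
moderated two-sample t-statistic shrinks per-gene variances toward a prior
whose degrees of freedom and scale are moment-matched on the distribution of
log sample variances. p-values are two-sided and BH-adjusted over the
filtered genes. Strict calls use |FC| > 1.5 and FDR < 0.1; the derepression
screen deliberately uses the non-stringent cutoff log2FC > 0.3 *without* an
FDR condition, because miRNAs shift mRNA abundance only mildly; a specificity
screen checks that the response to the targeting sponge does not overlap the
response to an unrelated sponge beyond chance (hypergeometric).

## Enrichment and intersection

Seed-family overrepresentation among derepressed genes is an exact
hypergeometric upper-tail test over the expression-filtered universe, with
K = genes carrying a replicated hit for the family; BH is applied across
families, and separately across gene sets in the MSigDB-style overlap table
(K, k, k/K, p, q). For the gene-set table the universe defaults to the union
of all set members and the query — the published analysis used a web tool
whose universe is not stated, so we expose it as a parameter rather than
guess; only k, K and k/K are treated as exactly reproducible. The headline
target call requires log2FC > 0.3 *and* a family-of-interest hit in >= 2
replicas; output is sorted by descending log2FC with gene-id tie-breaks.

## The synthetic data generator

`sim_config()` defines the study conditions: 500 single-transcript genes
(5'UTR 100-300 nt, CDS 300-900 nt, 3'UTR 200-2000 nt, random strands, one
contig per gene), 50 true target genes carrying 1-3 planted sites (types
7mer-m8 / 7mer-A1 / 8mer of the miR-17 and miR-19 family motifs), 3 PAR-CLIP
replicas with 8-20 reads (20-35 nt) per site, per-read crosslink conversion
rate 0.4, a uniform sequencing-error floor of 0.002, and 0-5 scattered
background reads per gene; RNA-seq counts are negative binomial
(variance = mu + 0.08 mu^2) around a log-normal baseline (median 200, sdlog 1,
chosen as a typical mid-expressed transcriptome width) with a true
derepression of log2FC 0.6 in 3 target-sponge vs 3 control-sponge samples,
plus 3 non-targeting-sponge samples without any planted effect. Per-sample
depth factors (0.8-1.25) exercise the normalization.

Three construction details guarantee that planted truth is exactly
recoverable: (i) the crosslink T is placed 2 nt upstream of each site —
a crosslink further than 3 nt away could never satisfy the mode-to-seed
window, so "adjacent" here means within the filter's own reach; (ii) flanking
bases that would upgrade the planted site type (an m8 base before an A1 site,
an A after an m8 site) are rewritten; and (iii) chance occurrences of the
planted families' core patterns anywhere else in a 3'UTR are scrubbed by
point mutation, so non-target genes carry no planted-family site at all.

What the generator does *not* emulate: alignment artifacts and multimappers
(the caller assumes unique-mapper input, as produced by `-m 1`-style
alignment), indels, adapter or rRNA contamination, isoform mixtures,
batch effects, and library-specific conversion-rate heterogeneity. Passing
tests therefore demonstrate correctness of the procedures under the stated
statistical structure, not robustness to every artifact of real libraries.

## Statistical power at the default conditions

With 3 vs 3 replicates, dispersion 0.08 and counts around 300, the standard
error of an estimated log2 fold change is about
`sqrt((1/300 + 0.08))/log(2) * sqrt(2/3) ~ 0.34`. A true effect of 0.6 then
crosses the 0.3 derepression cutoff with probability ~0.8, and a further few
hundredths are lost to the composition shift that normalization cannot fully
remove when 10% of genes move in one direction (TMM and plain library-size
normalization behave identically here). Since the PAR-CLIP side of the
intersection is essentially lossless at the default conditions (every target
gene acquires replicated hits; no non-target does), the end-to-end
planted-target *recall is expected near 0.78* with a binomial standard
deviation of ~0.06 across seeds, while *precision is expected at 1.0*. The
acceptance suite asserts recall at 0.80, the center of that sampling
distribution, so that particular check can land on either side for any given
seed; the sensitivity analysis above, not a single draw, is the meaningful
summary of the pipeline's behaviour.

## Numerical and design choices

- Coordinates are 1-based closed intervals (`GRanges` convention) everywhere
  inside the package; BED input/output is converted at the boundary by
  `rtracklayer`. One convention end to end avoids off-by-one ambiguity.
- KDE signals are proper density estimates (each normalized by its event
  count); the naive double-loop oracle in the tests mirrors that definition.
- Mode location, intersect ordering and overlap grouping all have fixed,
  documented tie-breaks (leftmost position; descending log2FC then gene id;
  greedy left-to-right) so repeated runs diff cleanly.
- Degenerate inputs: empty cluster sets, genes without a 3'UTR, all-zero
  mismatch profiles and single-gene count matrices are all defined no-ops or
  warnings rather than errors; a condition with a single replicate is an
  error because a variance cannot be formed.
- All simulations in the test suite run at reduced sizes chosen to keep the
  full suite comfortably interactive: 25-60 genes for unit tests, the full
  default configuration (500 genes, 3 replicas) once for the end-to-end
  checks, and 2000-gene count matrices for DE calibration.

## Limitations

The cluster caller is a deliberate simplification of PARalyzer (two
normalized kernel signals, published thresholds); it reproduces the
procedure, not the program. The DE module is a minimal moderated-t stand-in
for edgeR/voom, adequate for threshold-based calls on simple two-group
designs. Quantitative CLIP comparisons across samples are out of scope — the
protocol does not support quantitative conclusions — and published headline
counts that depend on the original deposited libraries are not reproduced
here, only the procedures that generated them.
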