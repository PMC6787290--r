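---
title: "Methods and design of the longtrx pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the longtrx pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longtrx)
```

# Scope

`longtrx` implements the downstream, reference-guided stages of a hybrid
long-read plus short-read transcriptome analysis of cancer versus normal
cell lines: transcript novelty classification, TSS validation against
promoter and histone-mark peaks, consensus lncRNA filtering with
cancer-specific lincRNA set logic and co-expression target prediction,
local alternative-splicing (AS) event enumeration with an isoform-usage
divergence score, and multi-criteria fusion-transcript detection with
short-read junction support. Upstream read processing (consensus calling,
error correction, alignment) and external database annotation are out of
scope: the package consumes alignments, call tables and peak files, not
raw reads.

# Coordinate and identity conventions

All internal coordinates are 0-based and half-open; conversion happens only
in the GTF/SAM readers and writers (both 1-based formats). A single
convention throughout eliminates off-by-one drift between modules.

Isoform identity across samples is structural: two transcripts are the same
isoform when they share chromosome, strand and the complete ordered intron
chain ([intron_chain_key()]). Variation at the 5' and 3' termini is
deliberately ignored, since long-read 5' ends are degradation- and
protocol-sensitive; mono-exonic transcripts, which have no introns, fall
back to exact exon bounds. This is the field-standard choice for matching
isoforms between samples when no joint clustering of reads is available.

The TSS of a transcript is its single 5'-most transcribed base: the first
exon start on the plus strand, the last base of the last exon on the minus
strand. Distances to peaks are unsigned and measured to the nearest covered
base, 0 when the TSS lies inside a peak.

# Transcript novelty classification

A query transcript is compared with the annotation in three steps, which
also define the four reported categories:

1. intron-chain match with any annotated transcript →
   *known isoform of a known gene*;
2. otherwise, at least 1 bp of same-strand **exonic** overlap with an
   annotated gene → *novel isoform of a known gene*. Intron-only
   containment does not count: a mono-exonic query inside an annotated
   intron is treated as novel-gene class. Queries whose only exonic
   overlap is antisense are flagged and classified as novel-gene class,
   preserving the information rather than forcing them into a gene.
3. remaining queries are clustered into novel loci by single-linkage
   same-strand exonic overlap. The representative of each locus (longest
   summed exon length, ties broken lexicographically by id) is the
   *isoform of a novel gene*; additional distinct intron chains at the
   locus are *novel isoforms of novel genes*. The representative rule is an
   interpretation — the distinction between the last two categories has no
   canonical definition — and the tie-break makes it order-independent.

# Alternative splicing events and the divergence score

Events are enumerated from all transcript pairs of a gene and deduplicated
by `(type, defining coordinates)`, so the count reflects unique local
events rather than transcript-pair combinations. The definitions follow
the standard seven-type local-event scheme (as popularised by SUPPA):

- **SE** — an internal exon whose flanking introns' outer boundaries form a
  single intron of another transcript;
- **RI** — an intron contained in another transcript's exon with both outer
  exon boundaries shared;
- **A5/A3** — two introns sharing one boundary and differing at the other,
  with the exons flanking the differing boundary overlapping (this overlap
  requirement is what keeps an SE's skipping intron from also being
  reported as A5/A3); donor-side variation is 5', assigned strand-aware;
- **MXE** — two non-overlapping internal exons, each absent from the other
  transcript, sharing both outer flanking boundaries;
- **AF/AL** — distinct, non-overlapping terminal exons spliced to a shared
  internal boundary, first/last taken strand-aware. The non-overlap
  requirement distinguishes genuine alternative terminal exons from mere
  5'/3' end variation of the same exon.

Per-sample event-type proportions are compared with Pearson's chi-squared
test on the raw count table, without continuity correction and with
df = (rows−1)(cols−1), the standard multi-category usage.

Isoform-usage divergence of gene *j* between a normal sample (isoform set
*b*) and cancer samples (sets *a_i*) is the summed Jaccard distance

$$D_j = \sum_i \left(1 - \frac{|a_i \cap b|}{|a_i \cup b|}\right),$$

so each term lies in [0, 1] and D is bounded by the number of cancer
samples (4 in the motivating five-line design; the implementation
generalises the sum to however many cancer samples are supplied). A
comparison where the gene is absent from both samples contributes 0 — the
ratio is otherwise 0/0, and absence in both is "no divergence". Ranking is
by descending D with lexicographic tie-break, making top-N selection
deterministic.

# lncRNA stages

The consensus filter keeps a transcript only when all four coding-potential
predictors (CNCI, PLEK, CPC, PfamScan) call it non-coding — a single
coding call removes it. lincRNA (intergenic) status requires no span
overlap with any protein-coding gene on either strand, so intronic and
antisense lncRNAs are excluded while overlap with other non-coding genes is
ignored.

Cancer-specific lincRNAs are, by default, the union of the cancer-sample
sets minus the normal-sample set and the reference catalog. The union
("detected in at least one cancer cell") is the permissive reading of
"from the cancer cells"; an intersection mode is available. Presence means
membership in the supplied per-sample sets — no expression threshold is
re-applied here. The specific set is monotone non-increasing in the
reference catalog, which the tests verify.

Target genes of a lincRNA are coding genes with Pearson r above 0.95 at a
two-sided p below 0.001 (t transform with n−2 df) **and** a genomic gap
between feature spans below 100 kb (closest edges; overlapping spans give
gap 0). The two expression thresholds are jointly unsatisfiable at very
small n — with 5 samples, r > 0.95 yields p ≈ 0.013 — so they are applied
exactly as configured but kept independently adjustable, and the synthetic
validation uses 12 samples, where r > 0.95 implies p well below 0.001.

The pre-miRNA search aligns each hairpin locally (match +1, mismatch −2,
affine gap open/extend 2.5) against every lincRNA sequence and its reverse
complement; a hit needs ≥90% identity over ≥90% of the hairpin length.
These thresholds are package defaults, not values taken from any published
protocol, and are exposed as arguments.

# Fusion detection

A chimeric read (two or more aligned segments) is a fusion candidate when:

1. every segment covers at least 10% of the query length;
2. the union of query intervals covers at least 99% of the read
   (the union, not the sum — heavily overlapping segments must not
   double-count);
3. every pair of loci is on different chromosomes or separated by a gap of
   more than 100 kb (closest edges). For reads with more than two loci,
   criteria 1 and 3 must hold for every locus and every pair — the
   strictest consistent reading.

The per-read audit records each criterion separately, so a rejected read
shows exactly which criterion removed it. Criteria are conjunctive; their
order cannot affect the final set.

Short-read support at the junction is either passed through from a
precomputed (s, a, b) table or counted from reads aligned to the fused
transcript: a spanning read (s) needs at least 8 aligned bases on both
sides of the junction, and the flank counts (a, b) are reads overlapping
the 100 bp immediately interior to the junction on each parent. Both the
8 bp overhang and the 100 bp window are package defaults exposed as
arguments, not published values. Tier 1 requires s ≥ 2; tier 2 — the
shortlist of fusions expressed comparably to their parents — additionally
requires a/s < 2 and b/s < 2, with s = 0 failing by definition (no
division). Parental genes are assigned per locus by maximal same-strand
exonic overlap, and database matching compares unordered stable-id pairs
after symbol mapping, skipping (and reporting) records with unmappable
symbols.

MAPQ-0 segments are retained but carry their mapping quality, with a
`drop_mapq0` switch in the alignment reader; only primary and supplementary
alignments are expected on input, secondary hits being the aligner's
redundant descriptions of the same placement.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of the configuration (including the
mandatory seed): identical configurations give byte-identical outputs, and
every generated feature appears exactly once in the emitted truth tables.
Defaults mirror the motivating design: five samples (one normal-like, four
cancer), coding genes on large, non-overlapping loci spaced more than
100 kb apart, half of them carrying exactly one planted AS event with the
seven types cycling. Event-planting geometry is constructed so the planted
event is the *only* event derivable from the gene's transcript pair, which
is what makes exact-recovery testing meaningful.

Fusion reads are planted per class: true fusions satisfy all four criteria;
each failure class violates exactly its named criterion and satisfies the
others (e.g. a `fails_distance` read joins loci 40–80 kb apart but keeps
per-locus coverage, combined coverage and spanning support). Junction
support is emitted as a (s, a, b) table, keeping unit tests independent of
any short-read alignment format.

Planted lincRNA-target pairs share a latent log-normal profile with 5%
multiplicative jitter and are re-drawn until the realised correlation and
p-value clear the detector's own thresholds, so truth labels are consistent
with the detection rule by construction. Decoys violate exactly one
condition: "far" decoys are equally correlated but placed 120–180 kb from
their partner; "near" decoys are co-located (20–60 kb) but re-drawn until
|r| < 0.8. Expression noise is log-normal with σ = 0.25 on a log-normal
mean profile — a conventional bulk-expression noise model.

What the synthetic data does **not** emulate: sequencing error profiles,
quality scores, genome sequence content (random bases only), library
chimeras, alignment ambiguity, or expression heteroskedasticity beyond the
log-normal model. Passing tests therefore demonstrate the correctness of
the decision logic at the stated thresholds, not robustness to real-data
artefacts such as mis-alignment near repeats or degraded 5' ends.

# Numerical choices and degenerate inputs

- FLNC/CCS ratios are rounded half-even to 2 decimals, with trailing zeros
  trimmed for display (so 0.7996 prints as "0.8"); the rounding convention
  of the motivating table is not stated anywhere, and round-half-even is
  R's default.
- Zero-variance expression vectors make r undefined; such pairs are
  skipped with a warning rather than propagating NaN.
- Samples with zero AS events are excluded from the proportion test with a
  warning; all-zero event-type columns are dropped before the chi-squared
  statistic; two identical count profiles short-circuit to statistic 0,
  p = 1.
- A read ending exactly at a fusion junction has zero overhang on one side
  and never counts as spanning.
- Unmapped reads parse to zero-segment records and are never candidates.
- `sharing_counts` is limited to 10 samples (2^n − 1 subset cells).

# Problem sizes used in validation

The bundled test-and-acceptance workload uses a 100-gene annotation (4–5
exons per transcript) for oracle-vs-implementation event comparison, a
200-read chimeric set (20 true fusions, 8 reads per failure class), a
40-lincRNA placement with 6 planted target pairs and 8 decoys at 12
expression samples, and 10,000-permutation checks of the correlation
p-value on bivariate-normal fixtures (where the t transform is exact).
These sizes were chosen so each validation exercises every planted class
several times over while the whole suite stays interactive.

# Known limitations

- Novel-locus category assignment depends on a representative choice with
  no canonical definition; the rule here is deterministic but
  interpretation-dependent.
- The AS event enumerator reports local events derivable from annotated
  transcript pairs; it does not quantify event usage (no PSI) and cannot
  see events whose inclusion form was never assembled into a transcript
  model.
- `predict_targets` tests all same-chromosome pairs; on very dense
  annotations the O(lincRNAs × genes) scan would need an interval index.
- The fusion detector trusts the aligner's segmentation; it does not
  re-align or assemble breakpoints, and reciprocal fusions are counted as
  distinct reads, not merged events.
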