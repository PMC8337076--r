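---
title: "Evaluating long-read genome assemblies with asmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating long-read genome assemblies with asmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The problem

A multi-species long-read assembly project produces dozens of de novo
genomes that must be compared on an equal footing: how contiguous is
each assembly, how complete is its gene space, how large is the genome
it represents, how much residual polymorphism is in the sequenced
sample, and how accurate is the consensus — overall, and specifically in
coding sequence, where indel errors corrupt protein prediction. When
the species span a whole family, the same single-copy orthologs that
measure completeness also support a comparative view: which markers
travel together on the same chromosome arm across all the assemblies.

`asmqc` implements this evaluation battery. Every statistic is computed
from standard files (FASTA, BUSCO full tables, VCF/gVCF, PAF with `cs`
tags, RepeatMasker `.out`, depth TSVs), and a synthetic-data module
generates all of these inputs with known ground truth so the whole
pipeline is testable without any external download.

## Coordinate conventions and containers

All interval data inside the package are 0-based half-open, the BED/PAF
convention; conversions from the 1-based inclusive file formats (VCF,
BUSCO tables, RepeatMasker) happen once, at the file boundary. Interval
arithmetic (merging, intersection, complement) is delegated to IRanges
behind a thin internal layer, so the 1-based/0-based conversion exists
in exactly one file. Containers are plain data frames with light S3
classes, so results print readably and drop into ordinary R workflows.

## Contiguity

`nx_curve()` and `contiguity_stats()` compute the Nx/NGx step functions,
N50/NG50/L50, and the auN statistic
\[
auN = \sum_i L_i \frac{L_i}{\sum_j L_j},
\]
the expected contig length of a uniformly chosen assembled base, equal
to the area under the Nx curve. N50 is a single point of that curve and
can be blind to a break; auN strictly decreases whenever any contig is
split, which the test suite asserts as a property. "Cumulative length
*first reaches* x%" is interpreted with `>=`, the standard N50
convention (a single contig then has N50 equal to its own length).
Equal-length contigs are ordered stably by name; no statistic depends on
that order, it only fixes the step table. For NGx, values of x beyond
the fraction of the genome size covered by the assembly are undefined
and reported as `NA`.

```{r}
cs <- contig_set(c("a", "b", "c"), c(60, 30, 10))
contiguity_stats(cs, genome_size = 150, large_threshold = 50)
```

## Completeness and the purging rule

`busco_summary()` collapses placements to one status per marker (two or
more placements means duplicated) and reports the standard C/S/D/F/M
breakdown. The duplication rate uses the total number of markers
searched as its denominator — the number the BUSCO tool itself reports —
not the complete subset. `purge_decision()` encodes the haplotig rule:
purge when the duplication rate *strictly exceeds* the threshold
(default 1%); a rate of exactly 1% does not trigger it.

## Genome size from marker coverage

Nanopore reads are too error-prone for k-mer based genome size
estimation, but complete single-copy orthologs behave like unique
k-mers: read depth over them reflects true sequencing depth. The
estimator is \(G = B(1-r)/d\) with \(B\) total read bases, \(d\) mean
depth over single-copy marker intervals and \(r\) the fraction of the
assembly removed as contaminant. Three choices are worth stating:

- Only `complete_single` markers contribute; duplicated or fragmented
  markers are not trustworthy single-copy anchors.
- Overlapping marker intervals are merged before averaging, so no
  position is double-counted (the underlying annotation can overlap
  when neighbouring genes share sequence).
- Positions inside marker intervals but absent from the depth file are
  counted as depth 0 by default (`zero_fill = TRUE`), because depth
  files conventionally omit zero rows; `zero_fill = FALSE` restricts the
  mean to observed positions. The mean (not median) is used, matching
  the estimator's definition; a median can be computed from the track
  directly if a robust variant is wanted.

## Heterozygosity and variant-based QV

Variant records and banded gVCF invariant blocks are filtered together
(`filter_calls()`): thresholds are inclusive (`>=`), defaults DP 10,
QUAL 30, GQ 30. A variant row must carry a depth and site quality to
pass — a record whose callability cannot be established is discarded —
while GQ is only required when present, since not all callers emit it.
Banded blocks are checked only on the fields they actually carry
(banded gVCF rows often lack QUAL); this is the package's resolution of
an underspecified corner, chosen so that band filtering never silently
discards whole genomes whose caller omits a field. Callable sites are
the lengths of passing invariant intervals plus the number of distinct
passing variant sites. A repeat BED can be excluded from both before
counting.

Heterozygosity is het SNPs / callable sites (indels and homozygous
variants are tallied separately). Consensus quality treats *every*
site carrying a non-reference variant — SNP or indel, het or hom — as an
error:
\[
QV = -10\log_{10}\!\left(\frac{\text{variant sites}}{\text{callable sites}}\right),
\]
with zero observed errors reported at the cap (default 60). The cap is
a reporting convention for perfect observations, not a ceiling applied
to positive error rates. Because the sequenced samples are rarely fully
inbred, residual heterozygosity inflates this error estimate; QV from
variant calls is best read as a lower bound on consensus accuracy.

## Reference-based windowed QV

When an independent reference assembly of the same strain exists,
differences between the assemblies (from PAF alignments carrying `cs`
difference strings; `parse_cs_diffs()` splits substitution runs into
unit SNVs) are scored as errors in non-overlapping windows (default
100 kb), overall and per genomic element. Element classes come from
`derive_elements()`: introns are the within-gene complement of exons,
intergenic is the complement of genes, so exon/intron/intergenic
partition each contig exactly; repeats are an overlay class because
they overlap genes. Numerical choices:

- the denominator is *aligned* bp in the window/class, not the window
  length — unaligned reference carries no evidence;
- an insertion contributes its full inserted length at its single
  reference anchor (it consumes no reference span to prorate);
- a deletion is prorated across windows and classes by reference
  overlap;
- windows with zero aligned bp in a class are omitted rather than
  reported as 0/0.

`aggregate_qv()` reports the pooled mean (Phred of summed errors over
summed aligned bp), the median of window QVs, and the value below which
a given percent of windows fall (the bottom-decile accuracy by
default; the empirical quantile uses the inverse-ECDF definition so the
cutoff is always an observed window value). Errors cluster into few
windows in real comparisons, so the median typically exceeds the pooled
mean. `indel_impact()` counts insertions and deletions touching coding
intervals, the genes affected, and the share of differing bp carried by
large (default ≥ 100 bp) insertions.

## The marker-adjacency graph

`build_adjacency()` walks each assembly contig by contig: complete
single-copy markers are ordered by start coordinate (ties by end, then
id, for determinism; strand is stored but ignored — the graph is
undirected) and each pair of immediate neighbours increments an edge
weight. Only immediate neighbours form edges: a run of k markers
contributes k−1 edges and no transitive pairs. The alternative reading
— discarding any contig carrying three or more markers — is available
via `mode = "drop_chains_ge3"`, but it is not the default because it
would discard nearly all the signal in well-assembled genomes.
`components()` clusters markers by connectivity above a weight cutoff;
with conserved arm content and no translocation each chromosome arm is
one component. `fa2_layout()` implements the ForceAtlas2 force model
(linear weighted attraction, degree-scaled repulsion, gravity, adaptive
speed) with the conventional settings tolerance 1, gravity 1, 3000
iterations as defaults; it is exact (no Barnes–Hut), which is adequate
to a few thousand nodes. Quantitative claims in the tests rest on
`components()`, not on layout geometry, which is only required to place
connected nodes nearer than unconnected ones.

## Repeats, read sets, downsampling

`repeat_summary()` merges within-class intervals before summing (so
nested/overlapping hits are not double-counted) and reports the
cross-class union as total repetitive bp; the class is the part of the
RepeatMasker class/family string before `/`, and unrecognised strings
are kept verbatim. `read_stats()` applies the N50 cumulative rule to
read lengths and reports the fraction of bases in reads longer than
each threshold (strict `>`, configurable). `downsample()` takes reads
in a seeded uniform permutation until the target base count is first
reached: selection is length-unbiased, so the subsample preserves the
read-length distribution, and the overshoot is less than one read.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure the analyses assume,
at the study's own operating points, and their defaults are fixed:

- `sim_marker_assemblies()`: conserved per-arm marker content with
  intra-arm inversions (block endpoints uniform over within-arm pairs —
  the simplest model that preserves arm content, since no rearrangement
  model is otherwise implied), optional rare translocations, geometric
  fragmentation into contigs. Six arms of a few hundred markers
  emulate the drosophilid Muller-element architecture.
- `sim_variant_calls()`: i.i.d. per-site het/hom SNPs; emitted records
  carry DP 30 / QUAL 50 / GQ 50 so all pass default filters, with an
  optional sub-threshold contaminant fraction (DP 5 / QUAL 10 / GQ 10)
  that filtering must remove. Heterozygosity inputs from
  3.5×10⁻⁶ to 10⁻² per site are the realistic range.
- `sim_alignment_diffs()`: Poisson differences per element class;
  indel lengths 90% in 1–3 bp with a 10% geometric tail, mimicking the
  homopolymer-dominated indel spectrum of Nanopore consensus.
- `sim_reads_and_depth()`: lognormal read lengths (shape 0.55) rescaled
  to a target read N50 of 20–30 kb; per-position depth Poisson or
  exactly uniform.
- `sim_repeat_annotation()`: tile-based non-overlapping class intervals
  hitting target proportions to within one tile.

Every generator is a pure function of its arguments and seed (RNG state
is saved and restored around each call; per-species streams derive from
the master seed as `seed*1000 + index`). What the simulations do *not*
contain: sequence-level read errors, alignment artefacts, mapping bias
near repeats, segmental duplications, or correlated (clustered) error
processes. Passing tests therefore demonstrate that the estimators are
correct for their definitions and recover known truth under the stated
sampling models — not that those models capture every pathology of real
data.

## Problem sizes and tolerances in the test suite

The suite exercises the estimators at sizes chosen to make sampling
noise small relative to the asserted tolerances while keeping a full
run around a minute: heterozygosity at 10⁶ callable sites and h = 10⁻³
(asserted within 4 binomial SDs), genome size at Poisson depth 30 over
1.2×10⁵ marker positions (within 2%), pooled windowed QV at an SNV rate
of 10⁻³ over 2×10⁶ aligned bp (within 0.5 QV), and arm recovery with
20 species × 6 arms × 300 markers (exactly 6 components, zero cross-arm
edges). Exact statistics (N50/NG50/auN) are checked against brute-force
oracles on 1000 random contig sets.

## Known limitations

- VCF handling targets single-sample files; with multi-sample input the
  first sample's FORMAT fields are used.
- Whole-file streaming parsers: no bgzip/tabix random access, which is
  sufficient at per-assembly scale.
- Scaffold-aware (gap-split) contiguity and the auNG variant are not
  implemented.
- `fa2_layout()` is O(n²) per iteration; for graphs beyond a few
  thousand nodes use the components and matrix exports with external
  layout tools.
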