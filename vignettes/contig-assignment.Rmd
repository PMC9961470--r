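---
title: "Assigning assembly contigs to chromosomes by homology and evidence consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning assembly contigs to chromosomes by homology and evidence consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctga)
```

## The problem

Many plant genome assemblies — the cucumber B10v3 assembly is the
motivating case — consist of thousands of contigs of which only a small
fraction has been tied to chromosomes experimentally. Several
independent lines of evidence can each claim a chromosome for a contig:
reference-guided scaffolding against related chromosome-level genomes,
protein homology of the genes a contig carries, genetic-map markers,
DArT-seq loci anchored by sequence similarity, and BAC/FISH probe
hybridization. These tracks mostly agree, but not always, and the
disagreements are scientifically interesting (mis-assembly,
misinterpreted hybridization signals, true structural divergence between
lines). `ctga` implements the whole workflow: reading the standard
formats, placing contigs on reference chromosomes, quantifying what was
and was not placed, and integrating all tracks into per-contig consensus
assignments with explicit conflict reporting.

## Homology placement by unique k-mer anchors

External scaffolders (RagTag and relatives) can be ingested directly
through their AGP output (`read_agp()`, `agp_to_evidence()`). The
package also ships its own self-contained placer so the pipeline runs
end to end without external binaries.

`build_anchor_index()` indexes every k-mer that occurs exactly once
across the reference chromosomes, counting both strands via canonical
(lexicographically smaller of forward and reverse-complement) forms.
Each contig k-mer found in the index votes for one chromosome
(`place_contigs()`). A contig is *placed* when

* total votes ≥ `min_anchors` (default 10),
* the winning chromosome is a unique maximum, and
* its vote fraction ≥ `min_confidence` (default 0.8).

A tied maximum yields *ambiguous* — the typical signature of a chimeric
contig — and is never resolved arbitrarily; everything else is
*unplaced*. Orientation is the majority strand agreement of the
supporting anchors (a tie reports `+` with a warning), and the position
used for ordering contigs along a chromosome is the median supporting
anchor coordinate, which is robust to a minority of stray anchors.

Defaults and rationale:

| parameter        | default | unit | why                                              |
|------------------|---------|------|--------------------------------------------------|
| `k`              | 21      | bp   | odd (no palindromes); specific at genome scale; tolerant of ~1% divergence (≈0.81 of k-mers survive) |
| `min_anchors`    | 10      | anchors | excludes placements supported by a handful of chance matches |
| `min_confidence` | 0.8     | fraction | an exact substring always places; a balanced chimera never does |

Repeat arrays shared across chromosomes contain no unique k-mers, so
contigs drawn entirely from repeat arrays collect no votes and stay
unplaced — matching the observation that the unassigned fraction of a
plant assembly is repeat-dominated. Each reference genome is processed
independently (one evidence track per reference); no multi-reference
merge is attempted, since merging homologous but diverged references
tends to destroy chromosome-level assignment rather than improve it.

## Composition of the placed and unplaced partitions

`compute_composition()` splits contigs into *placed* and *unplaced*
(ambiguous and unlisted contigs count as unplaced) and reports repeat
coverage and gene-biotype counts per partition. Overlapping repeat
annotations are merged (`merge_intervals()`, via `IRanges::reduce`)
before base counting so no base is counted twice; raw summing is
available for comparison (`merge = FALSE`). Genes belong to the
partition of their host contig — the natural unit here, since the
question is which contigs (and hence which genes) reached chromosomes —
and gene and repeat accounting are independent: a gene overlapping a
repeat still counts once. Internal values are exact fractions; rounding
is left to presentation.

## Protein matching

`best_hit_per_query()` reduces a BLASTP table to one hit per query with
a fully deterministic key: minimal e-value, then maximal bitscore, then
maximal percent identity, then smallest subject id. Identity-bin
summaries (`bin_by_identity()`) use the conventional reporting bins
`=100`, `[95,100)`, `[90,95)`, `[80,90)`, `<80`; membership in `=100`
requires the tabular identity field to parse to exactly 100, with no
additional coverage requirement imposed. Queries with no hits are
visible as the difference between query count and bin total, never
silently dropped. `intersect_identity_sets()` counts queries satisfying
identity predicates in two searches at once, e.g. "found at 100%
identity against both reference proteomes".

## Evidence integration and consensus

All tracks reduce to *evidence records*: `(contig, chromosome, source,
locus, weight)`. Chromosome labels are normalized
(`"Chr2_9930"` → `"Chr2"`) because scaffolding tracks carry
reference-suffixed object names.

`consensus_assign()` proceeds in two stages:

1. **Per-source aggregation.** If one source claims several chromosomes
   for a contig (two DArT loci disagreeing, say), the source's internal
   majority is taken first; an internal tie makes that source abstain.
   This keeps a locus-rich source from outvoting all others by volume.
2. **Across-source vote.** Sources vote with their weights (all 1 by
   default — no published basis exists for unequal weights). A unique
   maximum is the consensus; a tie is reported as *ambiguous*; sources
   disagreeing with the consensus are listed as conflicts.

Because the cytogenetic (BAC/FISH) track is the one independent
wet-lab line of evidence, `build_integrated_table()` reports two
consensi: `consensus_bioinf` over everything except `bac_fish`, and
`consensus_all` over all sources. A contig where the two differ, or
where `bac_fish` appears in the conflict list, is exactly the kind of
case (like the published ctg2607 disagreement) a curator should look at.

## The synthetic study

`synth_generate()` builds a miniature study with complete ground truth,
so every stage can be validated without downloads. Default conditions:

* 7 chromosomes (the cucumber karyotype) of 120–160 kb — about 1 Mb in
  total, large enough for ~35 contigs and dense unique anchors, small
  enough that the full pipeline runs in seconds;
* a random (hence essentially k-mer-unique) backbone with one
  pericentromeric tandem-repeat array per chromosome (10% of its
  length), built from 180 bp units of a few families shared across
  chromosomes, echoing the classic cucumber FISH probe classes
  (Type III/IV satellites, 45S rDNA);
* fragmentation into 2–50 kb contigs with breakpoints forced at array
  boundaries — assemblers break at long repeat arrays, and this
  guarantees genuinely unplaceable repeat-only contigs;
* 1% substitutions plus rare short indels on the assembly copy, random
  contig orientations, shuffled contig naming;
* 210 genes (25% lncRNA) placed proportional to contig length, plus
  occasional dispersed repeat-unit copies annotated in the
  RepeatMasker-style output;
* five evidence tracks. The marker, DArT and STC/BAC tracks are sparse —
  each locus lands on a distinct gene-space contig — mirroring real
  marker sets, which are small relative to the contig count; protein
  tracks cover every protein-coding gene against two synthetic reference
  proteomes. Each claim is corrupted to a uniformly random wrong
  chromosome with probability 0.05, and every corruption is recorded,
  as is the per-source claim that survives within-source aggregation
  (the proper recall target for conflict detection).

What the generator does **not** emulate: real transposon landscapes and
segmental duplications, assembly-specific error modes (collapsed
repeats, chimeric joins), GC/coverage biases, realistic e-value
distributions, or inter-line structural variation. Passing the
synthetic recovery tests therefore demonstrates correctness of the
algorithms under controlled conditions, not performance on any
particular real genome.

`truth_compare()` scores a placement or consensus result: fraction of
assigned contigs on their true chromosome, per-chromosome Kendall tau
of contig order, and — given a conflict list — precision and recall of
conflict detection against the recorded corruptions.

## Numerical and design choices

* **Coordinates are 1-based inclusive everywhere.** Every format this
  package touches (FASTA indexing conventions, GFF3, AGP, BLAST
  tabular, RepeatMasker) and the R interval stack (`IRanges`) are
  1-based closed; converting internally to half-open would reintroduce
  the off-by-one class of bugs at every boundary. `to_halfopen()` /
  `from_halfopen()` are provided for BED-style interoperability and are
  exact inverses.
* **N50** follows the shortest-covering-contig definition: sort lengths
  descending, accumulate, report the first length where the running sum
  reaches half the total. Accumulation is done in double precision so
  multi-gigabase assemblies cannot overflow integer arithmetic.
* **Base percentages** use total assembly length as denominator, so `N`
  bases depress the four base percentages (their share is reported
  separately) — consistent with standard assembly-statistics tools,
  whose four base percentages sum to less than 100 for N-containing
  assemblies.
* **Ties** are never broken arbitrarily: tied chromosome votes yield
  ambiguity at both the placement and consensus level; tied best hits
  fall back to a deterministic lexicographic key; tied orientation
  votes report `+` with a warning.
* **RepeatMasker rows flagged `*`** (overlapping, lower-scoring) are
  kept by default: overlap is resolved by interval merging, which is
  what the coverage fractions require; dropping them is an option.
* **Gene biotype keys** are tried in order (`biotype`, `gene_biotype`,
  `locus_type`) because annotation providers do not agree on the
  attribute name; the list is configurable.
* **AGP gaps** are written as component type `U`, length 100, gap type
  `scaffold`, linkage `yes`, evidence `align_genus`, mirroring common
  reference-guided scaffolder output.

## Problem sizes and determinism

The test suite validates against independent oracles (brute-force N50
on 1000 random length multisets, a per-base coverage bitmap, an
exhaustive best-hit argmin) and runs the full synthetic study at its
default size (~1 Mb, ~35 contigs), which keeps a complete run under a
minute on one CPU. All randomness flows from the single seed in
`synth_params()`; identical seeds produce byte-identical output files,
and placement and consensus are fully deterministic given their inputs.

## Limitations

* The anchor placer assigns and orders contigs but does not estimate
  gap sizes, detect mis-assemblies, or split chimeric contigs — a
  chimera is surfaced as *ambiguous*, not repaired.
* Consensus is a weighted vote, not a probabilistic fusion; it reports
  support fractions, not calibrated posteriors.
* Reproducing published full-genome numbers requires the released
  genome FASTA/annotation files and an external scaffolder run;
  `scripts/reproduce_fullscale.R` wraps the statistics and
  protein-summary stages for such data.
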