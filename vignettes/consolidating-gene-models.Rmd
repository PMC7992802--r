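---
title: "Consolidating redundant gene models and auditing ortholog detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating redundant gene models and auditing ortholog detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genewinnow)
```

## The problem

An evidence-based annotation of a draft genome merges two tracks of gene
models. Homology models come from spliced protein-to-genome alignment of
a well-annotated relative's proteome; keeping the two best placements per
protein also annotates recent duplicates, at the price of redundant
placements. Transcript models come from ORFs extracted from assembled
RNA-seq transcripts (six frames, partial and complete, minimum 40 aa)
aligned back to the assembly; fragmented assemblies contribute several
overlapping isoforms and spurious short ORFs. The joint annotation
therefore holds *several* candidate models per locus, and the task is to
keep exactly one representative per locus without inventing structure
that the evidence does not support.

## The selection procedure

`select_nonredundant()` implements a greedy window-coverage heuristic.
Strands are treated fully independently throughout. Per sequence and
strand:

1. **Coverage.** Every exon start and every exon end coordinate *c*
   (1-based) of *every* input model is assigned to the window
   `floor((c - 1) / window_size)`; a window's coverage is the count of
   boundary features assigned to it. Both boundaries of a short exon can
   fall into one window and then count twice: each boundary is a feature.
   Coverage is deliberately computed from all models, including ones that
   later fail the eligibility filters — a heavily supported locus should
   be resolved early even if some of its support is ineligible, and the
   filters are part of the *choice*, not of the agenda.
2. **Agenda.** Windows are processed in order of decreasing coverage.
3. **Choice.** At each window, the candidates are the still-available
   models whose gene span (minimum exon start to maximum exon end)
   intersects the window and that pass both filters: at least `min_exons`
   exons and an ORF of at least `min_orf_aa` amino acids. The candidate
   with the longest ORF is selected, and every other still-available
   model whose gene span overlaps the selected model's gene span is
   discarded. A window with no eligible candidate is skipped.
4. **No backtracking.** A selected model is never displaced by a later
   window.

Models that are never selected and never overlap a selected model are
reported with the filter they failed (`filter_exons` before
`filter_orf_len` when both apply); everything else discarded carries
`overlap_with_selected`. The result partitions the input: every model id
appears exactly once in `selected` or `discarded`, which the tests assert
on every fixture.

### Why discard by model overlap, not window overlap

"Discard the other intersecting models" admits two readings: models
intersecting the *window*, or models intersecting the *chosen model*.
Discarding by window would delete neighbors that merely touch a busy
window without competing for the locus, so the default discards by
overlap with the chosen model's gene span. Gene-span overlap (rather than
exon-level overlap) is used for the discard test because competing
isoforms interleave exons with introns; exon-level disjointness of the
final selection then follows and is asserted separately. Because the
choice is not derivable from first principles, `discard_scope = "window"`
is available and the audit log records every decision either way.

### Determinism

The procedure is reproducible to the byte. Window-order ties break by
(sequence id, window index, `+` before `-`); candidate ties break by
(longest ORF, smaller gene start, lexicographically smaller model id).
All string comparisons use C-locale radix ordering so results do not
depend on the session locale. Two runs on one input produce identical
audit logs, and every writer emits features in a fixed sort order.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_size` | 100 | bp | granularity of the coverage agenda |
| `min_orf_aa` | 60 | aa | minimum ORF for a selectable model |
| `min_exons` | 3 | exons | minimum structure for a selectable model |
| `min_len` (ORF extraction) | 40 | aa | minimum reported ORF |
| `max_evalue` (RBH) | 1e-4 | — | strict cutoff, `evalue < max_evalue` |
| `top_k` (patterns) | 20 | — | most abundant patterns reported |

The exon and ORF thresholds exist to keep partially assembled transcript
fragments and transcriptional noise from inflating the gene count. They
are calibrated for gene-dense genomes with many exons per gene; genomes
with fewer exons per gene need a lower `min_exons`, and unusually short
real genes will be lost at any positive threshold — a known, documented
trade-off rather than a bug.

ORF length is defined as `floor(total CDS length / 3)` for both evidence
tracks (stop codons are not subtracted). A single span-derived rule keeps
homology and transcript models comparable and avoids translating genomic
sequence, which the selector never needs. Exonerate alignments are taken
verbatim; possible frameshifts or split codons in the alignment are not
post-processed.

## ORF extraction semantics

`extract_orfs()` scans all six frames and reports every *maximal*
stop-free stretch of the frame translation at or above `min_len`.
"Partial" means edge-truncated: an ORF need not begin with ATG and need
not end at a stop, which matches what fragmented transcript assemblies
deliver. Codons containing `N` translate to `X` and never terminate an
ORF. The first codon of a frame is translated as an ordinary codon, not
as an initiator (otherwise leucine initiator codons would silently become
methionine). Because whether a "complete" ORF must start with methionine
is a modelling decision downstream tools disagree on, the records expose
`starts_with_met` plus the two edge flags (`complete5p`, `complete3p`)
instead of filtering; for maximal ORFs `complete3p` is always true and is
kept for symmetry.

## The evaluation toolkit

`presence_matrix()` reduces per-genome BUSCO classifications to a binary
gene × genome matrix. Presence defaults to status Complete or Duplicated;
Fragmented counts as absent, because a fragmented hit does not evidence a
usable gene model — the alternative reading is one flag away
(`present_statuses`). The row-pattern tally always sums to the number of
genes, and the all-zeros class (missing in every genome) is the input to
`rescue_missing()`: a gene missing everywhere but with a reciprocal best
hit in every genome is better explained as a detection failure of the
completeness pipeline than as a repeated loss. Rescue fractions are
reported unrounded.

`reciprocal_best_hits()` ranks hits per query by bitscore (ties: lower
e-value, then subject id) after removing hits with `evalue >= max_evalue`
— the cutoff is strict by definition. When one query has several HSP rows
against one subject, the highest-bitscore row represents the pair; HSPs
are not summed, since tabular rows are treated as independent alignments.
`metric_matrices()` never zero-fills: a gene without a hit in a genome is
`NA`, because zero is a valid bitscore-adjacent value and would corrupt
downstream summaries. `subsample_matched()` exists because metric
distributions of a large gene set and a small one are only comparable at
matched sample size; it draws uniform without-replacement replicates,
reproducibly from a seed, without touching the caller's RNG state.

## What the fixture generators emulate — and what they do not

`gen_locus_set()` reproduces the *statistical structure* the selector
faces: 2–6 redundant models per locus (shorter-ORF isoforms, duplicate
homology placements, two-exon fragments, sub-60-aa ORFs), both strands,
several sequences. Two layout guarantees make the planted ground truth
exact by construction: every decoy competing for a locus is nested inside
the winner's gene span, so every covered window at the locus also
intersects the winner; and consecutive loci are separated by at least two
window widths, so loci cannot interact. `tie_mode` plants exact
ORF-length ties that must be resolved by the documented tie-breaks.
Sequence content is irrelevant to the coordinate-driven selector and is
not generated; only `gen_transcripts()` produces nucleotide sequence, for
the translation path.

Consequently, passing tests show that the implementation matches its
specification and an independent naive re-implementation on inputs of
realistic shape. They do not show that the thresholds are optimal for any
particular genome, nor how the heuristic behaves on pathological real
data (nested genes, trans-splicing, assembly artifacts) — real gene
models are not required to nest the way the generator's decoys do. The
oracle-equivalence tests cover arbitrary overlapping geometries via
unconstrained random model sets, but biological realism of those
geometries is not claimed.

`gen_busco_tables()` realizes planted pattern frequencies exactly and
decorates them with Duplicated and Fragmented rows that must not change
the presence calls. `gen_blast_tables()` plants mutual-best pairs as
strict bitscore maxima and adds the confounders that break naive RBH
implementations: one-way bests, mutual pairs just above the e-value
cutoff, extra HSP rows, and background hits that are never reverse-best.

## Numerical and degenerate-input choices

* External files are 1-based inclusive (GFF convention); internal
  arithmetic is 0-based half-open, and the conversion appears in exactly
  one pair of helpers.
* An empty input set selects nothing and discards nothing; a header-only
  GFF3 parses to an empty set; a BUSCO `Missing` row may carry only two
  columns; all readers tolerate CRLF endings and trailing blank lines.
* Malformed coordinates, unknown strand symbols, unknown BUSCO status
  literals and wrong BLAST column counts are errors that name the line;
  an exonerate file without a GFF dump section or a gene without exon
  rows degrades to a warning, since both occur in real exonerate output.
* Models lacking CDS/exon children are skipped with a warning rather than
  invented as single-exon genes.
* CDS phase is computed in translation order (right to left on the minus
  strand) when writing GFF3.
* Monotonicity of the selection under a lowered ORF threshold is checked
  as a property on generator fixtures. It is not a theorem of the greedy
  procedure for arbitrary geometries: a newly eligible short model can in
  principle be selected at a window a longer model does not reach and
  then displace it. The generator's nested-locus layout excludes this
  geometry, which is the scope of the test.

## Problem sizes

The shipped checks run the selector against a from-scratch naive
re-implementation on 1,000 generated loci (about 4,000 models), the ORF
extractor against a hand-coded six-frame enumerator on 200 transcripts of
1–2 kb, RBH detection against a double-loop oracle on 200 × 200
bipartite fixtures, idempotence on 100 seeded fixtures, and downsampling
on 10,000 replicates of 101 from 1,490 genes. These sizes make every
combinatorial path observable while keeping a full run in a couple of
minutes on one CPU.

## Known limitations

The selector neither merges isoforms nor infers UTRs, does not re-score
splice sites, and performs no ab initio prediction; it only chooses among
models it is given. GFF2/GTF input in general is out of scope (only the
exonerate dump dialect is parsed), proteins are not translated from
genomic sequence, and the BUSCO/BLAST programs themselves are never
executed — the package consumes their standard output files.
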