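# genewinnow

Evidence-based gene annotation of a draft genome typically combines two
redundant tracks: **homology models** (known proteins spliced-aligned onto
the assembly, e.g. with exonerate `protein2genome`, keeping the two best
placements per protein so duplicates are annotated) and **transcript
models** (ORFs of at least 40 aa extracted from assembled RNA-seq
transcripts and aligned back to the genome). Several isoforms and several
homology placements then describe the same locus. genewinnow consolidates
such a joint annotation into a non-redundant gene set and provides the
companion toolkit for auditing the result against universal single-copy
ortholog (BUSCO) classifications and reciprocal-best BLASTP orthology. It
targets genome annotators working on compact eukaryotic genomes (it was
designed around nematode-style gene structures) and anyone who needs to
ask whether "missing" BUSCO genes are truly absent or merely divergent.

## The consolidation heuristic

Per sequence and strand, with all coordinates 1-based:

1. every exon start and end coordinate *c* of every model is assigned to a
   window `w = floor((c - 1) / 100)` (window size 100 bp), and each
   window's **coverage** is the number of boundary features assigned to it;
2. windows are visited in order of decreasing coverage;
3. at each window, among the still-available models whose gene span
   intersects the window **and** that have ≥ 3 exons and an ORF of
   ≥ 60 aa, the model with the longest ORF is selected; every other
   still-available model overlapping the selected model's gene span is
   discarded;
4. selected models are never displaced (greedy, no backtracking).

ORF length is `floor(total CDS length / 3)` for both evidence tracks, so
homology and transcript models compete on the same scale. All ties
(window order, equal ORF lengths) break deterministically; two runs on
the same input are byte-identical. The exon/ORF thresholds suppress
inflation of gene counts by transcript fragments and noise — at the cost
of genuine short or few-exon genes, which is the documented trade-off.

The evaluation half of the package summarizes BUSCO `full_table`
classifications into a gene × genome presence/absence matrix with a
pattern tally, finds one-to-one ortholog candidates as reciprocal best
BLASTP hits (bitscore-ranked, strict e-value < 1e-4), counts how many
genes "missing in all genomes" nevertheless have an RBH partner
everywhere (detection failures of the completeness pipeline rather than
losses), and builds alignment-metric matrices — bitscore, alignment
length, percent identity, normalized bitscore (`bitscore / aln_len`) and
aligned proportion (`aln_len / query length`) — with matched
downsampling for fair comparison between gene sets of different size.

## Worked example

```r
library(genewinnow)

# a seeded fixture: 5 loci, each one intended winner plus decoy models
fx <- gen_locus_set(5, seed = 42)
fx$merged
#> <annotation_set> genome 'toy': 22 model(s), 84 exon(s)
#>   evidence: homology=17, transcript=5
#>   seqs: chrI, chrII, chrIII

res <- select_nonredundant(fx$merged)
res
#> <selection_result> 5 selected, 17 discarded (window 100 bp, ORF >= 60 aa, >= 3 exons)
#>   discard reasons: filter_exons=1, filter_orf_len=2, overlap_with_selected=14

identical(sort(res$selected$models$model_id), sort(fx$manifest$winners))
#> [1] TRUE
```

One model per locus survives: 14 decoys were discarded because they
overlap a selected model, and 3 models sitting beside the winners failed
the exon-count or ORF-length filter. `summary(res)` additionally reports
how many selected models came from each evidence track (here 3 homology,
2 transcript). `write_gff3(res$selected, "nonredundant.gff3")` writes the
result.

The evaluation side works the same way from BUSCO tables:

```r
bt <- gen_busco_tables(c("111" = 8, "011" = 3, "000" = 2), seed = 42)
pm <- presence_matrix(bt$tables)
pm$top_patterns
#>   pattern count
#> 1     111     8
#> 2     011     3
#> 3     000     2
```

Each pattern is one presence bitstring across the three genomes: 8 genes
are present everywhere, 3 are absent only from the first genome, and 2
are missing from all three — the set `rescue_missing()` then probes with
reciprocal best hits.

A command-line wrapper with subcommands `extract-orfs`, `select`,
`patterns`, `rbh`, `rescue`, `metrics` and `fixtures` ships at
`system.file("cli", "genewinnow.R", package = "genewinnow")`.

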