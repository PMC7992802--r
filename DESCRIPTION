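Package: genewinnow
Title: Non-Redundant Gene Annotation Consolidation and Ortholog Audit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Consolidates redundant evidence-based gene models (spliced
    protein-to-genome homology placements and transcript-derived open
    reading frames) into a non-redundant gene annotation using a 100 bp
    window-coverage, longest-ORF greedy heuristic, and provides the
    companion evaluation toolkit: six-frame ORF extraction from assembled
    transcripts, BUSCO full_table presence/absence pattern analysis across
    genomes, best-reciprocal BLASTP hit detection and rescue of orthologs
    the completeness pipeline misses, and alignment-metric matrices
    (bitscore, alignment length, percent identity, length-normalized
    bitscore, aligned proportion) with matched downsampling. Includes a
    seeded synthetic-fixture generator with known ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
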