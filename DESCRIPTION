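Package: clipfuse
Title: Gene Fusion Detection from RNA-Seq by Soft-Clip Clustering and Local Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene fusions, internal tandem duplications and
    non-canonical rearrangements from coordinate-sorted paired-end RNA-seq
    alignments. Candidate breakpoints are discovered from clusters of
    soft-clipped reads and from novel splice junctions, junction-informative
    reads are assembled into consensus contigs with a greedy overlap
    assembler, contigs are re-mapped to the reference with a seed-and-extend
    local aligner to resolve the partner locus, reading frame is annotated
    against refFlat gene models, and candidates are scored, graded
    (high-quality, low-quality, read-through) and ranked from read-level
    evidence and knowledge-based lists of known fusions and ITD genes.
    Includes a synthetic-fixture generator that builds a small genome, gene
    models and SAM read sets with planted fusions of all supported classes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
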