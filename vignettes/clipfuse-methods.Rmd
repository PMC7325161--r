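---
title: "Fusion detection from soft-clipped reads: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion detection from soft-clipped reads: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clipfuse)
```

This vignette documents the method implemented by `clipfuse`, the
assumptions behind it, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the procedure was genuinely open.

## The detection model

`clipfuse` assumes coordinate-sorted paired-end RNA-seq mapped by a
soft-clip-capable aligner (STAR-style local alignment) with duplicates
flagged or removed upstream. A fusion junction expressed in the sample
leaves up to four signatures: reads crossing the junction are
soft-clipped at the breakpoint; their mates may map discordantly (other
chromosome, or beyond the fragment-size bound); a mate crossing a
junction with a non-templated insertion may fail to map at all; and a
deletion small enough for the aligner's splicing model may be mapped as
a novel splice junction instead. The pipeline exploits all four.

### Breakpoint discovery

Soft-clip boundaries within 3 bp on the same side join a cluster
(single linkage: 3-bp proximity is not transitive on its own, and
single-linkage chaining is its deterministic closure). The representative position is
the boundary of the longest clip, leftmost on ties. Left- and
right-side clips cluster separately because they mark opposite junction
orientations.

Retention applies four filters with these defaults:

| parameter | default | meaning |
|---|---|---|
| `min_sc_genic` | 2 | minimum clipped reads at a genic site |
| `min_sc_intergenic` | 5 | minimum clipped reads at an intergenic site |
| `min_exp` | 0.01 | minimum `adjusted_gene_exp` at a genic site |
| `min_sc_taf` | 0.05 | soft-clip allele fraction, strict inequality |
| `cluster_window` | 3 bp | clip chaining distance |

`adjusted_gene_exp = w × read_cnt / mRNA_length` with
`w = (read_length − 20)/100` floored at zero: reads shorter than 20 bp
are effectively never soft-clipped, so short-read libraries carry less
clip evidence per unit of expression. `read_cnt` is the number of
primary alignments starting inside the gene's transcription span — a
cheap, deterministic proxy for expression that needs no quantification
step. When a cluster overlaps several genes the maximum over their
adjusted expressions is used, so a cluster inside a well-expressed gene
is never discarded because an overlapping antisense model is silent.

The allele-fraction denominator is the *local* read depth at the
cluster position, not the library size: an allelic fraction must be
local to lie in (0, 1].

Genic means anywhere inside a transcription span, introns included —
breakpoints at cryptic or intronic exons must count as genic, and
soft-clip evidence at such sites is exactly what distinguishes this
approach from exon-database methods.

### Assembly

Junction-informative reads (cluster members, their mates, discordant
pairs whose fragment projection crosses the junction, and unmapped
mates reverse-complemented onto the anchor strand) are assembled by a
greedy overlap-consensus assembler written for this package: candidate
placements come from shared exact 11-mers, overlaps must span
`asm_min_overlap = 25` bp at `asm_min_identity = 0.9`, and the
consensus is a per-column majority vote (ties broken A<C<G<T). Reads
are processed in descending length then name, making the output
deterministic and invariant to input order. The fragment-size bound
used by the discordant-projection rule is estimated as median + 3×MAD
of proper-pair inserts, since the projection needs an insert model the
procedure itself does not quantify. An external assembler could be
substituted behind the same function surface, but all tests run on the
built-in one; its consensus is not quality-weighted.

### Two-round contig mapping

Contigs are re-mapped by an in-repo seed-and-extend aligner over an
11-mer index of the reference: each (chromosome, strand, diagonal) with
a seed is extended ungapped and the maximal-scoring segment kept, with
score = matches − mismatches and `min_align_score = 25`, reporting the
top `max_hits = 3`. Round 1 maps the full contig; a contig whose
near-full length (`full_map_frac = 0.95`) maps contiguously to a locus away from bp1 is rejected as a
paralogous-mapping artifact. The remainder on the clipped side is `s2`;
round 2 maps it and prefers same-gene hits, then hits within
`proximity = 100` kb, then score — a conservative preference for local
events over gross rearrangements. Multi-mapping of `s2` is not
penalized, which is what allows discovery inside repetitive loci.

One detail matters for exactness: the boundary between the anchored
segment and `s2` is taken at the contig position that projects onto the
cluster position along the anchored hit's diagonal, not at the
alignment's end. Local alignments occasionally over-extend a few bases
past the junction by chance matches; cutting at the projected
breakpoint keeps partner coordinates exact.

Per-breakpoint repeat scores use each breakpoint's own segment aligned
separately: `repeat(p) = 1 − matches(p)/Σ matches(p_i)` over hits with
identity above 90 %. Computing it over the full contig's hit set would
give every clean two-partner fusion a repeat near 0.5, contradicting
the convention that 0 denotes unique mapping.

V(D)J-style rearrangements (both breakpoints inside configured IG/TCR
intervals with same-chromosome, same-strand geometry) are rejected;
the interval list ships with the run configuration rather than being
hard-coded.

### Splice rescue

Junctions from `N` CIGAR operations that do not match an annotated
intron exactly are rescued as deletion-type candidates when they span
at least `rescue_min_span = 10` kb, encompass at least two genes, and
their junction allele fraction (junction reads over depth at the donor,
the same local-depth convention as `SC_TAF`) exceeds
`rescue_min_taf = 0.01`. No upper span cap is imposed: any such cap
reflects aligner settings, not biology. Rescued candidates take
`w_Match = 1` (junction reads are fully mapped) and a reference-derived
contig of 100 bp per side; a junction also found through soft-clips is
merged with it (breakpoints within `merge_tol = 5` bp, unordered),
keeping the higher-scoring representative.

### Frame annotation

The contig is oriented to transcription sense and translated in three
frames. Gene B (the 3' partner) anchors first: from the breakpoint the
transcript is walked downstream to coding sequence and a 10-amino-acid
tuple of the protein is searched in the three frames. The tuple grows
by 5 AA up to 30 while it matches more than one frame (a schedule that
terminates quickly and never exhausted a fixture), and shrinks down to
5 AA near the end of a transcript. Breakpoints in the 5' UTR are
handled by translating synthetic codons from the UTR with phase
anchored at the CDS start. If the tuple search fails (e.g. a variant at
the junction), a protein-level ungapped local alignment of each frame
against the transcript protein is used instead, requiring 10 matched
residues, with the contig masked to the partner's segment so internal
single-gene events (ITDs) cannot anchor to the wrong copy. Gene A
anchors with the mirrored upstream procedure. A fusion is in-frame when
some pair of transcripts anchors both partners in the same frame —
anchoring is per-transcript, and one frame-compatible isoform pair
suffices biologically; out-of-frame when both anchor but never agree;
unknown when either partner cannot be anchored (intergenic
breakpoints). Transcripts are only used for anchoring if their CDS
translation reproduces the expected protein within 4 % mismatch
(position-wise over the shorter protein, length differences counted as
mismatches, denominator the longer length — the simplest testable
reading of a percentage mismatch tolerance).

### Scoring, grading, ranking

Evidence combines as

    score_p = w_TAF × w_Match × area × (1 − repeat)
    score   = 0.5 × (score_p(bp1) + score_p(bp2)) × ort × frame

with the piecewise weights given in the README. `area` is the *sum* of
the mapped subsequence lengths of junction reads on the contig (not the
union of covered positions): the wording "a sum of the length of all
subsequences" reads as a sum, and a sum lets the score grow with read
support, which is what makes the retention threshold `score ≥ 1`
attainable for weakly covered events. `ort` is 2 when both partners are
genic and the fused segments are strand-consistent with both genes'
transcription in one reading of the contig; an intergenic partner
leaves transcription orientation undefined and conservatively takes
`ort = 1`. Retention requires `score ≥ 1`, repeat < 0.7 and TAF ≥ 0.01
at both breakpoints; blacklisted gene pairs (recurrent
template-switching artifacts) are removed after scoring so the
diagnostics file retains their scores. Grades: HQ for matches to the
known-fusion list (unordered gene pair) or ITDs in the known-ITD genes
(FGFR1, FLT3, PDGFRA, NOTCH1, EGFR, PIK3R1, BRAF, BCOR, MYC); RT for
read-through; LQ otherwise. Default ranking is HQ, LQ, RT, by
descending score within tiers, ties broken lexicographically for
determinism; `raw_mode` ranks by score alone.

Read-through is defined here as: same strand, gene B the nearest
downstream same-strand neighbour of gene A, deletion-like geometry
within 200 kb, and *both* breakpoints at annotated exon boundaries. The
exon-boundary requirement is deliberate: a genuine genomic deletion
between two adjacent genes (the promoter-swap deletions that create
fusions like those between adjacent pseudoautosomal genes) produces
junctions at novel positions, and tagging those as read-through would
discard true drivers.

## The synthetic-data generator

`generate_reference_and_genes()` builds two contigs (≈ 49.5 kb total)
carrying up to nine multi-exon genes with valid ORFs — every transcript
passes translation verification at zero mismatch by construction — one
minus-strand gene, and an intergenic enhancer region.
`simulate_fusion_reads()` plants one event of each class with
deterministic read layouts: 100-bp paired-end reads, 250-bp fragments,
junction reads with anchored-side lengths spread over 25–75 bp so both
partner clusters form, plus concordant background pairs that set depth,
expression and allele fraction. Per-class defaults (junction reads 6 /
4 / 30 / 8 / 6 for exon-exon, lowly expressed, intergenic, ITD and
deletion-splice; background 150 / 20 / 120 / 100 / 60 fragments per
gene) were chosen once to emulate a well-expressed fusion, a weakly
expressed one near the detection floor, a strongly expressed enhancer
hijack, and mid-range ITD and deletion events; the deletion partners
sit ≈ 12 kb apart so the splice-rescue span threshold is exercised.

Reads are error-free by default (an error rate is available for
robustness tests): recovery tests demand exact breakpoints, and
sequencing noise is exercised separately in the assembler's consensus
tests. The generator does not emulate realistic expression
distributions, quality-score profiles, intron-spanning background
splicing, polyA artefacts, or alignment ambiguity from a full-size
genome — so passing tests demonstrate the correctness of the machinery
under clean mapping signatures, not end-to-end sensitivity on real
tumour libraries, where aligner behaviour and repeat content dominate.

## Numerical choices and degenerate inputs

* All internal coordinates are 1-based inclusive (the
  GRanges/Biostrings convention); refFlat's 0-based half-open
  coordinates are converted exactly once at the I/O boundary. Carrying
  0-based coordinates through a 1-based stack invites off-by-one errors
  at every call.
* Maximal-scoring segments (aligner and protein fallback) are found by
  a cumulative-sum argmax that returns the earliest segment on ties.
* Consensus ties vote A<C<G<T; assembly seeds are ordered by length
  then name; candidate ties rank by (geneA, geneB, position). Every
  tie-break is lexicographic so reruns are byte-identical.
* Empty inputs: an empty alignment file yields an empty, headered
  output table; clusters with zero depth get `SC_TAF = 0` and fail
  retention; a transcript with `mRNA_length = 0` is an error.
* When a gene has several isoforms, `mRNA_length` uses the longest
  (configurable policy slot); a breakpoint side with no soft-clip
  support of its own inherits the discovery side's junction evidence
  for TAF and area rather than dividing by a foreign depth.
* Problem sizes in the test-suite were chosen at desk scale: a ≈ 50 kb
  two-contig genome, ≈ 1500 read cohort, 200 alignment-oracle queries
  and 100 + 100 assembler trials; these exercise every code path while
  keeping the default suite fast.

## Known limitations

* The aligner is ungapped per diagonal; contigs with junction-proximal
  indels relative to the reference will anchor with a shortened match
  rather than a gapped alignment.
* CAP3-style quality-weighted consensus parameters have no analog in
  the built-in assembler.
* Expression is approximated by read-start counts, not FPKM; the
  expression filter is therefore only as comparable across genes as
  those counts are.
* Cohort-level recurrence summarization and visualization are out of
  scope; the output TSV is the interface to downstream curation.
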