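# Three-frame translation and partner anchoring.

## Build a classified exon-exon pair with `ins` bases at the junction.
fusion_pair <- function(ins = "", flankA = 99L, flankB = 150L,
                        snv_at = NULL) {
  co <- shared_cohort()
  truth <- co$truth[class == "exon-exon"]
  chrA <- as.character(co$fix$reference[["chrA"]])
  chrB <- as.character(co$fix$reference[["chrB"]])
  left <- substr(chrA, truth$posA - flankA, truth$posA)
  right <- substr(chrB, truth$posB, truth$posB + flankB - 1L)
  contig <- paste0(left, ins, right)
  if (!is.null(snv_at)) {
    p <- nchar(left) + nchar(ins) + snv_at
    base <- substr(contig, p, p)
    substr(contig, p, p) <- if (base == "A") "C" else "A"
  }
  pair <- structure(list(
    bp1 = list(chrom = "chrA", pos = truth$posA, side = "right"),
    bp2 = list(chrom = "chrB", pos = truth$posB, side = "left"),
    strand1 = "+", strand2 = "+", contig = contig,
    q_interval1 = c(1L, nchar(left)),
    q_interval2 = c(nchar(left) + nchar(ins) + 1L, nchar(contig))),
    class = "BreakpointPair")
  classify_event(pair, shared_models())
}

test_that("three-frame translation follows the codon table", {
  expect_equal(translate_three_frames("ATGGCC"), c("MA", "W", "G"))
  # 7-mer: frames hold 2, 2, 1 codons
  expect_equal(nchar(translate_three_frames("ATGGCCA")), c(2L, 2L, 1L))
  expect_equal(translate_three_frames("TAATAG")[1L], "**")
  # ambiguous bases translate to X
  expect_equal(translate_three_frames("ATGNCC")[1L], "MX")
})

test_that("a fixture CDS prefix translates to its protein prefix", {
  co <- shared_cohort()
  g <- co$fix$genes$KNWB
  cds_prefix <- substr(g$mRNA, g$utr5 + 1L, g$utr5 + 60L)
  expect_equal(translate_three_frames(cds_prefix)[1L],
               substr(g$protein, 1L, 20L))
})

test_that("a codon-phased exon-exon junction is annotated in-frame", {
  fr <- annotate_frame(fusion_pair(), shared_models())
  expect_equal(fr$status, "in-frame")
  expect_equal(fr$frame, 2L)
  expect_equal(nrow(fr$anchorsB), 1L)
  expect_equal(fr$anchorsB$method, "tuple")
  expect_equal(fr$anchorsA$frame, fr$anchorsB$frame)
})

test_that("frame parity: 3k insertions preserve status, others flip it", {
  m <- shared_models()
  for (k in 0:3) {
    for (phase in 0:2) {
      n <- 3L * k + phase
      ins <- if (n > 0L) strrep("C", n) else ""
      fr <- annotate_frame(fusion_pair(ins = ins), m)
      expected <- if (phase == 0L) "in-frame" else "out-of-frame"
      expect_equal(fr$status, expected,
                   info = sprintf("insertion of %d bases", n))
      expect_equal(fr$frame, if (phase == 0L) 2L else 1L)
    }
  }
})

test_that("an intergenic partner leaves the frame unknown", {
  co <- shared_cohort()
  truth <- co$truth[class == "intergenic"]
  chrA <- as.character(co$fix$reference[["chrA"]])
  chrB <- as.character(co$fix$reference[["chrB"]])
  left <- substr(chrB, truth$posA - 99L, truth$posA)   # enhancer side
  right <- substr(chrA, truth$posB, truth$posB + 149L) # oncogene side
  pair <- structure(list(
    bp1 = list(chrom = "chrB", pos = truth$posA, side = "right"),
    bp2 = list(chrom = "chrA", pos = truth$posB, side = "left"),
    strand1 = "+", strand2 = "+", contig = paste0(left, right),
    q_interval1 = c(1L, 100L), q_interval2 = c(101L, 250L)),
    class = "BreakpointPair")
  pair <- classify_event(pair, shared_models())
  fr <- annotate_frame(pair, shared_models())
  expect_equal(fr$status, "unknown")
  expect_equal(fr$frame, 1L)
})

test_that("a breakpoint in the 5' UTR anchors through synthetic codons", {
  co <- shared_cohort()
  m <- shared_models()
  g <- co$fix$genes$KNWB
  truth <- co$truth[class == "exon-exon"]
  chrA <- as.character(co$fix$reference[["chrA"]])
  chrB <- as.character(co$fix$reference[["chrB"]])
  utr_bp <- g$exons[1L, 1L] + 11L  # 12 nt into the 5' UTR
  left <- substr(chrA, truth$posA - 99L, truth$posA)
  right <- substr(chrB, utr_bp, utr_bp + 199L)
  pair <- structure(list(
    bp1 = list(chrom = "chrA", pos = truth$posA, side = "right"),
    bp2 = list(chrom = "chrB", pos = utr_bp, side = "left"),
    strand1 = "+", strand2 = "+", contig = paste0(left, right),
    q_interval1 = c(1L, 100L), q_interval2 = c(101L, 300L)),
    class = "BreakpointPair")
  pair <- classify_event(pair, m)
  fr <- annotate_frame(pair, m)
  expect_gte(nrow(fr$anchorsB), 1L)
  expect_true(fr$status %in% c("in-frame", "out-of-frame"))
})

test_that("a junction-proximal variant falls back to alignment anchoring", {
  fr <- annotate_frame(fusion_pair(snv_at = 5L), shared_models())
  expect_equal(fr$status, "in-frame")
  expect_equal(fr$anchorsB$method, "alignment")
})

test_that("masking restricts fallback anchoring to one contig segment", {
  co <- shared_cohort()
  g <- co$fix$genes$FLT3
  chrA <- as.character(co$fix$reference[["chrA"]])
  truth <- co$truth[class == "ITD"]
  d1 <- truth$posB; d2 <- truth$posA
  # tandem duplication with a 1-base slip: the two copies sit in
  # different codon phases on the contig
  contig <- paste0(substr(chrA, d2 - 74L, d2), "C",
                   substr(chrA, d1, d1 + 74L))
  f_first <- clipfuse:::anchor_fallback(contig, c(1L, 75L), g$protein)
  f_second <- clipfuse:::anchor_fallback(contig, c(77L, 151L), g$protein)
  expect_false(is.null(f_first))
  expect_false(is.null(f_second))
  expect_false(f_first$frame == f_second$frame)
})

test_that("frame annotation is independent of transcript iteration order", {
  # two identical transcripts of gene B anchor in the same frame; the
  # annotation must not depend on which is seen first
  co <- shared_cohort()
  rf <- tempfile(fileext = ".refflat")
  lines <- readLines(co$paths$refflat)
  dupB <- sub("TX_KNWB", "TX_KNWB2", lines[grepl("TX_KNWB", lines)])
  writeLines(c(lines, dupB), rf)
  prot <- data.table::fread(co$paths$proteins)
  prot <- rbind(prot, data.table::data.table(
    name = "TX_KNWB2", protein = prot$protein[prot$name == "TX_KNWB"]))
  pp <- tempfile(fileext = ".tsv")
  data.table::fwrite(prot, pp, sep = "\t")
  m2 <- suppressMessages(load_gene_model(rf, co$paths$reference,
                                         proteins = pp))
  pair <- fusion_pair()
  fr <- annotate_frame(pair, m2)
  expect_equal(fr$status, "in-frame")
  expect_equal(length(unique(fr$anchorsB$frame)), 1L)
})
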