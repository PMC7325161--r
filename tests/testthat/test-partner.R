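# Two-round partner resolution, proximity preference, paralog/V(D)J
# rejection and event classification.

## empty gene model over an arbitrary reference
bare_models <- function(reference, ...) {
  rf <- tempfile(fileext = ".refflat")
  writeLines(character(), rf)
  suppressMessages(load_gene_model(rf, reference, verify = FALSE, ...))
}

cluster_row <- function(chrom, pos, side) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         clip_side = side, SC_cnt = 3L,
                         members = list("r"))
}

test_that("a translocation contig resolves the planted partner exactly", {
  co <- shared_cohort()
  truth <- co$truth[co$truth$class == "exon-exon"]
  chrA <- as.character(co$fix$reference[["chrA"]])
  chrB <- as.character(co$fix$reference[["chrB"]])
  contig <- paste0(substr(chrA, truth$posA - 99L, truth$posA),
                   substr(chrB, truth$posB, truth$posB + 99L))
  pair <- resolve_partner(cluster_row("chrA", truth$posA, "right"),
                          contig, shared_models(), shared_index())
  expect_s3_class(pair, "BreakpointPair")
  expect_equal(pair$bp2$chrom, "chrB")
  expect_equal(pair$bp2$pos, truth$posB)
  expect_equal(pair$bp2$side, "left")
  expect_equal(pair$repeat1, 0)
  expect_equal(pair$repeat2, 0)
  ev <- classify_event(pair, shared_models())
  expect_equal(ev$event_type, "inter-chromosomal")
  expect_equal(ev$ort, 2L)
  expect_equal(ev$geneA, "KNWA")
  expect_equal(ev$geneB, "KNWB")
})

test_that("a contig mapping full-length to a second locus is a paralog artifact", {
  with_seed(41, {
    seg <- paste(sample(c("A", "C", "G", "T"), 150L, replace = TRUE),
                 collapse = "")
    bg <- paste(sample(c("A", "C", "G", "T"), 4000L, replace = TRUE),
                collapse = "")
    genome <- paste0(substr(bg, 1L, 1000L), seg,
                     substr(bg, 1001L, 2000L), seg,
                     substr(bg, 2001L, 4000L))
    ref <- Biostrings::DNAStringSet(c(chrP = genome))
    models <- bare_models(ref)
    idx <- build_kmer_index(ref)
    # bp1 sits inside the first copy; the full contig also maps to the
    # second (pseudogene) copy
    res <- resolve_partner(cluster_row("chrP", 1075L, "right"), seg,
                           models, idx)
    expect_s3_class(res, "PartnerRejection")
    expect_equal(res$reason, "paralog artifact")
  })
})

test_that("equal-scoring partner hits prefer the locus within 100 kb", {
  with_seed(42, {
    piece <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
    anchor <- piece(80L)
    s2 <- piece(60L)
    chrP <- paste0(piece(1000L), anchor, piece(50000L), s2, piece(2000L))
    chrQ <- paste0(piece(500L), s2, piece(500L))
    ref <- Biostrings::DNAStringSet(c(chrP = chrP, chrQ = chrQ))
    models <- bare_models(ref)
    idx <- build_kmer_index(ref)
    bp_pos <- 1080L  # end of the anchor on chrP
    contig <- paste0(anchor, s2)
    pair <- resolve_partner(cluster_row("chrP", bp_pos, "right"), contig,
                            models, idx, min_score = 25L, max_hits = 3L,
                            proximity = 1e5)
    expect_s3_class(pair, "BreakpointPair")
    expect_equal(pair$bp2$chrom, "chrP")
    expect_equal(pair$bp2$pos, 51081L)
    # the s2 match is genuinely multi-mapped but not rejected
    expect_gte(nrow(pair$hits2), 2L)
    expect_gt(pair$repeat2, 0)
  })
})

test_that("pairs inside V(D)J-style regions with deletion geometry are rejected", {
  with_seed(43, {
    piece <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
    anchor <- piece(80L); s2 <- piece(60L)
    chrP <- paste0(piece(1000L), anchor, piece(20000L), s2, piece(1000L))
    ref <- Biostrings::DNAStringSet(c(chrP = chrP))
    vdj <- GenomicRanges::GRanges("chrP", IRanges::IRanges(1L, 30000L))
    models <- bare_models(ref, vdj_regions = vdj)
    res <- resolve_partner(cluster_row("chrP", 1080L, "right"),
                           paste0(anchor, s2), models,
                           build_kmer_index(ref))
    expect_s3_class(res, "PartnerRejection")
    expect_match(res$reason, "V\\(D\\)J")
  })
})

test_that("ITD geometry is recognized: partner re-maps upstream in the same gene", {
  run <- shared_run()
  itd <- run$fusions[run$fusions$event_type == "ITD"]
  expect_equal(nrow(itd), 1L)
  expect_equal(itd$geneA, "FLT3")
  truth <- shared_cohort()$truth[class == "ITD"]
  expect_equal(itd$posA, truth$posA)
  expect_equal(itd$posB, truth$posB)
})

test_that("read-through requires adjacency and annotated exon boundaries", {
  m <- shared_models()
  g <- shared_cohort()$fix$genes
  mk_pair <- function(posA, posB) {
    structure(list(
      bp1 = list(chrom = "chrA", pos = posA, side = "right"),
      bp2 = list(chrom = "chrA", pos = posB, side = "left"),
      strand1 = "+", strand2 = "+", contig = "",
      q_interval1 = c(1L, 10L), q_interval2 = c(11L, 20L)),
      class = "BreakpointPair")
  }
  # DELB is DELA's nearest downstream same-strand neighbor; junction at
  # annotated exon end -> exon start looks like read-through
  rt <- classify_event(mk_pair(g$DELA$exons[2L, 2L],
                               g$DELB$exons[1L, 1L]), m)
  expect_equal(rt$event_type, "deletion-like")
  expect_true(rt$readthrough_flag)

  # mid-exon junction: a genomic deletion, not read-through
  del <- classify_event(mk_pair(g$DELA$exons[2L, 2L] - 37L,
                                g$DELB$exons[1L, 1L] + 11L), m)
  expect_false(del$readthrough_flag)

  # non-adjacent genes are never read-through
  far <- classify_event(mk_pair(g$KNWA$exons[3L, 2L],
                                g$DELB$exons[1L, 1L]), m)
  expect_false(far$readthrough_flag)
})

test_that("orientation multiplier reflects transcription consistency", {
  m <- shared_models()
  g <- shared_cohort()$fix$genes
  base <- list(
    bp1 = list(chrom = "chrA", pos = g$KNWA$exons[1L, 2L] - 50L,
               side = "right"),
    bp2 = list(chrom = "chrB", pos = g$KNWB$exons[1L, 1L] + 50L,
               side = "left"),
    strand1 = "+", strand2 = "+", contig = "",
    q_interval1 = c(1L, 10L), q_interval2 = c(11L, 20L))
  consistent <- classify_event(structure(base, class = "BreakpointPair"), m)
  expect_equal(consistent$ort, 2L)

  inverted <- base
  inverted$strand2 <- "-"
  inc <- classify_event(structure(inverted, class = "BreakpointPair"), m)
  expect_equal(inc$ort, 1L)
  expect_equal(inc$event_type, "inter-chromosomal")

  # an intergenic partner leaves transcription orientation undefined
  enh <- base
  enh$bp1 <- list(chrom = "chrB", pos = 11500L, side = "right")
  enh$bp2 <- list(chrom = "chrA", pos = g$ONC1$exons[1L, 1L] + 147L,
                  side = "left")
  e <- classify_event(structure(enh, class = "BreakpointPair"), m)
  expect_equal(e$ort, 1L)
})

test_that("acceptance and rejection partition resolved breakpoints", {
  co <- shared_cohort()
  m <- shared_models()
  idx <- shared_index()
  aln <- shared_aln()
  sc <- extract_softclips(aln)
  cl <- annotate_clusters(cluster_softclips(sc), aln, m)
  bps <- filter_clusters(cl, m)$retained
  for (i in seq_len(nrow(bps))) {
    reads <- collect_reads_for_breakpoint(bps[i], aln)
    contigs <- assemble_contigs(reads[, c("id", "seq")])
    for (ct in contigs) {
      res <- resolve_partner(bps[i], ct$seq, m, idx)
      expect_true(inherits(res, "BreakpointPair") ||
                    inherits(res, "PartnerRejection"))
      if (inherits(res, "PartnerRejection")) {
        expect_true(nzchar(res$reason))
      } else {
        expect_gt(nchar(res$s2), 0L)
      }
    }
  }
})
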