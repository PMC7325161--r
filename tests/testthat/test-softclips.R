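# Soft-clip extraction, 3-bp clustering, expression weighting and the
# four retention filters.

test_that("soft-clip boundaries follow CIGAR semantics", {
  sam <- tempfile(fileext = ".sam")
  write_mini_sam(sam, c(chrT = 5000L),
                 qname = c("left", "right", "none"),
                 flag = c(0L, 0L, 0L),
                 rname = "chrT",
                 pos = c(1000L, 1000L, 2000L),
                 cigar = c("30S70M", "70M30S", "100M"),
                 seq = strrep("A", 100L))
  aln <- read_alignments(sam)
  sc <- extract_softclips(aln)
  expect_equal(nrow(sc), 2L)
  left <- sc[sc$qname == "left"]
  expect_equal(left$clip_side, "left")
  expect_equal(left$clip_pos, 1000L)
  expect_equal(left$clip_len, 30L)
  right <- sc[sc$qname == "right"]
  expect_equal(right$clip_side, "right")
  expect_equal(right$clip_pos, 1069L)  # last aligned base of 70M from 1000
  expect_equal(right$clip_len, 30L)
})

test_that("secondary, supplementary and duplicate records are skipped", {
  sam <- tempfile(fileext = ".sam")
  write_mini_sam(sam, c(chrT = 5000L),
                 qname = c("pri", "sec", "sup", "dup"),
                 flag = c(0L, 256L, 2048L, 1024L),
                 rname = "chrT", pos = 1000L,
                 cigar = "30S70M", seq = strrep("C", 100L))
  sc <- extract_softclips(read_alignments(sam))
  expect_equal(sc$qname, "pri")
})

test_that("planted junction reads yield one soft-clip each", {
  co <- shared_cohort()
  sc <- extract_softclips(shared_aln())
  itd <- sc[sc$chrom == "chrA" & sc$clip_side == "right" &
              sc$clip_pos == co$truth[co$truth$class == "ITD"]$posA]
  expect_equal(nrow(itd), 4L)  # half of the 8 planted reads anchor here
})

test_that("clustering chains soft clips within 3 bp, single linkage", {
  mk <- function(pos, side = "right", len = 20L) data.table::data.table(
    qname = sprintf("r%02d", seq_along(pos)), chrom = "chrT",
    clip_pos = as.integer(pos), clip_side = side,
    clip_len = as.integer(len), read_length = 100L,
    clipped_seq = "A", mchrom = "chrT", mpos = 1L, mate_mapped = TRUE)

  chain <- cluster_softclips(mk(c(100, 102, 104)))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$SC_cnt, 3L)

  split <- cluster_softclips(mk(c(100, 104)))
  expect_equal(nrow(split), 2L)

  single <- cluster_softclips(mk(77))
  expect_equal(single$pos, 77L)
  expect_equal(single$SC_cnt, 1L)
})

test_that("cluster representative is the longest clip, leftmost on ties", {
  sc <- data.table::data.table(
    qname = c("a", "b", "c"), chrom = "chrT",
    clip_pos = c(100L, 102L, 103L), clip_side = "right",
    clip_len = c(10L, 40L, 40L), read_length = 100L,
    clipped_seq = "A", mchrom = "chrT", mpos = 1L, mate_mapped = TRUE)
  cl <- cluster_softclips(sc)
  expect_equal(cl$pos, 102L)

  # left- and right-side clips never share a cluster
  sc2 <- data.table::copy(sc)
  sc2$clip_side <- c("left", "right", "right")
  expect_equal(nrow(cluster_softclips(sc2)), 2L)
})

test_that("clustering is idempotent and order independent", {
  with_seed(3, {
    pos <- sort(sample.int(500L, 40L, replace = TRUE))
    sc <- data.table::data.table(
      qname = sprintf("r%02d", seq_along(pos)), chrom = "chrT",
      clip_pos = as.integer(pos),
      clip_side = sample(c("left", "right"), 40L, replace = TRUE),
      clip_len = sample(10:60, 40L, replace = TRUE),
      read_length = 100L, clipped_seq = "A", mchrom = "chrT",
      mpos = 1L, mate_mapped = TRUE)
    base <- cluster_softclips(sc)
    for (k in 1:5) {
      perm <- cluster_softclips(sc[sample.int(nrow(sc))])
      expect_equal(perm[, -"members"], base[, -"members"])
    }
  })
})

test_that("adjusted expression follows the read-length weighting", {
  r <- compute_adjusted_expression("G", 100L, 100L, 2000L)
  expect_equal(r$w, 0.8)
  expect_equal(r$adjusted_gene_exp, 0.04)

  expect_equal(compute_adjusted_expression("G", 50L, 20L,
                                           1000L)$adjusted_gene_exp, 0)
  expect_equal(compute_adjusted_expression("G", 0L, 120L,
                                           1000L)$adjusted_gene_exp, 0)
  # weight never negative for very short reads
  expect_equal(compute_adjusted_expression("G", 10L, 10L, 1000L)$w, 0)
  expect_error(compute_adjusted_expression("G", 10L, 100L, 0L),
               "empty transcript")
})

test_that("retention filters apply the default thresholds", {
  mk <- function(locus, cnt, taf, expq, chrom = "chrT", pos = 500L) {
    data.table::data.table(
      cluster_id = 1L, chrom = chrom, pos = pos, clip_side = "right",
      SC_cnt = as.integer(cnt), max_clip = 30L, members = list("r"),
      total_depth = 100L, SC_TAF = taf, locus_class = locus,
      genes = list(if (locus == "genic") "G" else character()),
      adjusted_gene_exp = expq)
  }
  models <- structure(list(blacklist_regions = GenomicRanges::GRanges()),
                      class = "GeneModelSet")

  keep <- filter_clusters(mk("genic", 2, 0.1, 0.04), models)
  expect_equal(nrow(keep$retained), 1L)

  few <- filter_clusters(mk("intergenic", 4, 0.5, NA), models)
  expect_equal(nrow(few$retained), 0L)
  expect_match(few$rejected$reject_reason, "intergenic")

  # SC_TAF threshold is strict: exactly 0.05 is rejected
  taf <- filter_clusters(mk("genic", 5, 0.05, 0.04), models)
  expect_equal(nrow(taf$retained), 0L)
  expect_match(taf$rejected$reject_reason, "SC_TAF")

  lowexp <- filter_clusters(mk("genic", 5, 0.2, 0.005), models)
  expect_match(lowexp$rejected$reject_reason, "adjusted_gene_exp")

  blk <- structure(list(blacklist_regions = GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(400L, 600L))), class = "GeneModelSet")
  bl <- filter_clusters(mk("genic", 5, 0.2, 0.04), blk)
  expect_match(bl$rejected$reject_reason, "blacklist")
})

test_that("filtering is a fixpoint: refiltering output changes nothing", {
  m <- shared_models()
  cl <- annotate_clusters(cluster_softclips(extract_softclips(shared_aln())),
                          shared_aln(), m)
  once <- filter_clusters(cl, m)
  twice <- filter_clusters(once$retained, m)
  expect_equal(twice$retained, once$retained)
  expect_equal(nrow(twice$rejected), 0L)
  expect_true(nrow(once$retained) + nrow(once$rejected) == nrow(cl))
})
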