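# Evidence formulas, retention thresholds, grading and ranking.

test_that("allele-fraction weight follows the piecewise definition", {
  expect_equal(weight_taf(0.01), 1)
  expect_equal(weight_taf(0.5), 1)
  expect_equal(weight_taf(0.005), exp(-2))
  expect_error(weight_taf(0), "positive")
})

test_that("match-length weight follows the piecewise definition", {
  expect_equal(weight_match(50, 100), 1)
  expect_equal(weight_match(80, 100), 1)
  expect_equal(weight_match(46, 100), exp(-2))
  expect_error(weight_match(0, 100), "positive")
  expect_error(weight_match(50, 0), "positive")
})

test_that("per-breakpoint score is the product of its factors", {
  expect_equal(score_breakpoint(1, 1, 10, 0), 10)
  expect_equal(score_breakpoint(1, 1, 10, 1), 0)
  expect_equal(score_breakpoint(0.5, 1, 4, 0.5), 1)
})

test_that("combined score halves the sum and applies both multipliers", {
  expect_equal(combine_score(1, 1, 1, 1), 1)
  expect_equal(combine_score(0, 0, 2, 2), 0)
  expect_equal(combine_score(3, 5, 2, 1), 8)
  # in-frame vs out-of-frame differs by exactly the frame multiplier
  expect_equal(combine_score(3, 5, 2, 2) / combine_score(3, 5, 2, 1), 2)
  expect_error(combine_score(1, 1, 3, 1), "ort")
  expect_error(combine_score(1, 1, 1, 0), "frame")
})

test_that("score responds monotonically to its evidence inputs", {
  with_seed(51, {
    taf <- sort(stats::runif(20, 1e-4, 0.05))
    expect_true(all(diff(weight_taf(taf)) >= 0))
    ml <- sort(sample(1:100, 20))
    expect_true(all(diff(weight_match(ml, 100)) >= 0))
    rep_scores <- sort(stats::runif(20, 0, 0.99))
    expect_true(all(diff(score_breakpoint(1, 1, 10, rep_scores)) <= 0))
    # linearity: doubling both partner scores doubles the total
    sp <- stats::runif(20, 0, 100)
    expect_equal(combine_score(2 * sp, 2 * sp, 2, 2),
                 2 * combine_score(sp, sp, 2, 2))
  })
})

test_that("area sums the mapped subsequence lengths of junction reads", {
  with_seed(52, {
    contig <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                    collapse = "")
    r1 <- substr(contig, 1L, 100L)
    r2 <- substr(contig, 60L, 159L)
    expect_equal(compute_area(contig, c(r1, r2)), 200L)
    expect_equal(compute_area(contig, character()), 0L)
    # read matching over only 75 of its 100 bases contributes 75
    junk <- paste(rep("A", 25L), collapse = "")
    partial <- paste0(substr(contig, 40L, 114L), junk)
    expect_equal(compute_area(contig, partial), 75L)
    # reverse-complemented reads still map
    expect_equal(compute_area(contig, revcomp(r1)), 100L)
  })
})

test_that("retention keeps exactly the candidates passing all thresholds", {
  mk <- function(score, repA, repB, tafA, tafB,
                 geneA = "G1", geneB = "G2") {
    data.table::data.table(geneA = geneA, geneB = geneB, score = score,
                           repeat_A = repA, repeat_B = repB,
                           TAF_A = tafA, TAF_B = tafB)
  }
  pass <- apply_retention_filters(mk(1, 0, 0, 0.01, 0.01))
  expect_equal(nrow(pass$retained), 1L)

  low <- apply_retention_filters(mk(0.9, 0, 0, 0.5, 0.5))
  expect_match(low$rejected$reject_reason, "score")

  # repeat threshold is strict: exactly 0.7 is rejected
  rep7 <- apply_retention_filters(mk(10, 0.7, 0, 0.5, 0.5))
  expect_match(rep7$rejected$reject_reason, "repetitive")

  taf <- apply_retention_filters(mk(10, 0, 0, 0.5, 0.005))
  expect_match(taf$rejected$reject_reason, "TAF")

  bl <- apply_retention_filters(mk(10, 0, 0, 0.5, 0.5),
                                fusion_blacklist = "G1|G2")
  expect_match(bl$rejected$reject_reason, "blacklist")
})

test_that("retention partitions a randomized candidate set exactly", {
  with_seed(53, {
    n <- 200L
    cand <- data.table::data.table(
      geneA = "GA", geneB = "GB",
      score = stats::runif(n, 0, 3),
      repeat_A = stats::runif(n, 0, 1), repeat_B = stats::runif(n, 0, 1),
      TAF_A = stats::runif(n, 0, 0.05), TAF_B = stats::runif(n, 0, 0.05))
    res <- apply_retention_filters(cand)
    manual <- cand$score >= 1 & cand$repeat_A < 0.7 & cand$repeat_B < 0.7 &
      cand$TAF_A >= 0.01 & cand$TAF_B >= 0.01
    expect_equal(nrow(res$retained), sum(manual))
    expect_equal(nrow(res$retained) + nrow(res$rejected), n)
    expect_equal(res$retained$score, cand$score[manual])
  })
})

test_that("grading ranks HQ before LQ before RT; raw mode by score alone", {
  models <- structure(list(known_fusions = pair_key("KA", "KB"),
                           itd_genes = "FLT3"), class = "GeneModelSet")
  cand <- data.table::data.table(
    geneA = c("KA", "NOV1", "RT1", "FLT3"),
    geneB = c("KB", "NOV2", "RT2", "FLT3"),
    event_type = c("inter-chromosomal", "inter-chromosomal",
                   "deletion-like", "ITD"),
    readthrough_flag = c(FALSE, FALSE, TRUE, FALSE),
    score = c(2, 50, 80, 1.5), posA = 1:4)
  ranked <- grade_and_rank(cand, models)
  # default order: HQ tier first despite lower scores, RT last
  expect_equal(ranked$geneA, c("KA", "FLT3", "NOV1", "RT1"))
  expect_equal(ranked$grade, c("HQ", "HQ", "LQ", "RT"))
  expect_equal(ranked$rank, 1:4)

  raw <- grade_and_rank(cand, models, raw_mode = TRUE)
  expect_equal(raw$geneA, c("RT1", "NOV1", "KA", "FLT3"))

  single <- grade_and_rank(cand[2L], models)
  expect_equal(single$rank, 1L)
})
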