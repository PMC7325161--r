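# Evidence-based scoring, retention filtering, quality grading and
# ranking of fusion candidates.

#' Allele-fraction weight
#'
#' `w_TAF = 1` when `TAF >= 0.01`, else `exp(-0.01 / TAF)`.
#'
#' @param TAF transcript allele fraction(s), strictly positive
#' @return weight(s) in (0, 1]
#' @export
weight_taf <- function(TAF) {
  if (any(TAF <= 0)) stop("TAF must be positive")
  ifelse(TAF >= 0.01, 1, exp(-0.01 / TAF))
}

#' Matched contig-length weight
#'
#' `w_Match = 1` when `match_length >= 0.5 * read_length`, else
#' `exp((match_length - 0.5 * read_length) / 2)`.
#'
#' @param match_length matched contig length at the breakpoint (bp)
#' @param read_length sample read length (bp)
#' @return weight(s) in (0, 1]
#' @export
weight_match <- function(match_length, read_length) {
  if (any(match_length <= 0) || any(read_length <= 0)) {
    stop("match_length and read_length must be positive")
  }
  ifelse(match_length >= 0.5 * read_length, 1,
         exp((match_length - 0.5 * read_length) / 2))
}

#' Per-breakpoint evidence score
#'
#' `score_p = w_TAF * w_Match * area * (1 - repeat)`.
#'
#' @param w_TAF,w_Match weights from [weight_taf()], [weight_match()]
#' @param area junction-read coverage of the contig (see [compute_area()])
#' @param repeat_score repeat score in [0, 1]
#' @return numeric score(s)
#' @export
score_breakpoint <- function(w_TAF, w_Match, area, repeat_score) {
  w_TAF * w_Match * area * (1 - repeat_score)
}

#' Combined fusion score
#'
#' `score = 0.5 * (score_p(bp1) + score_p(bp2)) * ort * frame`, where
#' `ort` is 2 for orientation-consistent fusions (else 1) and `frame`
#' is 2 for in-frame fusions (else 1).
#'
#' @param score_p1,score_p2 per-breakpoint scores
#' @param ort orientation multiplier, 1 or 2
#' @param frame frame multiplier, 1 or 2
#' @return combined score(s)
#' @export
combine_score <- function(score_p1, score_p2, ort, frame) {
  if (!all(ort %in% c(1, 2))) stop("ort must be 1 or 2")
  if (!all(frame %in% c(1, 2))) stop("frame must be 1 or 2")
  0.5 * (score_p1 + score_p2) * ort * frame
}

#' Junction-read coverage of a fusion contig
#'
#' The sum over junction-supporting reads of the length of the read
#' subsequence that maps to the contig (best ungapped local placement
#' in either orientation; reads with no placement of at least
#' `min_matches` matched bases contribute 0).
#'
#' @param contig consensus sequence
#' @param read_seqs character vector of junction read sequences
#' @param min_matches minimum matched bases for a placement to count
#' @return total aligned length in bases
#' @export
compute_area <- function(contig, read_seqs, min_matches = 15L) {
  if (length(read_seqs) == 0L) return(0L)
  ci <- dna_to_int(contig)
  total <- 0L
  for (s in read_seqs) {
    best <- 0L
    for (orient in c(FALSE, TRUE)) {
      ri <- dna_to_int(if (orient) revcomp(s) else s)
      la <- length(ri); lb <- length(ci)
      if (la == 0L || lb == 0L) next
      for (dg in (1L - la):(lb - 1L)) {
        a1 <- max(1L, 1L - dg); a2 <- min(la, lb - dg)
        if (a2 < a1) next
        av <- ri[a1:a2]; bv <- ci[(a1 + dg):(a2 + dg)]
        v <- ifelse(av == bv & av > 0L, 1, -1)
        seg <- max_subarray(v)
        seglen <- seg$end - seg$start + 1L
        m <- as.integer((seg$score + seglen) / 2L)
        if (m >= min_matches && seglen > best) best <- seglen
      }
    }
    total <- total + best
  }
  total
}

#' Apply candidate retention thresholds
#'
#' Retains candidates with combined `score >= 1`, repeat score of both
#' breakpoints strictly below 0.7, and TAF at both breakpoints at least
#' 0.01. Pairs on the fusion blacklist are removed here (after scoring,
#' so diagnostics keep their scores).
#'
#' @param candidates data.table with score, repeat_A, repeat_B, TAF_A,
#'   TAF_B, geneA, geneB columns
#' @param fusion_blacklist character vector of "GENEA|GENEB" keys
#' @param min_score,max_repeat,min_taf thresholds
#' @return list(retained, rejected) with a `reject_reason` on rejected
#' @export
apply_retention_filters <- function(candidates, fusion_blacklist = character(),
                                    min_score = 1, max_repeat = 0.7,
                                    min_taf = 0.01) {
  if (nrow(candidates) == 0L) {
    return(list(retained = candidates,
                rejected = cbind(candidates,
                                 data.table(reject_reason = character()))))
  }
  reason <- rep("", nrow(candidates))
  reason[candidates$score < min_score] <- "score below minimum"
  hi_rep <- reason == "" & (candidates$repeat_A >= max_repeat |
                              candidates$repeat_B >= max_repeat)
  reason[hi_rep] <- "repetitive mapping"
  lo_taf <- reason == "" & (candidates$TAF_A < min_taf |
                              candidates$TAF_B < min_taf)
  reason[lo_taf] <- "TAF below minimum"
  bl <- reason == "" &
    pair_key(candidates$geneA, candidates$geneB) %in% fusion_blacklist
  reason[bl] <- "blacklisted fusion pair"
  keep <- reason == ""
  rejected <- candidates[!keep]
  if (nrow(rejected)) rejected[, reject_reason := reason[!keep]]
  else rejected <- cbind(rejected, data.table(reject_reason = character()))
  list(retained = candidates[keep], rejected = rejected)
}

#' Grade and rank retained candidates
#'
#' Grades: HQ for matches to known fusion pairs or ITD events in known
#' ITD genes; RT for read-through events not graded HQ; LQ otherwise.
#' Default ranking orders HQ, then LQ, then RT, by descending score
#' within each tier; `raw_mode` ranks by score alone. Ties break on
#' (geneA, geneB, posA) for determinism.
#'
#' @param candidates scored candidate table
#' @param models GeneModelSet (supplies known_fusions and itd_genes)
#' @param raw_mode rank by fusion score alone, ignoring grade tiers
#' @return candidates with `grade` and `rank` columns, ordered by rank
#' @export
grade_and_rank <- function(candidates, models, raw_mode = FALSE) {
  if (nrow(candidates) == 0L) {
    out <- data.table::copy(candidates)
    if (!"grade" %in% names(out)) out[, grade := character()]
    if (!"rank" %in% names(out)) out[, rank := integer()]
    return(out)
  }
  cand <- data.table::copy(candidates)
  known <- pair_key(cand$geneA, cand$geneB) %in% models$known_fusions
  itd <- cand$event_type == "ITD" &
    (cand$geneA %in% models$itd_genes | cand$geneB %in% models$itd_genes)
  cand[, grade := ifelse(known | itd, "HQ",
                         ifelse(readthrough_flag, "RT", "LQ"))]
  tier <- match(cand$grade, c("HQ", "LQ", "RT"))
  if (raw_mode) {
    ord <- order(-cand$score, cand$geneA, cand$geneB, cand$posA)
  } else {
    ord <- order(tier, -cand$score, cand$geneA, cand$geneB, cand$posA)
  }
  cand <- cand[ord]
  cand[, rank := seq_len(.N)]
  cand[]
}
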