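# Partner-locus resolution: two-round contig mapping, s2 extraction,
# 100-kb proximity preference, paralog/V(D)J exclusion, and event
# classification (ITD, read-through, orientation multiplier).

#' Resolve the partner breakpoint of a candidate from its contig
#'
#' Round 1 maps the full contig: a contig whose (near-)full length maps
#' contiguously to a single locus away from bp1 is discarded as a
#' paralogous-mapping artifact. Otherwise the contig portion not mapped
#' to bp1 (`s2`, on the clipped side) is mapped in round 2; among its
#' hits the partner is chosen preferring same-gene loci, then loci within
#' `proximity` of bp1, then alignment score. Multi-mapping of s2 is not
#' penalized. Pairs with both breakpoints inside blacklisted paralogous
#' regions, or matching V(D)J recombination geometry, are rejected.
#'
#' @param bp one-row candidate cluster (chrom, pos, clip_side)
#' @param contig assembled consensus sequence
#' @param models GeneModelSet
#' @param index KmerIndex of the reference
#' @param min_score,max_hits alignment parameters (defaults 25, 3)
#' @param proximity bp2 proximity preference radius in bp (default 1e5)
#' @param full_map_frac contig fraction that counts as "full length"
#'   for the paralog-artifact rejection (default 0.95)
#' @param tol breakpoint matching tolerance in bp
#' @return a list of class `BreakpointPair`, or a list of class
#'   `PartnerRejection` with a `reason`
#' @export
resolve_partner <- function(bp, contig, models, index,
                            min_score = 25L, max_hits = 3L,
                            proximity = 1e5, full_map_frac = 0.95,
                            tol = 5L) {
  reject <- function(reason) {
    structure(list(bp1 = list(chrom = bp$chrom, pos = bp$pos,
                              side = bp$clip_side),
                   contig = contig, reason = reason),
              class = "PartnerRejection")
  }
  L <- nchar(contig)
  hits1 <- align_contig(contig, index, min_score = min_score,
                        max_hits = max_hits)
  if (nrow(hits1) == 0L) return(reject("contig unmapped"))
  on_bp1 <- hits1$chrom == bp$chrom &
    hits1$ref_start - tol <= bp$pos & hits1$ref_end + tol >= bp$pos
  full_elsewhere <- !on_bp1 & (hits1$q_end - hits1$q_start + 1L) >=
    full_map_frac * L
  if (any(full_elsewhere)) return(reject("paralog artifact"))
  if (!any(on_bp1)) return(reject("bp1 not supported by contig mapping"))
  hit1 <- hits1[which(on_bp1)[1L]]
  if (hit1$strand == "-") {
    # orient the contig to the bp1 reference strand and retry once
    bp_flip <- bp
    bp_flip$clip_side <- bp$clip_side
    flipped <- resolve_partner(
      bp_flip, revcomp(contig), models, index, min_score = min_score,
      max_hits = max_hits, proximity = proximity,
      full_map_frac = full_map_frac, tol = tol)
    return(flipped)
  }

  side1 <- bp$clip_side
  # cut s2 at the contig position projecting onto bp1 along the anchored
  # hit's diagonal: the clip boundary, not the (possibly over-extended)
  # alignment end, separates the two partners
  qj <- bp$pos - (hit1$ref_start - hit1$q_start)
  if (side1 == "right") {
    s2_start <- qj + 1L; s2_end <- L
  } else {
    s2_start <- 1L; s2_end <- qj - 1L
  }
  if (s2_end < s2_start) return(reject("no partner sequence in contig"))
  s2 <- substr(contig, s2_start, s2_end)
  if (nchar(s2) < index$k) return(reject("partner sequence too short"))

  # per-breakpoint repeat/match evidence comes from each breakpoint's own
  # contig segment, so a clean two-partner fusion scores repeat = 0
  s1 <- if (side1 == "right") substr(contig, 1L, qj)
        else substr(contig, qj, L)
  hits1s <- align_contig(s1, index, min_score = min(min_score, nchar(s1)),
                         max_hits = max_hits)
  if (nrow(hits1s) == 0L) return(reject("bp1 segment unmapped"))
  on1 <- hits1s$chrom == bp$chrom & hits1s$ref_start - tol <= bp$pos &
    hits1s$ref_end + tol >= bp$pos
  hit1s <- if (any(on1)) hits1s[which(on1)[1L]] else hits1s[1L]

  hits2 <- align_contig(s2, index, min_score = min(min_score, nchar(s2)),
                        max_hits = max_hits)
  if (nrow(hits2) == 0L) return(reject("unmapped partner"))

  genes1 <- classify_locus(bp$chrom, bp$pos, models)$genes
  ls2 <- nchar(s2)
  proj <- vapply(seq_len(nrow(hits2)), function(i) {
    h <- hits2[i]
    if (side1 == "right") {
      if (h$strand == "+") h$ref_start - (h$q_start - 1L)
      else h$ref_end + (h$q_start - 1L)
    } else {
      if (h$strand == "+") h$ref_end + (ls2 - h$q_end)
      else h$ref_start - (ls2 - h$q_end)
    }
  }, numeric(1L))
  hits2 <- data.table::copy(hits2)
  hits2[, bp2_pos := as.integer(proj)]
  hits2[, same_gene := vapply(seq_len(.N), function(i) {
    g <- classify_locus(chrom[i], bp2_pos[i], models)$genes
    length(intersect(g, genes1)) > 0L
  }, logical(1L))]
  hits2[, proximal := chrom == bp$chrom & abs(bp2_pos - bp$pos) <= proximity]
  setorder(hits2, -same_gene, -proximal, -score, chrom, bp2_pos)
  hit2 <- hits2[1L]

  side2 <- if (side1 == "right") {
    if (hit2$strand == "+") "left" else "right"
  } else {
    if (hit2$strand == "+") "right" else "left"
  }

  bp1d <- list(chrom = bp$chrom, pos = bp$pos, side = side1)
  bp2d <- list(chrom = hit2$chrom, pos = hit2$bp2_pos, side = side2)

  blk <- models$blacklist_regions
  if (length(blk) && in_regions(bp1d$chrom, bp1d$pos, blk) &&
      in_regions(bp2d$chrom, bp2d$pos, blk)) {
    return(reject("both breakpoints in paralogous blacklist regions"))
  }
  vdj <- models$vdj_regions
  if (length(vdj) && in_regions(bp1d$chrom, bp1d$pos, vdj) &&
      in_regions(bp2d$chrom, bp2d$pos, vdj) &&
      bp1d$chrom == bp2d$chrom && hit2$strand == hit1$strand) {
    return(reject("V(D)J recombination geometry"))
  }

  q1 <- if (side1 == "right") c(1L, qj) else c(qj, L)
  q2 <- c(s2_start + hit2$q_start - 1L, s2_start + hit2$q_end - 1L)
  structure(list(
    bp1 = bp1d, bp2 = bp2d, contig = contig, s2 = s2,
    hit1 = hit1s, hits1 = hits1s, hit2 = hit2, hits2 = hits2,
    repeat1 = compute_repeat_score(hit1s, hits1s),
    repeat2 = compute_repeat_score(hit2, hits2),
    match1 = hit1s$matches, match2 = hit2$matches,
    strand1 = hit1s$strand, strand2 = hit2$strand,
    q_interval1 = q1, q_interval2 = q2
  ), class = "BreakpointPair")
}

## TRUE when the breakpoint's segment is the transcriptional 5' part of
## the fused product: a right-side breakpoint keeps the genomic-left
## sequence, which is 5' for a + strand gene.
is_five_prime <- function(side, gene_strand) {
  if (is.na(gene_strand)) return(side == "right")
  (side == "right" & gene_strand == "+") |
    (side == "left" & gene_strand == "-")
}

gene_strand_of <- function(models, gene) {
  sel <- which(models$transcripts$gene == gene)
  tx <- models$transcripts[sel]
  if (nrow(tx) == 0L) return(NA_character_)
  tx$strand[1L]
}

## Nearest same-strand gene starting downstream of `gene` (transcription
## order), or NA.
nearest_downstream_gene <- function(models, gene) {
  tx <- models$transcripts
  sel <- which(tx$gene == gene)
  gt <- tx[sel]
  if (nrow(gt) == 0L) return(NA_character_)
  strand <- gt$strand[1L]; chrom <- gt$chrom[1L]
  sel2 <- which(tx$chrom == chrom & tx$strand == strand &
                  tx$gene != gene)
  same <- tx[sel2]
  if (nrow(same) == 0L) return(NA_character_)
  if (strand == "+") {
    sel3 <- which(same$tx_start > max(gt$tx_end))
    cand <- same[sel3]
    if (nrow(cand) == 0L) return(NA_character_)
    cand$gene[which.min(cand$tx_start)]
  } else {
    sel3 <- which(same$tx_end < min(gt$tx_start))
    cand <- same[sel3]
    if (nrow(cand) == 0L) return(NA_character_)
    cand$gene[which.max(cand$tx_end)]
  }
}

## Is pos an annotated exon end (kind="end") or start (kind="start") of
## any transcript of `gene`?
at_exon_boundary <- function(models, gene, pos, kind) {
  sel <- which(models$transcripts$gene == gene)
  tx <- models$transcripts[sel]
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    b <- if (kind == "end") ex[, 2L] else ex[, 1L]
    if (pos %in% b) return(TRUE)
  }
  FALSE
}

#' Classify a resolved breakpoint pair
#'
#' Sets the event type (inter-chromosomal, deletion-like,
#' duplication-like, inversion-like, ITD, internal, intergenic), the
#' read-through flag, the orientation multiplier `ort`, and orients the
#' partners so that `geneA` is the transcriptional 5' partner.
#'
#' An ITD is a same-gene junction whose geometry implies a tandemly
#' duplicated segment (the partner sequence re-maps upstream of a
#' right-side breakpoint on the same strand). Read-through requires
#' same-strand adjacent genes joined deletion-like at annotated exon
#' boundaries within `rt_max_distance`. `ort` is 2 when the fused
#' segments are strand-consistent with the transcription orientation of
#' both (genic) partners, otherwise 1.
#'
#' @param pair a `BreakpointPair` from [resolve_partner()]
#' @param models GeneModelSet
#' @param rt_max_distance read-through distance cap in bp (default 2e5)
#' @return the pair with event_type, readthrough_flag, ort, geneA, geneB,
#'   strandA/strandB and five-prime bookkeeping added
#' @export
classify_event <- function(pair, models, rt_max_distance = 2e5) {
  b1 <- pair$bp1; b2 <- pair$bp2
  loc1 <- classify_locus(b1$chrom, b1$pos, models)
  loc2 <- classify_locus(b2$chrom, b2$pos, models)
  g1 <- if (length(loc1$genes)) loc1$genes[1L] else "intergenic"
  g2 <- if (length(loc2$genes)) loc2$genes[1L] else "intergenic"
  gs1 <- if (g1 == "intergenic") NA_character_ else gene_strand_of(models, g1)
  gs2 <- if (g2 == "intergenic") NA_character_ else gene_strand_of(models, g2)

  common <- intersect(loc1$genes, loc2$genes)
  dup_geom <- (b1$side == "right" & b2$pos <= b1$pos) |
    (b1$side == "left" & b2$pos >= b1$pos)

  event <- if (b1$chrom != b2$chrom) {
    "inter-chromosomal"
  } else if (!is.null(pair$strand1) && !is.null(pair$strand2) &&
             pair$strand1 != pair$strand2) {
    "inversion-like"
  } else if (length(common)) {
    if (dup_geom) "ITD" else "internal"
  } else if (g1 == "intergenic" && g2 == "intergenic") {
    "intergenic"
  } else if (dup_geom) {
    "duplication-like"
  } else {
    "deletion-like"
  }

  five1 <- is_five_prime(b1$side, gs1)
  five2 <- is_five_prime(b2$side, gs2)

  # strand concordance of each fused segment with its gene
  s1 <- pair$strand1 %||% "+"; s2 <- pair$strand2 %||% "+"
  conc1 <- if (is.na(gs1)) NA else s1 == gs1
  conc2 <- if (is.na(gs2)) NA else s2 == gs2
  ort <- if (!is.na(conc1) && !is.na(conc2) &&
             conc1 == conc2 && xor(five1, five2)) 2L else 1L

  rt <- FALSE
  if (event == "deletion-like" && g1 != "intergenic" &&
      g2 != "intergenic" && !is.na(gs1) && identical(gs1, gs2) &&
      abs(b2$pos - b1$pos) <= rt_max_distance) {
    up <- if (five1) g1 else g2
    dn <- if (five1) g2 else g1
    upbp <- if (five1) b1 else b2
    dnbp <- if (five1) b2 else b1
    nd <- nearest_downstream_gene(models, up)
    if (identical(nd, dn) &&
        at_exon_boundary(models, up, upbp$pos,
                         if (gs1 == "+") "end" else "start") &&
        at_exon_boundary(models, dn, dnbp$pos,
                         if (gs1 == "+") "start" else "end")) {
      rt <- TRUE
    }
  }

  pair$event_type <- event
  pair$readthrough_flag <- rt
  pair$ort <- ort
  pair$gene1 <- g1
  pair$gene2 <- g2
  pair$five1 <- five1
  pair$geneA <- if (five1 || !five2) g1 else g2
  pair$geneB <- if (five1 || !five2) g2 else g1
  pair
}
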