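# Reading-frame annotation: three-frame translation of the fusion contig
# and tuple-based anchoring of both partner genes, with a protein-level
# alignment fallback.

#' Translate a contig in all three forward frames
#'
#' @param contig DNA sequence (A/C/G/T/N)
#' @return character vector of 3 peptides (frames 0, 1, 2); stop codons
#'   are rendered as '*', codons containing non-ACGT bases as 'X'
#' @export
translate_three_frames <- function(contig) {
  L <- nchar(contig)
  vapply(0:2, function(f) {
    n_codon <- (L - f) %/% 3L
    if (n_codon < 1L) return("")
    sub <- substr(contig, f + 1L, f + 3L * n_codon)
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "X"))
  }, character(1L))
}

## Transcript (mRNA) coordinate of a genomic position, moved onto the
## nearest exon in the given transcript-direction when intronic.
## direction: +1 = downstream (3'), -1 = upstream (5').
tx_position_snapped <- function(t, gpos, direction) {
  tp <- genomic_to_tx(t, gpos)
  if (!is.na(tp)) return(tp)
  ex <- t$exons[[1L]]
  genomic_dir <- if (t$strand == "+") direction else -direction
  if (genomic_dir > 0L) {
    nxt <- ex[ex[, 1L] > gpos, 1L]
    if (length(nxt) == 0L) return(NA_integer_)
    genomic_to_tx(t, min(nxt))
  } else {
    prv <- ex[ex[, 2L] < gpos, 2L]
    if (length(prv) == 0L) return(NA_integer_)
    genomic_to_tx(t, max(prv))
  }
}

## Downstream amino-acid sample for gene B anchoring at a breakpoint.
## Walks from the breakpoint downstream to coding sequence; if the
## breakpoint lies in the 5' UTR, synthetic codons are translated from
## the UTR with phase anchored at the CDS start. Returns NULL when no
## coding sequence lies downstream.
geneB_aa_sample <- function(models, t, gpos) {
  tp <- tx_position_snapped(t, gpos, direction = +1L)
  if (is.na(tp)) return(NULL)
  cds <- cds_tx_bounds(t)
  P <- sub("\\*$", "", t$protein)
  if (is.na(P)) return(NULL)
  if (tp > cds[2L]) return(NULL)
  if (tp >= cds[1L]) {
    j <- ceiling((tp - cds[1L]) / 3) + 1L
    if (j > nchar(P)) return(NULL)
    return(substring(P, j))
  }
  u <- (cds[1L] - tp) %/% 3L
  synth <- ""
  if (u > 0L) {
    mrna <- transcript_mrna_seq(models, t$name)
    utr <- substr(mrna, cds[1L] - 3L * u, cds[1L] - 1L)
    synth <- as.character(Biostrings::translate(Biostrings::DNAString(utr),
                                                if.fuzzy.codon = "X"))
  }
  paste0(synth, P)
}

## Upstream amino-acid sample for gene A anchoring: residues of the
## protein encoded fully upstream of the breakpoint. NULL when the
## breakpoint precedes the CDS.
geneA_aa_sample <- function(models, t, gpos) {
  tp <- tx_position_snapped(t, gpos, direction = -1L)
  if (is.na(tp)) return(NULL)
  cds <- cds_tx_bounds(t)
  P <- sub("\\*$", "", t$protein)
  if (is.na(P)) return(NULL)
  if (tp < cds[1L]) return(NULL)
  j <- (tp - cds[1L] + 1L) %/% 3L
  j <- min(j, nchar(P))
  if (j < 1L) return(NULL)
  substr(P, 1L, j)
}

## Search a tuple taken from one end of `sample` in the three frame
## peptides; the tuple grows while found in more than one frame and
## shrinks when the sample is short. Returns list(frame, tuple_size) with
## frame in 0:2, or NULL.
search_tuple <- function(frames, sample, from = c("start", "end"),
                         tuple_size = 10L, grow = 5L, max_size = 30L,
                         min_size = 5L) {
  from <- match.arg(from)
  avail <- nchar(sample)
  if (avail < min_size) return(NULL)
  size <- min(tuple_size, avail)
  repeat {
    tup <- if (from == "start") substr(sample, 1L, size)
           else substr(sample, avail - size + 1L, avail)
    found <- which(vapply(frames, function(p) grepl(tup, p, fixed = TRUE),
                          logical(1L)))
    if (length(found) == 1L) {
      return(list(frame = found - 1L, tuple_size = size))
    }
    if (length(found) == 0L) return(NULL)
    if (size >= min(max_size, avail)) return(NULL)
    size <- min(size + grow, avail, max_size)
  }
}

## Replace contig bases outside [interval] with N so translation yields X
## there (used before the alignment fallback to restrict anchoring to one
## partner's portion of the contig).
mask_outside <- function(contig, interval) {
  L <- nchar(contig)
  s <- max(1L, interval[1L]); e <- min(L, interval[2L])
  paste0(strrep("N", s - 1L), substr(contig, s, e), strrep("N", L - e))
}

## Best ungapped protein-level local match (matches - mismatches scoring)
## between two peptides; returns the matched residue count of the best
## segment.
protein_local_matches <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  la <- length(ai); lb <- length(bi)
  if (la == 0L || lb == 0L) return(0L)
  xcode <- utf8ToInt("X")
  best <- 0L
  for (dg in (1L - la):(lb - 1L)) {
    a1 <- max(1L, 1L - dg); a2 <- min(la, lb - dg)
    if (a2 < a1) next
    av <- ai[a1:a2]; bv <- bi[(a1 + dg):(a2 + dg)]
    v <- ifelse(av == bv & av != xcode, 1, -1)
    seg <- max_subarray(v)
    if (seg$score > 0) {
      m <- as.integer((seg$score + (seg$end - seg$start + 1L)) / 2L)
      if (m > best) best <- m
    }
  }
  best
}

## Alignment-fallback anchoring: contig masked to one partner's portion,
## each frame's peptide aligned to the transcript protein; the uniquely
## best frame with >= min_aa matched residues anchors.
anchor_fallback <- function(contig, interval, protein, min_aa = 10L) {
  if (is.na(protein)) return(NULL)
  masked <- mask_outside(contig, interval)
  frames <- translate_three_frames(masked)
  scores <- vapply(frames, protein_local_matches,
                   integer(1L), b = sub("\\*$", "", protein))
  ord <- order(-scores)
  if (scores[ord[1L]] < min_aa) return(NULL)
  if (length(scores) > 1L && scores[ord[1L]] == scores[ord[2L]]) return(NULL)
  list(frame = ord[1L] - 1L, tuple_size = NA_integer_, method = "alignment")
}

## Anchor one partner gene in the three contig frames. role "B" samples
## downstream of the breakpoint, role "A" upstream. Returns a data.table
## of anchors (transcript, frame, method), possibly empty.
anchor_partner <- function(frames, contig, bp, interval, models,
                           role = c("B", "A"), tuple_size = 10L,
                           min_aa = 10L) {
  role <- match.arg(role)
  txs <- transcripts_at(models, bp$chrom, bp$pos, verified_only = TRUE)
  out <- list()
  for (i in seq_len(nrow(txs))) {
    t <- txs[i]
    sample <- if (role == "B") geneB_aa_sample(models, t, bp$pos)
              else geneA_aa_sample(models, t, bp$pos)
    if (is.null(sample) || !nzchar(sample)) next
    hit <- search_tuple(frames, sample,
                        from = if (role == "B") "start" else "end",
                        tuple_size = tuple_size)
    method <- "tuple"
    if (is.null(hit)) {
      hit <- anchor_fallback(contig, interval, t$protein, min_aa = min_aa)
      method <- "alignment"
    }
    if (!is.null(hit)) {
      out[[length(out) + 1L]] <- data.table(
        transcript = t$name, gene = t$gene, frame = hit$frame,
        method = method, tuple_size = hit$tuple_size %||% NA_integer_)
    }
  }
  if (length(out) == 0L) {
    return(data.table(transcript = character(), gene = character(),
                      frame = integer(), method = character(),
                      tuple_size = integer()))
  }
  rbindlist(out)
}

#' Annotate the reading frame of a classified breakpoint pair
#'
#' The contig is oriented to the transcription sense of the partner
#' genes and translated in three frames. The 3' partner (gene B) is
#' anchored first by searching a sample of its downstream amino-acid
#' sequence (default tuple 10 AA, grown when ambiguous, with synthetic
#' codons translated into the 5' UTR when the breakpoint precedes the
#' CDS); gene A is anchored with the corresponding upstream sample. A
#' candidate is in-frame when some pair of transcripts anchors both
#' partners in the same contig frame, out-of-frame when both anchor but
#' never agree, and unknown when either partner cannot be anchored
#' (e.g. an intergenic breakpoint).
#'
#' @param pair a classified `BreakpointPair` (after [classify_event()])
#' @param models GeneModelSet
#' @param tuple_size starting anchor tuple size in amino acids
#' @return list(status, frame_index, frame multiplier, anchorsA, anchorsB)
#'   of class `FrameAnnotation`
#' @export
annotate_frame <- function(pair, models, tuple_size = 10L) {
  unknown <- structure(list(status = "unknown", frame_index = NA_integer_,
                            frame = 1L,
                            anchorsA = NULL, anchorsB = NULL),
                       class = "FrameAnnotation")
  if (is.null(pair$gene1)) stop("pair must be classified first")
  if (pair$gene1 == "intergenic" && pair$gene2 == "intergenic") {
    return(unknown)
  }

  # orient the contig to transcription sense
  gs1 <- if (pair$gene1 == "intergenic") NA_character_
         else gene_strand_of(models, pair$gene1)
  gs2 <- if (pair$gene2 == "intergenic") NA_character_
         else gene_strand_of(models, pair$gene2)
  sense_ok <- if (!is.na(gs1)) identical(pair$strand1 %||% "+", gs1)
              else identical(pair$strand2 %||% "+", gs2)
  contig <- pair$contig
  i1 <- pair$q_interval1; i2 <- pair$q_interval2
  L <- nchar(contig)
  if (!sense_ok) {
    contig <- revcomp(contig)
    i1 <- c(L - i1[2L] + 1L, L - i1[1L] + 1L)
    i2 <- c(L - i2[2L] + 1L, L - i2[1L] + 1L)
  }
  frames <- translate_three_frames(contig)

  if (pair$five1) {
    bpA <- pair$bp1; bpB <- pair$bp2; iA <- i1; iB <- i2
  } else {
    bpA <- pair$bp2; bpB <- pair$bp1; iA <- i2; iB <- i1
  }

  anchorsB <- anchor_partner(frames, contig, bpB, iB, models, role = "B",
                             tuple_size = tuple_size)
  anchorsA <- anchor_partner(frames, contig, bpA, iA, models, role = "A",
                             tuple_size = tuple_size)
  if (nrow(anchorsB) == 0L || nrow(anchorsA) == 0L) {
    unknown$anchorsA <- anchorsA; unknown$anchorsB <- anchorsB
    return(unknown)
  }
  shared <- intersect(anchorsA$frame, anchorsB$frame)
  if (length(shared)) {
    structure(list(status = "in-frame", frame_index = shared[1L],
                   frame = 2L, anchorsA = anchorsA, anchorsB = anchorsB),
              class = "FrameAnnotation")
  } else {
    structure(list(status = "out-of-frame",
                   frame_index = anchorsB$frame[1L], frame = 1L,
                   anchorsA = anchorsA, anchorsB = anchorsB),
              class = "FrameAnnotation")
  }
}
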