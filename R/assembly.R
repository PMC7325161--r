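# Local assembly: junction-informative read collection and a greedy
# overlap-consensus assembler (exact k-mer seeds, per-column majority vote).

#' Estimate an upper fragment-size bound from proper pairs
#'
#' Median + 3*MAD of the absolute insert size of up to `n` pairs with both
#' mates mapped to the same chromosome; used to project whether a
#' discordant read's mate could extend past a junction.
#'
#' @param aln alignment table
#' @param n number of pairs to sample
#' @return fragment-size bound in bp
#' @export
estimate_fragment_bound <- function(aln, n = 10000L) {
  pairs <- aln[usable == TRUE & paired == TRUE & !mate_unmapped &
                 chrom == mchrom & first_in_pair == TRUE]
  if (nrow(pairs) == 0L) return(1000L)
  isz <- abs(pairs$mpos - pairs$pos) + pairs$read_length
  isz <- utils::head(isz, n)
  bound <- stats::median(isz) + 3 * stats::mad(isz)
  max(200L, as.integer(ceiling(bound)))
}

#' Collect junction-informative reads around a candidate breakpoint
#'
#' Gathers (a) the cluster's soft-clipped reads, (b) their paired mates,
#' (c) discordantly mapped pairs anchored within `window` of the
#' breakpoint whose fragment projection crosses the junction, and (d)
#' mapped reads near the breakpoint whose mates are unmapped, together
#' with those unmapped mates (reverse-complemented onto the anchored
#' strand). Concordant clip-free pairs carry no junction information and
#' are excluded.
#'
#' @param bp one-row cluster (chrom, pos, clip_side, members)
#' @param aln alignment table
#' @param window collection window in bp around the breakpoint
#' @param frag_bound fragment-size bound from [estimate_fragment_bound()]
#' @return data.table: id, qname, seq, evidence class
#' @export
collect_reads_for_breakpoint <- function(bp, aln, window = 1000L,
                                         frag_bound = NULL) {
  frag_bound <- frag_bound %||% estimate_fragment_bound(aln)
  members <- bp$members[[1L]]
  out <- list()

  sc_rows <- aln[usable == TRUE & qname %in% members & chrom == bp$chrom &
                   pos <= bp$pos + window & ref_end >= bp$pos - window]
  if (nrow(sc_rows)) {
    out[["sc"]] <- data.table(
      id = paste0(sc_rows$qname, "/", ifelse(sc_rows$first_in_pair, 1L, 2L)),
      qname = sc_rows$qname, seq = sc_rows$seq, class = "SC")
  }

  mate_rows <- aln[qname %in% members & mapped == TRUE &
                     !secondary & !supplementary & !duplicate]
  mate_rows <- mate_rows[!(paste0(qname, "/",
                                  ifelse(first_in_pair, 1L, 2L)) %in%
                             (out[["sc"]]$id %||% character()))]
  if (nrow(mate_rows)) {
    out[["mate"]] <- data.table(
      id = paste0(mate_rows$qname, "/",
                  ifelse(mate_rows$first_in_pair, 1L, 2L)),
      qname = mate_rows$qname, seq = mate_rows$seq, class = "mate")
  }

  near <- aln[usable == TRUE & chrom == bp$chrom &
                pos <= bp$pos + window & ref_end >= bp$pos - window]
  # discordant pairs whose mapped read's fragment projection can extend
  # past the junction on the clipped side
  disc <- near[paired == TRUE & !mate_unmapped &
                 (is.na(mchrom) | mchrom != chrom |
                    abs(mpos - pos) > frag_bound)]
  if (nrow(disc)) {
    crosses <- if (bp$clip_side == "right") {
      !disc$reverse & disc$pos <= bp$pos &
        disc$pos + frag_bound > bp$pos
    } else {
      disc$reverse & disc$ref_end >= bp$pos &
        disc$ref_end - frag_bound < bp$pos
    }
    disc <- disc[crosses]
    if (nrow(disc)) {
      ids <- paste0(disc$qname, "/", ifelse(disc$first_in_pair, 1L, 2L))
      out[["disc"]] <- data.table(id = ids, qname = disc$qname,
                                  seq = disc$seq, class = "discordant")
      partners <- aln[mapped == TRUE & !secondary & !supplementary &
                        !duplicate & qname %in% disc$qname]
      partners <- partners[!(paste0(qname, "/",
                                    ifelse(first_in_pair, 1L, 2L)) %in% ids)]
      if (nrow(partners)) {
        out[["disc_mate"]] <- data.table(
          id = paste0(partners$qname, "/",
                      ifelse(partners$first_in_pair, 1L, 2L)),
          qname = partners$qname, seq = partners$seq,
          class = "discordant")
      }
    }
  }

  anchors <- near[paired == TRUE & mate_unmapped == TRUE]
  if (nrow(anchors)) {
    out[["anchor"]] <- data.table(
      id = paste0(anchors$qname, "/",
                  ifelse(anchors$first_in_pair, 1L, 2L)),
      qname = anchors$qname, seq = anchors$seq, class = "anchor")
    unm <- aln[mapped == FALSE & qname %in% anchors$qname]
    if (nrow(unm)) {
      anchor_fwd <- !anchors$reverse[match(unm$qname, anchors$qname)]
      seqs <- ifelse(anchor_fwd,
                     vapply(unm$seq, revcomp, character(1L)),
                     unm$seq)
      out[["unmapped"]] <- data.table(
        id = paste0(unm$qname, "/u"),
        qname = unm$qname, seq = unname(seqs), class = "mate_unmapped")
    }
  }

  reads <- rbindlist(out)
  if (is.null(reads) || nrow(reads) == 0L) {
    return(data.table(id = character(), qname = character(),
                      seq = character(), class = character()))
  }
  reads <- reads[!duplicated(id)]
  setorder(reads, id)
  reads[]
}

## integer encoding of a DNA string (A=1,C=2,G=3,T=4, other=0)
dna_to_int <- function(s) {
  r <- charToRaw(s)
  v <- integer(length(r))
  v[r == charToRaw("A")] <- 1L
  v[r == charToRaw("C")] <- 2L
  v[r == charToRaw("G")] <- 3L
  v[r == charToRaw("T")] <- 4L
  v
}

int_to_dna <- function(v) {
  chartr("01234", "NACGT", paste(v, collapse = ""))
}

## k-mer start positions of `kmers` within sequence `s` (character k-mers)
kmer_offsets <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Candidate placement offsets of `read` against `cons` from shared exact
## k-mers; offset o means read base i aligns with cons base i + o.
seed_offsets <- function(cons_kmers, read, k) {
  rk <- kmer_offsets(read, k)
  if (length(rk) == 0L) return(integer())
  m <- match(rk, cons_kmers)
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(integer())
  sort(unique(m[hit] - hit))
}

## Evaluate one placement: overlap length and matches between read and
## consensus at the given offset.
eval_offset <- function(cons_int, read_int, off) {
  Lc <- length(cons_int); Lr <- length(read_int)
  r1 <- max(1L, 1L - off); r2 <- min(Lr, Lc - off)
  if (r2 < r1) return(NULL)
  ci <- cons_int[(r1 + off):(r2 + off)]
  ri <- read_int[r1:r2]
  list(overlap = r2 - r1 + 1L, matches = sum(ci == ri))
}

#' Assemble reads into consensus contigs
#'
#' Greedy overlap-consensus assembly: reads are ordered by descending
#' length then name; each unplaced read (in either orientation) is
#' evaluated against the growing consensus at placements proposed by
#' shared exact `seed_k`-mers and merged when the best overlap spans at
#' least `min_overlap` bases at identity `min_identity` or better.
#' The consensus is the per-column majority vote over all placed reads
#' (ties broken in A<C<G<T order). Reads that never overlap become their
#' own contigs. Output is deterministic and independent of input order.
#'
#' @param seqs character vector of read sequences (named or not), or a
#'   data.table with `id` and `seq` columns
#' @param min_overlap minimum overlap in bp (default 25)
#' @param min_identity minimum overlap identity (default 0.9)
#' @param seed_k exact seed length for placement proposals
#' @return list of contigs, each a list(seq, n_reads, reads, offsets)
#'   ordered by descending read support then sequence
#' @export
assemble_contigs <- function(seqs, min_overlap = 25L, min_identity = 0.9,
                             seed_k = 11L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    seqs <- seqs$seq
    names(seqs) <- ids
  }
  if (length(seqs) == 0L) return(list())
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%05d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ints <- lapply(seqs, dna_to_int)
  rcs <- lapply(seqs, revcomp)
  rints <- lapply(rcs, dna_to_int)
  unplaced <- rep(TRUE, length(seqs))
  contigs <- list()

  while (any(unplaced)) {
    seed <- which(unplaced)[1L]
    unplaced[seed] <- FALSE
    placed <- data.table(idx = seed, off = 0L, rc = FALSE)
    cons_int <- ints[[seed]]
    counts <- matrix(0L, nrow = 4L, ncol = length(cons_int))
    counts[cbind(cons_int, seq_along(cons_int))] <- 1L
    origin <- 0L  # consensus column 1 corresponds to coordinate origin+1

    repeat {
      cons_chr <- int_to_dna(cons_int)
      ck <- kmer_offsets(cons_chr, seed_k)
      best <- NULL
      for (j in which(unplaced)) {
        for (orient in c(FALSE, TRUE)) {
          rd_chr <- if (orient) rcs[[j]] else seqs[[j]]
          rd_int <- if (orient) rints[[j]] else ints[[j]]
          for (off in seed_offsets(ck, rd_chr, seed_k)) {
            ev <- eval_offset(cons_int, rd_int, off)
            if (is.null(ev) || ev$overlap < min_overlap) next
            if (ev$matches / ev$overlap < min_identity) next
            cand <- list(idx = j, off = off, rc = orient,
                         matches = ev$matches, overlap = ev$overlap)
            if (is.null(best) ||
                cand$matches > best$matches ||
                (cand$matches == best$matches &&
                   cand$overlap > best$overlap)) {
              best <- cand
            }
          }
        }
      }
      if (is.null(best)) break
      rd_int <- if (best$rc) rints[[best$idx]] else ints[[best$idx]]
      Lr <- length(rd_int)
      # grow the count matrix left/right as needed
      left_ext <- max(0L, 1L - (1L + best$off))
      right_ext <- max(0L, (Lr + best$off) - ncol(counts))
      if (left_ext > 0L) {
        counts <- cbind(matrix(0L, 4L, left_ext), counts)
        placed[, off := off + left_ext]
        best$off <- best$off + left_ext
        origin <- origin - left_ext
      }
      if (right_ext > 0L) {
        counts <- cbind(counts, matrix(0L, 4L, right_ext))
      }
      cols <- seq_len(Lr) + best$off
      keep <- rd_int > 0L
      counts[cbind(rd_int[keep], cols[keep])] <-
        counts[cbind(rd_int[keep], cols[keep])] + 1L
      placed <- rbind(placed, data.table(idx = best$idx, off = best$off,
                                         rc = best$rc))
      unplaced[best$idx] <- FALSE
      cons_int <- max.col(t(counts), ties.method = "first")
      cons_int[colSums(counts) == 0L] <- 0L
    }

    contigs[[length(contigs) + 1L]] <- list(
      seq = int_to_dna(cons_int),
      n_reads = nrow(placed),
      reads = names(seqs)[placed$idx],
      offsets = structure(placed$off, names = names(seqs)[placed$idx]),
      rc = structure(placed$rc, names = names(seqs)[placed$idx])
    )
  }
  ord <- order(-vapply(contigs, `[[`, integer(1L), "n_reads"),
               vapply(contigs, `[[`, character(1L), "seq"))
  contigs[ord]
}
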