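# Contig re-mapping: an in-repo seed(11-mer)-and-extend local aligner over
# a k-mer index of the reference, plus the repeat (multi-mapping) score.
# Scoring is matches - mismatches (ungapped), honoring a BLAT-style
# minimum score of 25.

#' Build a k-mer index of a reference
#'
#' @param reference DNAStringSet or FASTA path
#' @param k seed length (default 11)
#' @return an object of class `KmerIndex`
#' @export
build_kmer_index <- function(reference, k = 11L) {
  ref <- load_reference(reference)
  tabs <- list()
  for (chr in names(ref)) {
    s <- as.character(ref[[chr]])
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    tabs[[chr]] <- data.table(kmer = substring(s, starts, starts + k - 1L),
                              chrom = chr, pos = starts)
  }
  idx <- rbindlist(tabs)
  setkey(idx, kmer)
  structure(list(index = idx, reference = ref, k = k,
                 seqs = lapply(as.character(ref), dna_to_int)),
            class = "KmerIndex")
}

#' Align a query sequence to the reference (seed and extend)
#'
#' Exact k-mer seeds propose (chromosome, strand, diagonal) placements;
#' each diagonal is extended ungapped and the maximal-scoring segment
#' (score = matches - mismatches) is reported. Hits with score at least
#' `min_score` are returned sorted by score (descending) then genomic
#' coordinate, truncated to `max_hits`.
#'
#' @param query character sequence
#' @param index a `KmerIndex` (or reference acceptable to
#'   [build_kmer_index()], indexed on the fly)
#' @param min_score minimum alignment score (default 25)
#' @param max_hits maximum hits returned (default 3)
#' @return data.table of hits: chrom, ref_start, ref_end, strand,
#'   q_start, q_end (on the original query), matches, identity, score
#' @export
align_contig <- function(query, index, min_score = 25L, max_hits = 3L) {
  if (!is(index, "KmerIndex")) index <- build_kmer_index(index)
  k <- index$k
  empty <- data.table(chrom = character(), ref_start = integer(),
                      ref_end = integer(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      matches = integer(), identity = numeric(),
                      score = integer())
  L <- nchar(query)
  if (L < k) return(empty)
  hits <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") query else revcomp(query)
    qint <- dna_to_int(qseq)
    starts <- seq_len(L - k + 1L)
    qk <- data.table(kmer = substring(qseq, starts, starts + k - 1L),
                     qpos = starts)
    seeds <- index$index[qk, on = "kmer", nomatch = NULL]
    if (nrow(seeds) == 0L) next
    seeds[, diag := pos - qpos]
    diags <- unique(seeds[, .(chrom, diag)])
    for (i in seq_len(nrow(diags))) {
      chr <- diags$chrom[i]; dg <- diags$diag[i]
      rint <- index$seqs[[chr]]
      r1 <- max(1L, 1L + dg); r2 <- min(length(rint), L + dg)
      if (r2 < r1) next
      qs <- r1 - dg; qe <- r2 - dg
      v <- ifelse(rint[r1:r2] == qint[qs:qe] & qint[qs:qe] > 0L, 1, -1)
      seg <- max_subarray(v)
      if (seg$score < min_score) next
      sq1 <- qs + seg$start - 1L; sq2 <- qs + seg$end - 1L
      seglen <- sq2 - sq1 + 1L
      matches <- as.integer((seg$score + seglen) / 2L)
      oq1 <- if (strand == "+") sq1 else L - sq2 + 1L
      oq2 <- if (strand == "+") sq2 else L - sq1 + 1L
      hits[[length(hits) + 1L]] <- data.table(
        chrom = chr, ref_start = sq1 + dg, ref_end = sq2 + dg,
        strand = strand, q_start = oq1, q_end = oq2,
        matches = matches, identity = matches / seglen,
        score = as.integer(seg$score))
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- rbindlist(hits)
  out <- unique(out, by = c("chrom", "ref_start", "ref_end", "strand"))
  setorder(out, -score, chrom, ref_start, strand)
  utils::head(out, max_hits)
}

#' Repeat (multi-mapping) score of an alignment hit
#'
#' `repeat(p) = 1 - matches(p) / sum_i matches(p_i)` over all hits with
#' identity above 90\%. A value of 0 means unique mapping.
#'
#' @param hit one-row hit (from [align_contig()]) or its `matches` value
#' @param all_hits hit table containing `hit`
#' @param min_identity identity threshold for the hit set (strict)
#' @return repeat score in [0, 1)
#' @export
compute_repeat_score <- function(hit, all_hits, min_identity = 0.9) {
  m <- if (is.numeric(hit)) hit else hit$matches
  keep <- all_hits[all_hits$identity > min_identity]
  if (nrow(keep) == 0L) stop("no hits above identity threshold")
  total <- sum(keep$matches)
  if (total <= 0L) stop("hit set has no matched bases")
  1 - m / total
}
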