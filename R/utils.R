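# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setkey setorder rbindlist :=
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#' @param x character scalar of A/C/G/T/N bases
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#' @param n length in bases
#' @keywords internal
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Maximal-scoring contiguous segment (Kadane via cumulative sums).
## v: numeric vector of per-position scores (+1 match / -1 mismatch).
## Returns list(start, end, score); ties resolved to the earliest segment.
max_subarray <- function(v) {
  n <- length(v)
  if (n == 0L) return(list(start = 0L, end = -1L, score = -Inf))
  cs <- cumsum(v)
  prefix <- c(0, cs[-n])
  pm <- cummin(prefix)
  gains <- cs - pm
  e <- which.max(gains)
  s <- which(prefix[seq_len(e)] == pm[e])[1L]
  list(start = s, end = e, score = gains[e])
}

## Split a CIGAR string into ops and lengths.
cigar_ops <- function(cigar) {
  list(
    op  = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
    len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  )
}

## Width of the reference span consumed by each CIGAR (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

## Most common read length in an alignment table (used as the sample
## read length for expression weighting and w_Match).
modal_read_length <- function(len) {
  if (length(len) == 0L) return(100L)
  tab <- table(len)
  as.integer(names(tab)[which.max(tab)])
}

## Canonical unordered gene-pair key, e.g. "ABL1|BCR".
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
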