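# Alignment I/O: load SAM/BAM into a flat table, flag decoding, local depth.
#
# SAM text input is converted and coordinate-sorted through Rsamtools;
# BAM input must already be coordinate-sorted (the header is checked).

#' Load a SAM or BAM file into an alignment table
#'
#' Reads every record (including placed unmapped mates) and decodes the
#' FLAG bits into logical columns. Secondary, supplementary and duplicate
#' records are retained in the table but skipped by all discovery
#' operations.
#'
#' @param path a `.sam` or `.bam` file. SAM input is converted and
#'   coordinate-sorted internally; BAM input must be coordinate-sorted.
#' @return a data.table with one row per record: qname, flag, chrom, pos,
#'   strand, mapq, cigar, mchrom, mpos, seq, plus decoded flags and
#'   `ref_end` (last reference base consumed, 1-based inclusive).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam, tempfile())
    bam <- sorted
  } else {
    bam <- path
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$text
    so <- hdr[["@HD"]]
    if (is.null(so) || !any(grepl("^SO:coordinate$", so))) {
      stop("input BAM is not coordinate-sorted; sort it first ",
           "(e.g. samtools sort)")
    }
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mrnm", "mpos", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  n <- length(res$qname)
  aln <- data.table(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    strand = as.character(res$strand),
    mapq = res$mapq,
    cigar = res$cigar,
    mchrom = as.character(res$mrnm),
    mpos = res$mpos,
    seq = as.character(res$seq)
  )
  aln[, read_length := nchar(seq)]
  aln[, paired := bitwAnd(flag, 0x1L) > 0L]
  aln[, mapped := bitwAnd(flag, 0x4L) == 0L]
  aln[, mate_unmapped := bitwAnd(flag, 0x8L) > 0L]
  aln[, reverse := bitwAnd(flag, 0x10L) > 0L]
  aln[, first_in_pair := bitwAnd(flag, 0x40L) > 0L]
  aln[, secondary := bitwAnd(flag, 0x100L) > 0L]
  aln[, duplicate := bitwAnd(flag, 0x400L) > 0L]
  aln[, supplementary := bitwAnd(flag, 0x800L) > 0L]
  aln[, usable := mapped & !secondary & !supplementary & !duplicate]
  aln[, ref_end := NA_integer_]
  if (any(aln$usable)) {
    aln[usable == TRUE, ref_end := pos + cigar_ref_width(cigar) - 1L]
  }
  aln[]
}

## Number of usable reads whose reference span covers `pos`.
depth_at <- function(aln, chrom, pos) {
  sum(aln$usable & aln$chrom == chrom & aln$pos <= pos &
        aln$ref_end >= pos, na.rm = TRUE)
}

## Primary-alignment count with start inside each gene's transcription
## span (cheap deterministic expression proxy; counts both mates).
gene_read_counts <- function(aln, models) {
  tx <- models$transcripts
  genes <- unique(tx$gene)
  cnt <- integer(length(genes))
  names(cnt) <- genes
  use <- aln[usable == TRUE]
  for (g in genes) {
    gsel <- which(tx$gene == g)
    gt <- tx[gsel]
    k <- 0L
    for (i in seq_len(nrow(gt))) {
      k <- k + sum(use$chrom == gt$chrom[i] & use$pos >= gt$tx_start[i] &
                     use$pos <= gt$tx_end[i])
    }
    # transcripts of one gene overlap; count reads once via the union span
    if (nrow(gt) > 1L) {
      k <- sum(use$chrom == gt$chrom[1L] &
                 use$pos >= min(gt$tx_start) & use$pos <= max(gt$tx_end))
    }
    cnt[g] <- k
  }
  cnt
}
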