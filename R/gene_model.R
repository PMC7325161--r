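# Gene model I/O: refFlat parsing, coding-sequence verification and
# genic/intergenic locus classification.
#
# Coordinates: refFlat files are 0-based half-open; everything inside this
# package is 1-based inclusive (the GRanges/Biostrings convention). The
# conversion happens exactly once, in read_refflat()/write_refflat().

#' Default known-ITD gene symbols
#'
#' Genes with recurrent internal tandem duplications; candidates calling
#' an ITD in one of these genes are graded high-quality.
#' @export
ITD_GENES_DEFAULT <- c("FGFR1", "FLT3", "PDGFRA", "NOTCH1", "EGFR",
                       "PIK3R1", "BRAF", "BCOR", "MYC")

#' Read a refFlat (genePred, 11 column) gene model file
#'
#' @param path path to a tab-separated refFlat file with columns
#'   geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#'   exonCount, exonStarts, exonEnds (UCSC 0-based half-open coordinates).
#' @return a data.table with 1-based inclusive coordinates and a list-column
#'   `exons` holding per-transcript two-column (start, end) matrices.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stop("refFlat file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.table(gene = character(), name = character(),
                      chrom = character(), strand = character(),
                      tx_start = integer(), tx_end = integer(),
                      cds_start = integer(), cds_end = integer(),
                      exons = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) {
    stop("malformed refFlat record at line ", bad[1L], " of ", path,
         " (expected 11 tab-separated fields)")
  }
  f <- function(i) vapply(parts, `[[`, character(1L), i)
  exons <- lapply(parts, function(p) {
    es <- as.integer(strsplit(p[[10L]], ",", fixed = TRUE)[[1L]]) + 1L
    ee <- as.integer(strsplit(p[[11L]], ",", fixed = TRUE)[[1L]])
    m <- cbind(start = es, end = ee)
    m[order(m[, 1L]), , drop = FALSE]
  })
  dt <- data.table(
    gene = f(1L), name = f(2L), chrom = f(3L), strand = f(4L),
    tx_start = as.integer(f(5L)) + 1L, tx_end = as.integer(f(6L)),
    cds_start = as.integer(f(7L)) + 1L, cds_end = as.integer(f(8L)),
    exons = exons
  )
  dt
}

#' Write transcripts to a refFlat file (0-based half-open on disk)
#'
#' @param transcripts data.table as returned by [read_refflat()]
#' @param path output path
#' @export
write_refflat <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i]
    ex <- t$exons[[1L]]
    paste(t$gene, t$name, t$chrom, t$strand,
          t$tx_start - 1L, t$tx_end, t$cds_start - 1L, t$cds_end,
          nrow(ex),
          paste0(paste(ex[, 1L] - 1L, collapse = ","), ","),
          paste0(paste(ex[, 2L], collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

## Load a reference as a named DNAStringSet from a path or pass one through.
load_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  stop("reference must be a FASTA path or a DNAStringSet")
}

#' Load reference sequence and gene models into a GeneModelSet
#'
#' Builds the transcript interval index, verifies coding translations
#' against the supplied protein table, and attaches the knowledge-based
#' lists used downstream (known fusions, ITD genes, blacklists).
#'
#' @param refflat_path refFlat file path
#' @param reference FASTA path or DNAStringSet
#' @param proteins optional named character vector (transcript name ->
#'   expected amino-acid sequence), or a 2+ column TSV path with columns
#'   name, protein
#' @param known_fusions character vector of "GENEA|GENEB" pairs, a
#'   two-column data.frame, or a TSV path with columns geneA, geneB
#' @param itd_genes character vector of gene symbols with known internal
#'   tandem duplications; defaults to FGFR1, FLT3, PDGFRA, NOTCH1, EGFR,
#'   PIK3R1, BRAF, BCOR and MYC
#' @param blacklist_regions GRanges, BED path, or NULL: highly paralogous
#'   regions whose soft-clip clusters are discarded
#' @param fusion_blacklist gene pairs (same forms as `known_fusions`)
#'   removed at the retention step
#' @param vdj_regions GRanges or BED path of IG/TCR loci used by the
#'   V(D)J-recombination filter
#' @param verify verify coding translations (requires `proteins`)
#' @param isoform_policy transcript used for a gene's mRNA_length when it
#'   has several isoforms; only "longest" is implemented
#' @return an object of class `GeneModelSet`
#' @export
load_gene_model <- function(refflat_path, reference, proteins = NULL,
                            known_fusions = NULL,
                            itd_genes = ITD_GENES_DEFAULT,
                            blacklist_regions = NULL,
                            fusion_blacklist = NULL,
                            vdj_regions = NULL,
                            verify = TRUE,
                            isoform_policy = c("longest")) {
  isoform_policy <- match.arg(isoform_policy)
  ref <- load_reference(reference)
  tx <- read_refflat(refflat_path)

  missing_chrom <- !(tx$chrom %in% names(ref))
  if (any(missing_chrom)) {
    warning("skipping ", sum(missing_chrom),
            " transcript(s) on chromosomes absent from the reference: ",
            paste(unique(tx$chrom[missing_chrom]), collapse = ", "))
    tx <- tx[!missing_chrom]
  }

  tx[, mRNA_length := vapply(exons, function(m)
    sum(m[, 2L] - m[, 1L] + 1L), integer(1L))]

  prot <- read_protein_table(proteins)
  tx[, protein := prot[name]]

  if (nrow(tx)) {
    ranges <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$tx_start, tx$tx_end),
      strand = tx$strand)
    S4Vectors::mcols(ranges)$name <- tx$name
    S4Vectors::mcols(ranges)$gene <- tx$gene
  } else {
    ranges <- GenomicRanges::GRanges()
  }

  models <- structure(list(
    transcripts = tx,
    tx_ranges = ranges,
    reference = ref,
    blacklist_regions = as_granges_or_empty(blacklist_regions),
    known_fusions = read_pair_list(known_fusions),
    itd_genes = itd_genes %||% character(),
    fusion_blacklist = read_pair_list(fusion_blacklist),
    vdj_regions = as_granges_or_empty(vdj_regions),
    isoform_policy = isoform_policy
  ), class = "GeneModelSet")

  models$transcripts[, verified := NA]
  if (verify && nrow(tx)) {
    ok <- logical(nrow(tx))
    for (i in seq_len(nrow(tx))) {
      if (is.na(tx$protein[i])) { ok[i] <- NA; next }
      v <- verify_coding_translation(tx$name[i], models)
      ok[i] <- v$pass
      if (isFALSE(v$pass)) {
        message("transcript ", tx$name[i],
                " failed translation verification (",
                v$reason %||% sprintf("mismatch %.3f", v$mismatch_fraction),
                "); excluded from frame anchoring")
      }
    }
    models$transcripts[, verified := ok]
  }
  models
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$transcripts), "transcript(s),",
      length(unique(x$transcripts$gene)), "gene(s) on",
      length(x$reference), "reference sequence(s)\n")
  invisible(x)
}

read_protein_table <- function(proteins) {
  if (is.null(proteins)) return(structure(character(), names = character()))
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    dt <- data.table::fread(proteins, header = TRUE, sep = "\t",
                            colClasses = "character")
    return(structure(dt[[2L]], names = dt[[1L]]))
  }
  if (!is.null(names(proteins))) return(proteins)
  stop("proteins must be a named vector or a TSV path")
}

read_pair_list <- function(x) {
  if (is.null(x)) return(character())
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    dt <- data.table::fread(x, header = TRUE, sep = "\t",
                            colClasses = "character")
    return(unique(pair_key(dt[[1L]], dt[[2L]])))
  }
  if (is.data.frame(x)) return(unique(pair_key(x[[1L]], x[[2L]])))
  if (is.character(x)) {
    parts <- strsplit(x, "|", fixed = TRUE)
    return(unique(pair_key(vapply(parts, `[[`, "", 1L),
                           vapply(parts, `[[`, "", 2L))))
  }
  stop("unsupported gene-pair list")
}

as_granges_or_empty <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    dt <- data.table::fread(x, header = FALSE, sep = "\t")
    # BED: 0-based half-open -> 1-based inclusive
    return(GenomicRanges::GRanges(
      as.character(dt[[1L]]),
      IRanges::IRanges(as.integer(dt[[2L]]) + 1L, as.integer(dt[[3L]]))))
  }
  stop("regions must be a GRanges or a BED path")
}

## Spliced sequence of one transcript in transcription (5'->3') order.
transcript_mrna_seq <- function(models, name) {
  sel <- which(models$transcripts$name == name)
  t <- models$transcripts[sel]
  if (nrow(t) != 1L) stop("unknown transcript: ", name)
  ex <- t$exons[[1L]]
  chrseq <- models$reference[[t$chrom]]
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(chrseq, ex[i, 1L], ex[i, 2L])),
    character(1L))
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  s
}

## Map a genomic position to a 1-based mRNA coordinate (transcription
## direction). Intronic positions return NA.
genomic_to_tx <- function(t, gpos) {
  ex <- t$exons[[1L]]
  off <- NA_integer_
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L] + 1L
    if (gpos >= ex[i, 1L] && gpos <= ex[i, 2L]) {
      off <- cum + (gpos - ex[i, 1L] + 1L)
      break
    }
    cum <- cum + w
  }
  if (is.na(off)) return(NA_integer_)
  if (t$strand == "-") off <- t$mRNA_length - off + 1L
  off
}

## CDS bounds in mRNA coordinates: c(start, end), 1-based inclusive.
cds_tx_bounds <- function(t) {
  a <- genomic_to_tx(t, t$cds_start)
  b <- genomic_to_tx(t, t$cds_end)
  sort(c(a, b))
}

#' Verify that a transcript's CDS translates to its expected protein
#'
#' The spliced CDS is translated de novo and compared position-wise with
#' the expected protein; a transcript passes when the amino-acid mismatch
#' fraction is at most `max_mismatch` (default 4\%). Length differences
#' count as mismatches; the denominator is the longer of the two proteins.
#'
#' @param name transcript accession present in `models`
#' @param models a GeneModelSet
#' @param max_mismatch maximum tolerated mismatch fraction
#' @param protein override the expected protein (defaults to the one
#'   loaded with the model)
#' @return list(pass, mismatch_fraction, reason)
#' @export
verify_coding_translation <- function(name, models, max_mismatch = 0.04,
                                      protein = NULL) {
  sel <- which(models$transcripts$name == name)
  t <- models$transcripts[sel]
  if (nrow(t) != 1L) stop("unknown transcript: ", name)
  expected <- protein %||% t$protein
  if (is.null(expected) || is.na(expected)) {
    stop("transcript ", name, " has no expected protein")
  }
  mrna <- transcript_mrna_seq(models, name)
  b <- cds_tx_bounds(t)
  cds <- substr(mrna, b[1L], b[2L])
  if (nchar(cds) %% 3L != 0L) {
    return(list(pass = FALSE, mismatch_fraction = 1, reason = "incomplete CDS"))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  expected <- sub("\\*$", "", expected)
  mf <- mismatch_fraction(aa, expected)
  list(pass = mf <= max_mismatch, mismatch_fraction = mf, reason = NULL)
}

## Position-wise mismatch fraction over min(length); the length difference
## is counted as additional mismatches; denominator is max(length).
mismatch_fraction <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (max(na, nb) == 0L) return(0)
  n <- min(na, nb)
  mm <- if (n > 0L) {
    sum(charToRaw(substr(a, 1L, n)) != charToRaw(substr(b, 1L, n)))
  } else 0L
  (mm + abs(na - nb)) / max(na, nb)
}

#' Classify a genomic position as genic or intergenic
#'
#' A position is genic when it falls inside the transcription span
#' (including introns) of at least one transcript.
#'
#' @param chrom reference name
#' @param pos 1-based position
#' @param models a GeneModelSet
#' @return list(class = "genic"|"intergenic", genes = character vector)
#' @export
classify_locus <- function(chrom, pos, models) {
  if (!(chrom %in% names(models$reference)) &&
      !(chrom %in% as.character(
        GenomicRanges::seqnames(models$tx_ranges)))) {
    warning("unknown chromosome '", chrom, "'; classified intergenic")
    return(list(class = "intergenic", genes = character()))
  }
  if (length(models$tx_ranges) == 0L) {
    return(list(class = "intergenic", genes = character()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, models$tx_ranges,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(list(class = "intergenic",
                                      genes = character()))
  genes <- unique(S4Vectors::mcols(models$tx_ranges)$gene[
    S4Vectors::subjectHits(hits)])
  list(class = "genic", genes = sort(genes))
}

## All transcript rows overlapping a position (ignoring strand).
transcripts_at <- function(models, chrom, pos, verified_only = FALSE) {
  tx <- models$transcripts
  sel <- tx$chrom == chrom & tx$tx_start <= pos & tx$tx_end >= pos
  if (verified_only) sel <- sel & (is.na(tx$verified) | tx$verified)
  tx[sel][order(name)]
}

## mRNA length of a gene under the isoform policy (longest isoform).
gene_mrna_length <- function(models, gene) {
  sel <- which(models$transcripts$gene == gene)
  tx <- models$transcripts[sel]
  if (nrow(tx) == 0L) return(NA_integer_)
  max(tx$mRNA_length)
}
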