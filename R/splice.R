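# Splice-junction rescue: deletion-type fusions whose junction reads were
# mapped as (novel) splice junctions rather than soft-clips.

#' Harvest novel splice junctions from spliced alignments
#'
#' Collects every N CIGAR operation of usable reads as a junction
#' (donor = last aligned base before the gap, acceptor = first aligned
#' base after it), drops junctions that exactly match an annotated
#' intron, and aggregates read support per junction.
#'
#' @param aln alignment table
#' @param models GeneModelSet
#' @return data.table: chrom, donor_pos, acceptor_pos, span,
#'   junction_read_cnt, junction_TAF, genes_spanned (list), and member
#'   read names
#' @export
harvest_novel_junctions <- function(aln, models) {
  empty <- data.table(chrom = character(), donor_pos = integer(),
                      acceptor_pos = integer(), span = integer(),
                      junction_read_cnt = integer(),
                      junction_TAF = numeric(),
                      genes_spanned = list(), members = list())
  spliced <- aln[usable == TRUE & grepl("N", cigar, fixed = TRUE)]
  if (nrow(spliced) == 0L) return(empty)
  recs <- list()
  for (i in seq_len(nrow(spliced))) {
    co <- cigar_ops(spliced$cigar[i])
    refpos <- spliced$pos[i]
    for (j in seq_along(co$op)) {
      op <- co$op[j]; len <- co$len[j]
      if (op == "N") {
        recs[[length(recs) + 1L]] <- data.table(
          qname = spliced$qname[i], chrom = spliced$chrom[i],
          donor_pos = refpos - 1L, acceptor_pos = refpos + len)
      }
      if (op %in% c("M", "D", "N", "=", "X")) refpos <- refpos + len
    }
  }
  jx <- rbindlist(recs)[, .(junction_read_cnt = .N,
                            members = list(unique(qname))),
                        by = .(chrom, donor_pos, acceptor_pos)]

  ann <- annotated_introns(models)
  if (nrow(ann)) {
    jx <- jx[!ann, on = c("chrom", "donor_pos", "acceptor_pos")]
  }
  if (nrow(jx) == 0L) return(empty)
  jx[, span := acceptor_pos - donor_pos]
  jx[, genes_spanned := lapply(seq_len(.N), function(i) {
    sort(unique(c(classify_locus(chrom[i], donor_pos[i], models)$genes,
                  classify_locus(chrom[i], acceptor_pos[i], models)$genes)))
  })]
  jx[, junction_TAF := vapply(seq_len(.N), function(i) {
    d <- depth_at(aln, chrom[i], donor_pos[i])
    if (d > 0L) junction_read_cnt[i] / d else 0
  }, numeric(1L))]
  setorder(jx, chrom, donor_pos, acceptor_pos)
  jx[, .(chrom, donor_pos, acceptor_pos, span, junction_read_cnt,
         junction_TAF, genes_spanned, members)][]
}

## Annotated intron set (exact donor/acceptor coordinates) of a model.
annotated_introns <- function(models) {
  tx <- models$transcripts
  out <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    if (nrow(ex) < 2L) next
    out[[length(out) + 1L]] <- data.table(
      chrom = tx$chrom[i],
      donor_pos = ex[-nrow(ex), 2L],
      acceptor_pos = ex[-1L, 1L])
  }
  if (length(out) == 0L) {
    return(data.table(chrom = character(), donor_pos = integer(),
                      acceptor_pos = integer()))
  }
  unique(rbindlist(out))
}

#' Rescue fusion candidates from novel splice junctions
#'
#' Retains junctions spanning at least `min_span` bases, encompassing at
#' least two distinct genes, with junction allele fraction strictly above
#' `min_taf`, and converts them to breakpoint-pair seeds (donor = right
#' side, acceptor = left side) that flow into frame annotation and
#' scoring with the junction reads as supporting evidence.
#'
#' @param junctions from [harvest_novel_junctions()]
#' @param models GeneModelSet
#' @param min_span minimum junction span in bp (default 10000)
#' @param min_taf junction allele-fraction threshold (strict, default 0.01)
#' @return data.table of rescued seeds (possibly empty)
#' @export
rescue_candidates <- function(junctions, models, min_span = 10000L,
                              min_taf = 0.01) {
  if (nrow(junctions) == 0L) return(junctions[0L])
  keep <- junctions$span >= min_span &
    vapply(junctions$genes_spanned, length, integer(1L)) >= 2L &
    junctions$junction_TAF > min_taf
  junctions[keep]
}
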