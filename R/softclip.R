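# Breakpoint discovery: soft-clip extraction, 3-bp clustering,
# expression weighting, and the four retention filters.

#' Extract soft-clipped read ends from an alignment table
#'
#' Emits one record per soft-clipped read end of every usable (primary,
#' non-supplementary, non-duplicate, mapped) alignment. For a leading
#' S operation the clip boundary is the first aligned base (`clip_side =
#' "left"`); for a trailing S it is the last aligned base (`clip_side =
#' "right"`). Coordinates are 1-based.
#'
#' @param aln alignment table from [read_alignments()]
#' @param min_clip minimum soft-clip length in bases (default 1)
#' @return data.table: qname, chrom, clip_pos, clip_side, clip_len,
#'   read_length, clipped_seq, mate columns
#' @export
extract_softclips <- function(aln, min_clip = 1L) {
  use <- aln[usable == TRUE & !is.na(cigar)]
  out <- vector("list", 2L * nrow(use))
  k <- 0L
  for (i in seq_len(nrow(use))) {
    co <- cigar_ops(use$cigar[i])
    nop <- length(co$op)
    if (co$op[1L] == "S" && co$len[1L] >= min_clip) {
      k <- k + 1L
      out[[k]] <- data.table(
        qname = use$qname[i], chrom = use$chrom[i],
        clip_pos = use$pos[i], clip_side = "left",
        clip_len = co$len[1L], read_length = use$read_length[i],
        clipped_seq = substr(use$seq[i], 1L, co$len[1L]),
        mchrom = use$mchrom[i], mpos = use$mpos[i],
        mate_mapped = !use$mate_unmapped[i])
    }
    if (co$op[nop] == "S" && co$len[nop] >= min_clip) {
      k <- k + 1L
      out[[k]] <- data.table(
        qname = use$qname[i], chrom = use$chrom[i],
        clip_pos = use$ref_end[i], clip_side = "right",
        clip_len = co$len[nop], read_length = use$read_length[i],
        clipped_seq = substr(use$seq[i],
                             use$read_length[i] - co$len[nop] + 1L,
                             use$read_length[i]),
        mchrom = use$mchrom[i], mpos = use$mpos[i],
        mate_mapped = !use$mate_unmapped[i])
    }
  }
  if (k == 0L) {
    return(data.table(qname = character(), chrom = character(),
                      clip_pos = integer(), clip_side = character(),
                      clip_len = integer(), read_length = integer(),
                      clipped_seq = character(), mchrom = character(),
                      mpos = integer(), mate_mapped = logical()))
  }
  rbindlist(out[seq_len(k)])
}

#' Cluster soft-clipped reads into candidate breakpoints
#'
#' Single-linkage chaining: consecutive soft-clip boundaries on the same
#' chromosome and clip side within `window` bases of one another join one
#' cluster. The representative position of a cluster is the clip boundary
#' of its longest-clip member (ties broken to the leftmost).
#'
#' @param screads data.table from [extract_softclips()]
#' @param window chaining distance in bp (default 3)
#' @return data.table: cluster_id, chrom, pos, clip_side, SC_cnt, max_clip,
#'   and a list-column `members` of member read names
#' @export
cluster_softclips <- function(screads, window = 3L) {
  empty <- data.table(cluster_id = integer(), chrom = character(),
                      pos = integer(), clip_side = character(),
                      SC_cnt = integer(), max_clip = integer(),
                      members = list())
  if (nrow(screads) == 0L) return(empty)
  sc <- data.table::copy(screads)
  setorder(sc, chrom, clip_side, clip_pos, qname)
  sc[, new_cluster := c(TRUE, chrom[-1L] != chrom[-.N] |
                          clip_side[-1L] != clip_side[-.N] |
                          (clip_pos[-1L] - clip_pos[-.N]) > window)]
  sc[, cluster_id := cumsum(new_cluster)]
  sc[, .(
    chrom = chrom[1L],
    pos = {
      best <- which(clip_len == max(clip_len))
      clip_pos[best[which.min(clip_pos[best])]]
    },
    clip_side = clip_side[1L],
    SC_cnt = .N,
    max_clip = max(clip_len),
    members = list(unique(qname))
  ), by = cluster_id][]
}

#' Read-length-adjusted expression for a gene
#'
#' `adjusted_gene_exp = w * read_cnt / mRNA_length` with
#' `w = (read_length - 20) / 100`, floored at 0: a soft-clip signature
#' needs at least 20 aligned bases, so shorter reads carry no clip
#' evidence and contribute no expression weight.
#'
#' @param gene gene symbol (carried through to the record)
#' @param read_cnt reads assigned to the gene
#' @param read_length sample read length in bp
#' @param mRNA_length transcript length in bp (> 0)
#' @return list(gene, read_cnt, mRNA_length, w, adjusted_gene_exp)
#' @export
compute_adjusted_expression <- function(gene, read_cnt, read_length,
                                        mRNA_length) {
  if (is.na(mRNA_length) || mRNA_length <= 0L) stop("empty transcript")
  if (read_cnt < 0L) stop("read_cnt must be non-negative")
  w <- max(0, (read_length - 20) / 100)
  list(gene = gene, read_cnt = read_cnt, mRNA_length = mRNA_length,
       w = w, adjusted_gene_exp = w * read_cnt / mRNA_length)
}

#' Annotate soft-clip clusters with depth, allele fraction, locus class
#' and expression
#'
#' `SC_TAF` is the soft-clip transcriptional allelic fraction: member
#' count divided by the number of reads overlapping the cluster position
#' (local depth). `adjusted_gene_exp` is the maximum over genes whose
#' transcription span contains the cluster.
#'
#' @param clusters from [cluster_softclips()]
#' @param aln alignment table
#' @param models GeneModelSet
#' @param read_length sample read length; defaults to the modal length
#' @param gene_counts optional precomputed [gene_read_counts()] vector
#' @return clusters with total_depth, SC_TAF, locus_class, genes,
#'   adjusted_gene_exp columns added
#' @export
annotate_clusters <- function(clusters, aln, models, read_length = NULL,
                              gene_counts = NULL) {
  if (nrow(clusters) == 0L) {
    return(cbind(clusters,
                 data.table(total_depth = integer(), SC_TAF = numeric(),
                            locus_class = character(), genes = list(),
                            adjusted_gene_exp = numeric())))
  }
  read_length <- read_length %||%
    modal_read_length(aln$read_length[aln$usable])
  gene_counts <- gene_counts %||% gene_read_counts(aln, models)
  cl <- data.table::copy(clusters)
  depth <- integer(nrow(cl))
  lclass <- character(nrow(cl))
  genes <- vector("list", nrow(cl))
  expq <- numeric(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    depth[i] <- depth_at(aln, cl$chrom[i], cl$pos[i])
    loc <- classify_locus(cl$chrom[i], cl$pos[i], models)
    lclass[i] <- loc$class
    genes[[i]] <- loc$genes
    expq[i] <- if (loc$class == "genic") {
      max(vapply(loc$genes, function(g) {
        compute_adjusted_expression(
          g, unname(gene_counts[g]), read_length,
          gene_mrna_length(models, g))$adjusted_gene_exp
      }, numeric(1L)))
    } else NA_real_
  }
  cl[, total_depth := depth]
  cl[, SC_TAF := ifelse(depth > 0L, SC_cnt / depth, 0)]
  cl[, locus_class := lclass]
  cl[, genes := genes]
  cl[, adjusted_gene_exp := expq]
  cl[]
}

#' Apply the four soft-clip cluster retention filters
#'
#' A cluster is kept as a candidate breakpoint when (i) `SC_cnt >= 2` at a
#' genic site or `SC_cnt >= 5` at an intergenic site; (ii) for genic
#' sites, `adjusted_gene_exp >= 0.01`; (iii) the site is outside the
#' paralogous-region blacklist; and (iv) `SC_TAF` strictly exceeds 0.05.
#'
#' @param clusters annotated clusters from [annotate_clusters()]
#' @param models GeneModelSet (supplies `blacklist_regions`)
#' @param min_sc_genic,min_sc_intergenic minimum member counts
#' @param min_exp minimum adjusted expression at genic sites
#' @param min_sc_taf allele-fraction threshold (strict)
#' @return list(retained, rejected) where `rejected` carries a
#'   `reject_reason` column naming the first failing criterion
#' @export
filter_clusters <- function(clusters, models,
                            min_sc_genic = 2L, min_sc_intergenic = 5L,
                            min_exp = 0.01, min_sc_taf = 0.05) {
  if (nrow(clusters) == 0L) {
    return(list(retained = clusters,
                rejected = cbind(clusters,
                                 data.table(reject_reason = character()))))
  }
  reason <- character(nrow(clusters))
  bl <- models$blacklist_regions
  for (i in seq_len(nrow(clusters))) {
    genic <- clusters$locus_class[i] == "genic"
    if (genic && clusters$SC_cnt[i] < min_sc_genic) {
      reason[i] <- "SC_cnt below genic minimum"
    } else if (!genic && clusters$SC_cnt[i] < min_sc_intergenic) {
      reason[i] <- "SC_cnt below intergenic minimum"
    } else if (genic && (is.na(clusters$adjusted_gene_exp[i]) ||
                         clusters$adjusted_gene_exp[i] < min_exp)) {
      reason[i] <- "adjusted_gene_exp below minimum"
    } else if (length(bl) > 0L && in_regions(clusters$chrom[i],
                                             clusters$pos[i], bl)) {
      reason[i] <- "blacklisted paralogous region"
    } else if (clusters$SC_TAF[i] <= min_sc_taf) {
      reason[i] <- "SC_TAF not above minimum"
    }
  }
  keep <- reason == ""
  rejected <- clusters[!keep]
  if (nrow(rejected)) rejected[, reject_reason := reason[!keep]]
  else rejected <- cbind(rejected, data.table(reject_reason = character()))
  list(retained = clusters[keep], rejected = rejected)
}

in_regions <- function(chrom, pos, regions) {
  if (length(regions) == 0L) return(FALSE)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  length(GenomicRanges::findOverlaps(q, regions, ignore.strand = TRUE)) > 0L
}
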