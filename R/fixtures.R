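# Synthetic fixtures: a small two-contig genome with multi-exon genes
# carrying valid ORFs, an intergenic enhancer region, and paired-end SAM
# read sets with planted fusions of all supported classes
# (exon-exon, lowly expressed, intergenic/non-canonical, ITD,
# deletion-splice). Everything is deterministic given a seed.

# Fixed gene cast: symbol, chrom, strand, tx_start, exon/intron lengths.
# Exons are long (>= 400 bp) so junction-proximal read windows stay
# exonic; FLT3 is named after the ITD-positive kinase it emulates so the
# default known-ITD gene list applies.
fixture_gene_templates <- function() {
  list(
    list(symbol = "KNWA", chrom = "chrA", strand = "+", tx_start = 2001L,
         exon_lens = c(500L, 700L, 500L), intron_lens = c(300L, 300L)),
    list(symbol = "NOVA", chrom = "chrA", strand = "+", tx_start = 7001L,
         exon_lens = c(450L, 650L, 450L), intron_lens = c(250L, 250L)),
    list(symbol = "FLT3", chrom = "chrA", strand = "+", tx_start = 12001L,
         exon_lens = c(500L, 800L, 500L), intron_lens = c(300L, 300L)),
    list(symbol = "ONC1", chrom = "chrA", strand = "+", tx_start = 17001L,
         exon_lens = c(500L, 600L, 500L), intron_lens = c(200L, 200L)),
    list(symbol = "DELA", chrom = "chrA", strand = "+", tx_start = 21001L,
         exon_lens = c(600L, 600L), intron_lens = 300L),
    list(symbol = "DELB", chrom = "chrA", strand = "+", tx_start = 33501L,
         exon_lens = c(600L, 600L), intron_lens = 300L),
    list(symbol = "KNWB", chrom = "chrB", strand = "+", tx_start = 2001L,
         exon_lens = c(500L, 700L, 500L), intron_lens = c(300L, 300L)),
    list(symbol = "NOVB", chrom = "chrB", strand = "+", tx_start = 6001L,
         exon_lens = c(450L, 650L, 450L), intron_lens = c(250L, 250L)),
    list(symbol = "MINU", chrom = "chrB", strand = "-", tx_start = 9501L,
         exon_lens = c(400L, 400L), intron_lens = 200L)
  )
}

fixture_chrom_lengths <- c(chrA = 36500L, chrB = 13000L)
fixture_enhancer <- list(chrom = "chrB", start = 11200L, end = 11800L)

## Random CDS of the requested length: ATG + non-stop codons + TAA.
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_mid <- len %/% 3L - 2L
  codons <- character(n_mid)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n_mid)) {
    repeat {
      c3 <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                  collapse = "")
      if (!(c3 %in% stops)) break
    }
    codons[i] <- c3
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

## genomic coordinate of mRNA position txpos (1-based, transcript order)
fx_tx_to_genomic <- function(gene, txpos) {
  ex <- gene$exons
  if (gene$strand == "-") txpos <- gene$mRNA_length - txpos + 1L
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L] + 1L
    if (txpos <= cum + w) return(unname(ex[i, 1L] + (txpos - cum - 1L)))
    cum <- cum + w
  }
  stop("mRNA position out of range")
}

#' Genomic position of a codon boundary in a fixture gene
#'
#' @param gene a gene record from [generate_reference_and_genes()]
#' @param aa codon (amino-acid) index
#' @param which "end" for the last base of codon `aa`, "start" for the
#'   first base of codon `aa`
#' @return genomic coordinate (1-based)
#' @export
fixture_codon_pos <- function(gene, aa, which = c("end", "start")) {
  which <- match.arg(which)
  txpos <- if (which == "end") gene$utr5 + 3L * aa
           else gene$utr5 + 3L * (aa - 1L) + 1L
  fx_tx_to_genomic(gene, txpos)
}

#' Generate a synthetic reference genome and gene models
#'
#' Builds two contigs (under 50 kb total) carrying up to nine multi-exon
#' genes with valid open reading frames (every transcript passes coding
#' verification at zero mismatch by construction), plus one intergenic
#' enhancer region. Deterministic for a given seed.
#'
#' @param n_genes number of genes to place (2-9; the first `n_genes` of
#'   the fixed cast)
#' @param seed RNG seed
#' @param out_dir if non-NULL, writes genome.fa (+ .fai), genes.refflat,
#'   proteins.tsv there
#' @return list of class `FixtureSet`: reference, transcripts table,
#'   proteins, per-gene records, enhancer region, paths
#' @export
generate_reference_and_genes <- function(n_genes = 9L, seed = 1L,
                                         out_dir = NULL) {
  stopifnot(n_genes >= 2L, n_genes <= 9L)
  set.seed(seed)
  lens <- fixture_chrom_lengths
  chroms <- lapply(lens, rand_dna)

  templates <- fixture_gene_templates()[seq_len(n_genes)]
  genes <- list()
  for (tpl in templates) {
    ex_starts <- integer(length(tpl$exon_lens))
    ex_ends <- integer(length(tpl$exon_lens))
    p <- tpl$tx_start
    for (i in seq_along(tpl$exon_lens)) {
      ex_starts[i] <- p
      ex_ends[i] <- p + tpl$exon_lens[i] - 1L
      p <- ex_ends[i] + 1L
      if (i < length(tpl$exon_lens)) p <- p + tpl$intron_lens[i]
    }
    exons <- cbind(start = ex_starts, end = ex_ends)
    total <- sum(tpl$exon_lens)
    utr5 <- 60L
    cds_len <- total - utr5 - 60L
    cds_len <- cds_len - (cds_len %% 3L)
    utr3 <- total - utr5 - cds_len
    cds <- random_cds(cds_len)
    mrna <- paste0(rand_dna(utr5), cds, rand_dna(utr3))
    protein <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(cds))))

    # distribute the mRNA over exons (transcript order) and write the
    # genomic-forward pieces into the chromosome
    pieces <- character(nrow(exons))
    cum <- 0L
    order_tx <- if (tpl$strand == "+") seq_len(nrow(exons))
                else rev(seq_len(nrow(exons)))
    for (i in order_tx) {
      w <- exons[i, 2L] - exons[i, 1L] + 1L
      piece <- substr(mrna, cum + 1L, cum + w)
      cum <- cum + w
      pieces[i] <- if (tpl$strand == "+") piece else revcomp(piece)
    }
    chrseq <- chroms[[tpl$chrom]]
    for (i in seq_len(nrow(exons))) {
      substr(chrseq, exons[i, 1L], exons[i, 2L]) <- pieces[i]
    }
    # canonical-ish intron boundaries
    for (i in seq_len(nrow(exons) - 1L)) {
      substr(chrseq, exons[i, 2L] + 1L, exons[i, 2L] + 2L) <- "GT"
      substr(chrseq, exons[i + 1L, 1L] - 2L, exons[i + 1L, 1L] - 1L) <- "AG"
    }
    chroms[[tpl$chrom]] <- chrseq

    g <- tpl
    g$exons <- exons
    g$tx_end <- exons[nrow(exons), 2L]
    g$mRNA_length <- total
    g$utr5 <- utr5
    g$cds_len <- cds_len
    g$mRNA <- mrna
    g$protein <- protein
    cds_tx <- c(utr5 + 1L, utr5 + cds_len)
    gpos <- sort(c(fx_tx_to_genomic(g, cds_tx[1L]),
                   fx_tx_to_genomic(g, cds_tx[2L])))
    g$cds_start <- gpos[1L]
    g$cds_end <- gpos[2L]
    genes[[tpl$symbol]] <- g
  }

  transcripts <- rbindlist(lapply(genes, function(g) data.table(
    gene = g$symbol, name = paste0("TX_", g$symbol), chrom = g$chrom,
    strand = g$strand, tx_start = g$tx_start, tx_end = g$tx_end,
    cds_start = g$cds_start, cds_end = g$cds_end,
    exons = list(g$exons))))
  proteins <- vapply(genes, `[[`, character(1L), "protein")
  names(proteins) <- paste0("TX_", names(proteins))

  reference <- Biostrings::DNAStringSet(vapply(chroms, identity,
                                               character(1L)))
  names(reference) <- names(lens)

  fix <- structure(list(
    reference = reference, transcripts = transcripts,
    proteins = proteins, genes = genes,
    enhancer = fixture_enhancer, seed = seed, paths = NULL
  ), class = "FixtureSet")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(reference, fa, width = 70L)
    Rsamtools::indexFa(fa)
    rf <- file.path(out_dir, "genes.refflat")
    write_refflat(transcripts, rf)
    pr <- file.path(out_dir, "proteins.tsv")
    data.table::fwrite(data.table(name = names(proteins),
                                  protein = unname(proteins)),
                       pr, sep = "\t")
    fix$paths <- list(reference = fa, refflat = rf, proteins = pr)
  }
  fix
}

#' Specify a fusion event to plant in simulated reads
#'
#' Default breakpoints sit on codon boundaries inside exons of the fixed
#' gene cast, so the planted events are in-frame unless `frame_shift`
#' moves the acceptor.
#'
#' @param fix a FixtureSet (needs the genes the class uses)
#' @param class one of "exon-exon", "lowly-expressed", "intergenic",
#'   "ITD", "deletion-splice"
#' @param n_junction junction-spanning reads to plant
#' @param insertion non-templated sequence inserted at the junction
#' @param frame_shift bases added to the acceptor position (1 or 2 break
#'   the frame)
#' @param n_discordant discordant pairs across the junction
#' @param n_unmapped_pairs pairs with one unmapped junction-crossing mate
#' @param background named integer vector: concordant fragments per gene
#' @return list of class `FusionEventSpec`
#' @export
fusion_event_spec <- function(fix, class = c("exon-exon",
                                             "lowly-expressed",
                                             "intergenic", "ITD",
                                             "deletion-splice"),
                              n_junction = NULL, insertion = "",
                              frame_shift = 0L, n_discordant = NULL,
                              n_unmapped_pairs = NULL,
                              background = NULL) {
  class <- match.arg(class)
  g <- fix$genes
  spec <- switch(class,
    "exon-exon" = list(
      geneA = "KNWA", geneB = "KNWB",
      bp1 = fixture_codon_pos(g$KNWA, 100L, "end"),
      bp2 = fixture_codon_pos(g$KNWB, 30L, "start"),
      n_junction = n_junction %||% 6L,
      n_discordant = n_discordant %||% 3L,
      n_unmapped_pairs = n_unmapped_pairs %||% 2L,
      background = background %||% c(KNWA = 150L, KNWB = 150L),
      in_frame = TRUE),
    "lowly-expressed" = list(
      geneA = "NOVA", geneB = "NOVB",
      bp1 = fixture_codon_pos(g$NOVA, 90L, "end"),
      bp2 = fixture_codon_pos(g$NOVB, 25L, "start"),
      n_junction = n_junction %||% 4L,
      n_discordant = n_discordant %||% 2L,
      n_unmapped_pairs = n_unmapped_pairs %||% 0L,
      background = background %||% c(NOVA = 20L, NOVB = 20L),
      in_frame = TRUE),
    "intergenic" = list(
      geneA = "ENH", geneB = "ONC1",
      bp1 = 11500L,
      bp2 = fixture_codon_pos(g$ONC1, 30L, "start"),
      n_junction = n_junction %||% 30L,
      n_discordant = n_discordant %||% 3L,
      n_unmapped_pairs = n_unmapped_pairs %||% 0L,
      background = background %||% c(ONC1 = 120L),
      in_frame = NA),
    "ITD" = list(
      geneA = "FLT3", geneB = "FLT3",
      bp1 = fixture_codon_pos(g$FLT3, 59L, "end"),
      bp2 = fixture_codon_pos(g$FLT3, 40L, "start"),
      n_junction = n_junction %||% 8L,
      n_discordant = 0L, n_unmapped_pairs = n_unmapped_pairs %||% 0L,
      background = background %||% c(FLT3 = 100L),
      in_frame = TRUE),
    "deletion-splice" = list(
      geneA = "DELA", geneB = "DELB",
      bp1 = fixture_codon_pos(g$DELA, 100L, "end"),
      bp2 = fixture_codon_pos(g$DELB, 30L, "start"),
      n_junction = n_junction %||% 6L,
      n_discordant = 0L, n_unmapped_pairs = 0L,
      background = background %||% c(DELA = 60L, DELB = 60L),
      in_frame = TRUE)
  )
  spec$class <- class
  spec$insertion <- insertion
  spec$bp2 <- spec$bp2 + as.integer(frame_shift)
  if (frame_shift %% 3L != 0L && isTRUE(spec$in_frame)) {
    spec$in_frame <- FALSE
  }
  spec$chromA <- if (spec$geneA == "ENH") fix$enhancer$chrom
                 else g[[spec$geneA]]$chrom
  spec$chromB <- g[[spec$geneB]]$chrom
  spec$read_length <- 100L
  spec$fragment <- 250L
  structure(spec, class = c("FusionEventSpec", "list"))
}

chrom_seq <- function(fix, chrom) as.character(fix$reference[[chrom]])

sam_record <- function(qname, flag, rname, pos, mapq, cigar, rnext,
                       pnext, seq) {
  data.table(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = cigar, rnext = rnext, pnext = as.integer(pnext),
             tlen = 0L, seq = seq)
}

## Concordant 100-bp fragment pair fully inside one exon window.
background_pairs <- function(fix, gene_sym, n, prefix) {
  g <- fix$genes[[gene_sym]]
  chrseq <- chrom_seq(fix, g$chrom)
  ex <- g$exons
  windows <- ex[ex[, 2L] - ex[, 1L] + 1L >= 250L, , drop = FALSE]
  starts <- unlist(lapply(seq_len(nrow(windows)), function(i)
    seq(windows[i, 1L], windows[i, 2L] - 249L)))
  if (length(starts) == 0L || n == 0L) return(NULL)
  picks <- starts[(seq_len(n) * 37L) %% length(starts) + 1L]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- picks[i]
    r1 <- substr(chrseq, s, s + 99L)
    r2 <- substr(chrseq, s + 150L, s + 249L)
    qn <- sprintf("%s_bg%04d", prefix, i)
    out[[i]] <- rbind(
      sam_record(qn, 99L, g$chrom, s, 60L, "100M", "=", s + 150L, r1),
      sam_record(qn, 147L, g$chrom, s + 150L, 60L, "100M", "=", s, r2))
  }
  rbindlist(out)
}

#' Simulate SAM reads for one planted fusion event
#'
#' Emits paired-end reads with correct CIGARs: junction-spanning reads
#' soft-clipped at the planted breakpoint (anchored on whichever side
#' holds the longer read portion), or carrying an N gap for the
#' deletion-splice class; discordant pairs across the junction; pairs
#' with one unmapped junction-crossing mate; and concordant background
#' pairs setting depth, expression and allele fraction. Reads are
#' error-free.
#'
#' @param spec a `FusionEventSpec`
#' @param fix the FixtureSet it refers to
#' @return list(records, truth): SAM record table and one-row truth table
#' @export
simulate_fusion_reads <- function(spec, fix) {
  rl <- spec$read_length
  ins <- spec$insertion
  ni <- nchar(ins)
  seqA <- chrom_seq(fix, spec$chromA)
  seqB <- chrom_seq(fix, spec$chromB)
  a <- spec$bp1; b <- spec$bp2
  prefix <- gsub("[^A-Za-z]", "", spec$class)
  recs <- list()

  truth <- data.table(
    class = spec$class, geneA = spec$geneA, geneB = spec$geneB,
    chromA = spec$chromA, posA = a, sideA = "right",
    chromB = spec$chromB, posB = b, sideB = "left",
    frame_status = if (is.na(spec$in_frame)) "unknown"
                   else if (spec$in_frame) "in-frame" else "out-of-frame",
    n_junction = spec$n_junction)

  if (spec$n_junction > 0L && spec$class != "deletion-splice") {
    flank <- 200L
    FA <- substr(seqA, a - flank + 1L, a)
    FB <- substr(seqB, b, b + flank - 1L)
    FUS <- paste0(FA, ins, FB)
    ja <- flank  # last A base in fusion coordinates
    alens <- as.integer(round(seq(25L, 75L, length.out = spec$n_junction)))
    for (i in seq_along(alens)) {
      alen <- alens[i]
      rseq <- substr(FUS, ja - alen + 1L, ja - alen + rl)
      qn <- sprintf("%s_jx%03d", prefix, i)
      blen <- rl - alen
      if (alen >= blen) {
        pos <- a - alen + 1L
        rec <- sam_record(qn, 147L, spec$chromA, pos, 60L,
                          paste0(alen, "M", blen, "S"),
                          spec$chromA, pos - 150L, rseq)
        mate_s <- pos - 150L
        mate <- sam_record(qn, 97L, spec$chromA, mate_s, 60L, "100M",
                           spec$chromA, pos, substr(seqA, mate_s,
                                                    mate_s + 99L))
      } else {
        mlen <- blen - ni
        pos <- b
        rec <- sam_record(qn, 99L, spec$chromB, pos, 60L,
                          paste0(alen + ni, "S", mlen, "M"),
                          spec$chromB, pos + mlen + 50L, rseq)
        mate_s <- pos + mlen + 50L
        mate <- sam_record(qn, 147L, spec$chromB, mate_s, 60L, "100M",
                           spec$chromB, pos, substr(seqB, mate_s,
                                                    mate_s + 99L))
      }
      recs[[length(recs) + 1L]] <- rbind(rec, mate)
    }
    for (i in seq_len(spec$n_discordant)) {
      s1 <- a - 170L - 10L * i
      s2 <- b + 50L + 10L * i
      qn <- sprintf("%s_disc%03d", prefix, i)
      recs[[length(recs) + 1L]] <- rbind(
        sam_record(qn, 97L, spec$chromA, s1, 60L, "100M",
                   spec$chromB, s2, substr(seqA, s1, s1 + 99L)),
        sam_record(qn, 145L, spec$chromB, s2, 60L, "100M",
                   spec$chromA, s1, substr(seqB, s2, s2 + 99L)))
    }
    for (i in seq_len(spec$n_unmapped_pairs)) {
      s1 <- a - 130L - 10L * i
      qn <- sprintf("%s_unm%03d", prefix, i)
      win <- substr(FUS, ja - 20L, ja - 21L + rl)
      recs[[length(recs) + 1L]] <- rbind(
        sam_record(qn, 73L, spec$chromA, s1, 60L, "100M",
                   spec$chromA, s1, substr(seqA, s1, s1 + 99L)),
        # unmapped mate, placed at the anchor; stored as sequenced
        # (reverse-complement of the genome-forward fusion window)
        sam_record(qn, 133L, spec$chromA, s1, 0L, "*",
                   spec$chromA, s1, revcomp(win)))
    }
  }

  if (spec$class == "deletion-splice" && spec$n_junction > 0L) {
    gap <- b - a - 1L
    xs <- as.integer(round(seq(25L, 75L, length.out = spec$n_junction)))
    for (i in seq_along(xs)) {
      x <- xs[i]; y <- rl - x
      pos <- a - x + 1L
      rseq <- paste0(substr(seqA, pos, a), substr(seqB, b, b + y - 1L))
      qn <- sprintf("%s_jx%03d", prefix, i)
      mate_s <- pos - 150L
      recs[[length(recs) + 1L]] <- rbind(
        sam_record(qn, 147L, spec$chromA, pos, 60L,
                   paste0(x, "M", gap, "N", y, "M"),
                   spec$chromA, mate_s, rseq),
        sam_record(qn, 97L, spec$chromA, mate_s, 60L, "100M",
                   spec$chromA, pos, substr(seqA, mate_s, mate_s + 99L)))
    }
  }

  for (gsym in names(spec$background)) {
    recs[[length(recs) + 1L]] <-
      background_pairs(fix, gsym, spec$background[[gsym]],
                       paste0(prefix, "_", gsym))
  }

  records <- if (length(recs)) rbindlist(recs) else sam_record(
    character(), integer(), character(), integer(), integer(),
    character(), character(), integer(), character())[0L]
  list(records = records, truth = truth)
}

#' Write SAM records to a coordinate-sorted SAM file
#'
#' @param records record table from [simulate_fusion_reads()]
#' @param fix FixtureSet (for the sequence dictionary)
#' @param path output .sam path
#' @return the path, invisibly
#' @export
write_sam <- function(records, fix, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(fix$reference),
                   Biostrings::width(fix$reference)))
  chrom_order <- names(fix$reference)
  if (nrow(records)) {
    records <- records[order(match(rname, chrom_order), pos, qname)]
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, records$flag, records$rname,
                    records$pos, records$mapq, records$cigar,
                    records$rnext, records$pnext, records$tlen,
                    records$seq, strrep("I", nchar(records$seq)))
    writeLines(c(hdr, body), path)
  } else {
    writeLines(hdr, path)
  }
  invisible(path)
}

#' Generate the full fixture cohort: genome, gene models, reads, truth
#'
#' Plants one event of every requested class into a single SAM file and
#' writes genome.fa(.fai), genes.refflat, proteins.tsv, reads.sam,
#' truth.tsv and known_fusions.tsv (the exon-exon pair) under `out_dir`.
#'
#' @param out_dir output directory
#' @param seed RNG seed
#' @param classes fusion classes to plant (default: all five)
#' @return list: fix (FixtureSet), truth table, file paths
#' @export
fixture_cohort <- function(out_dir, seed = 1L,
                           classes = c("exon-exon", "lowly-expressed",
                                       "intergenic", "ITD",
                                       "deletion-splice")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fix <- generate_reference_and_genes(9L, seed = seed, out_dir = out_dir)
  recs <- list()
  truths <- list()
  for (cl in classes) {
    spec <- fusion_event_spec(fix, cl)
    sim <- simulate_fusion_reads(spec, fix)
    recs[[cl]] <- sim$records
    truths[[cl]] <- sim$truth
  }
  records <- rbindlist(recs)
  truth <- rbindlist(truths)
  sam <- file.path(out_dir, "reads.sam")
  write_sam(records, fix, sam)
  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t")
  kf <- file.path(out_dir, "known_fusions.tsv")
  data.table::fwrite(data.table(geneA = "KNWA", geneB = "KNWB"), kf,
                     sep = "\t")
  list(fix = fix, truth = truth,
       paths = c(fix$paths, list(sam = sam, truth = truth_path,
                                 known_fusions = kf)))
}
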