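# End-to-end orchestration: discover -> assemble -> map -> rescue ->
# frame -> score -> rank, with reproducible outputs.

#' Build a pipeline run configuration
#'
#' Threshold defaults: soft-clip cluster
#' window 3 bp, SC_cnt minima 2 (genic) / 5 (intergenic), adjusted
#' expression minimum 0.01, SC allele fraction 0.05 (strict), assembly
#' overlap 25 bp, alignment minimum score 25 with top 3 hits, partner
#' proximity 100 kb, splice-rescue span 10 kb and allele fraction 0.01,
#' retention score 1 / repeat 0.7 / TAF 0.01.
#'
#' @param bam SAM/BAM path
#' @param reference FASTA path or DNAStringSet
#' @param refflat refFlat gene model path
#' @param proteins protein table (see [load_gene_model()])
#' @param known_fusions,itd_genes,blacklist_regions,fusion_blacklist,vdj_regions
#'   knowledge-based lists (see [load_gene_model()])
#' @param out_dir output directory (created); NULL suppresses file output
#' @param sample sample label for the output table
#' @param seed integer seed applied at the start of the run
#' @param raw_mode rank by fusion score alone
#' @param ... threshold overrides (min_sc_genic, min_sc_intergenic,
#'   min_exp, min_sc_taf, cluster_window, min_clip, collect_window,
#'   asm_min_overlap, asm_min_identity, max_hits, min_align_score,
#'   proximity, full_map_frac, rescue_min_span, rescue_min_taf,
#'   rt_max_distance, retention_min_score, retention_max_repeat,
#'   retention_min_taf, merge_tol)
#' @return list of class `RunConfig`
#' @export
run_config <- function(bam, reference, refflat, proteins = NULL,
                       known_fusions = NULL,
                       itd_genes = ITD_GENES_DEFAULT,
                       blacklist_regions = NULL, fusion_blacklist = NULL,
                       vdj_regions = NULL, out_dir = NULL,
                       sample = basename(bam), seed = 1L,
                       raw_mode = FALSE, ...) {
  cfg <- list(
    bam = bam, reference = reference, refflat = refflat,
    proteins = proteins, known_fusions = known_fusions,
    itd_genes = itd_genes, blacklist_regions = blacklist_regions,
    fusion_blacklist = fusion_blacklist, vdj_regions = vdj_regions,
    out_dir = out_dir, sample = sample, seed = as.integer(seed),
    raw_mode = isTRUE(raw_mode),
    min_sc_genic = 2L, min_sc_intergenic = 5L, min_exp = 0.01,
    min_sc_taf = 0.05, cluster_window = 3L, min_clip = 1L,
    collect_window = 1000L, asm_min_overlap = 25L,
    asm_min_identity = 0.9, max_hits = 3L, min_align_score = 25L,
    proximity = 1e5, full_map_frac = 0.95,
    rescue_min_span = 10000L, rescue_min_taf = 0.01,
    rt_max_distance = 2e5, retention_min_score = 1,
    retention_max_repeat = 0.7, retention_min_taf = 0.01,
    merge_tol = 5L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config option(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

fusion_output_columns <- c(
  "sample", "geneA", "chrA", "posA", "sideA", "geneB", "chrB", "posB",
  "sideB", "event_type", "frame_status", "readsA", "readsB", "TAF_A",
  "TAF_B", "repeat_A", "repeat_B", "area", "score", "grade", "rank",
  "contig")

empty_candidate_table <- function() {
  data.table(sample = character(), geneA = character(), chrA = character(),
             posA = integer(), sideA = character(), geneB = character(),
             chrB = character(), posB = integer(), sideB = character(),
             event_type = character(), frame_status = character(),
             readsA = integer(), readsB = integer(), TAF_A = numeric(),
             TAF_B = numeric(), repeat_A = numeric(),
             repeat_B = numeric(), area = numeric(), score = numeric(),
             grade = character(), rank = integer(), contig = character(),
             readthrough_flag = logical(), ort = integer(),
             frame_mult = integer(), source = character())
}

## Soft-clip support near a position on one side (reads clipping within
## tol bases); returns list(n, seqs).
sc_support_at <- function(screads, chrom, pos, side, tol = 3L) {
  sel <- screads[screads$chrom == chrom & screads$clip_side == side &
                   abs(screads$clip_pos - pos) <= tol]
  aln_ids <- unique(sel$qname)
  list(n = length(aln_ids), qnames = aln_ids)
}

## Assemble one candidate row from a classified+annotated pair.
candidate_row <- function(cfg, pair, fr, evid) {
  a_first <- isTRUE(pair$five1)
  A <- if (a_first) pair$bp1 else pair$bp2
  B <- if (a_first) pair$bp2 else pair$bp1
  swap <- !a_first
  geneA <- if (swap) pair$gene2 else pair$gene1
  geneB <- if (swap) pair$gene1 else pair$gene2
  data.table(
    sample = cfg$sample,
    geneA = geneA, chrA = A$chrom, posA = A$pos, sideA = A$side,
    geneB = geneB, chrB = B$chrom, posB = B$pos, sideB = B$side,
    event_type = pair$event_type, frame_status = fr$status,
    readsA = if (swap) evid$n2 else evid$n1,
    readsB = if (swap) evid$n1 else evid$n2,
    TAF_A = if (swap) evid$taf2 else evid$taf1,
    TAF_B = if (swap) evid$taf1 else evid$taf2,
    repeat_A = if (swap) pair$repeat2 else pair$repeat1,
    repeat_B = if (swap) pair$repeat1 else pair$repeat2,
    area = (evid$area1 + evid$area2) / 2,
    score = combine_score(
      score_breakpoint(weight_taf(evid$taf1),
                       weight_match(pair$match1, evid$read_length),
                       evid$area1, pair$repeat1),
      score_breakpoint(weight_taf(evid$taf2),
                       weight_match(pair$match2, evid$read_length),
                       evid$area2, pair$repeat2),
      pair$ort, fr$frame),
    grade = NA_character_, rank = NA_integer_,
    contig = pair$contig,
    readthrough_flag = pair$readthrough_flag, ort = pair$ort,
    frame_mult = fr$frame, source = evid$source)
}

## Deduplicate candidates sharing both breakpoints (unordered, within
## tol bp); keeps the highest-scoring representative.
merge_candidates <- function(cand, tol = 5L) {
  if (nrow(cand) <= 1L) return(cand)
  setorder(cand, -score, geneA, geneB, posA, posB)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (j in which(keep)) {
      same <- (cand$chrA[i] == cand$chrA[j] &&
                 abs(cand$posA[i] - cand$posA[j]) <= tol &&
                 cand$chrB[i] == cand$chrB[j] &&
                 abs(cand$posB[i] - cand$posB[j]) <= tol) ||
        (cand$chrA[i] == cand$chrB[j] &&
           abs(cand$posA[i] - cand$posB[j]) <= tol &&
           cand$chrB[i] == cand$chrA[j] &&
           abs(cand$posB[i] - cand$posA[j]) <= tol)
      if (same) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  cand[keep]
}

#' Run the fusion-detection pipeline
#'
#' Executes breakpoint discovery from soft-clip clusters, local assembly
#' and two-round contig mapping, the splice-junction rescue path, frame
#' annotation, scoring, retention filtering and grading/ranking. Output
#' is deterministic for a fixed configuration and seed.
#'
#' @param config a `RunConfig` from [run_config()]
#' @return invisible list: fusions (ranked table), rejected (diagnostics),
#'   counts (per-stage tallies), config
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  cfg <- config
  set.seed(cfg$seed)
  t0 <- Sys.time()
  logmsg <- function(...) message("[clipfuse] ", sprintf(...))

  models <- load_gene_model(
    cfg$refflat, cfg$reference, proteins = cfg$proteins,
    known_fusions = cfg$known_fusions, itd_genes = cfg$itd_genes,
    blacklist_regions = cfg$blacklist_regions,
    fusion_blacklist = cfg$fusion_blacklist,
    vdj_regions = cfg$vdj_regions)
  index <- build_kmer_index(models$reference)
  aln <- read_alignments(cfg$bam)
  read_length <- modal_read_length(aln$read_length[aln$usable])
  frag_bound <- estimate_fragment_bound(aln)
  logmsg("loaded %d alignment records (read length %d)", nrow(aln),
         read_length)

  screads <- extract_softclips(aln, min_clip = cfg$min_clip)
  clusters <- cluster_softclips(screads, window = cfg$cluster_window)
  clusters <- annotate_clusters(clusters, aln, models,
                                read_length = read_length)
  filt <- filter_clusters(clusters, models,
                          min_sc_genic = cfg$min_sc_genic,
                          min_sc_intergenic = cfg$min_sc_intergenic,
                          min_exp = cfg$min_exp,
                          min_sc_taf = cfg$min_sc_taf)
  logmsg("%d soft-clip reads, %d clusters, %d candidate breakpoints",
         nrow(screads), nrow(clusters), nrow(filt$retained))

  cand_rows <- list()
  rejections <- list()
  bps <- filt$retained
  for (i in seq_len(nrow(bps))) {
    bp <- bps[i]
    reads <- collect_reads_for_breakpoint(bp, aln,
                                          window = cfg$collect_window,
                                          frag_bound = frag_bound)
    if (nrow(reads) == 0L) next
    contigs <- assemble_contigs(reads[, .(id, seq)],
                                min_overlap = cfg$asm_min_overlap,
                                min_identity = cfg$asm_min_identity)
    pair <- NULL
    for (ct in contigs) {
      res <- resolve_partner(bp, ct$seq, models, index,
                             min_score = cfg$min_align_score,
                             max_hits = cfg$max_hits,
                             proximity = cfg$proximity,
                             full_map_frac = cfg$full_map_frac)
      if (is(res, "BreakpointPair")) { pair <- res; break }
      rejections[[length(rejections) + 1L]] <- data.table(
        chrom = bp$chrom, pos = bp$pos, side = bp$clip_side,
        contig = ct$seq, reason = res$reason)
    }
    if (is.null(pair)) next
    pair <- classify_event(pair, models,
                           rt_max_distance = cfg$rt_max_distance)
    fr <- annotate_frame(pair, models)

    sup2 <- sc_support_at(screads, pair$bp2$chrom, pair$bp2$pos,
                          pair$bp2$side)
    n1 <- bp$SC_cnt
    n2 <- sup2$n
    depth2 <- depth_at(aln, pair$bp2$chrom, pair$bp2$pos)
    taf1 <- bp$SC_TAF
    taf2 <- if (n2 > 0L && depth2 > 0L) n2 / depth2 else taf1
    seqs1 <- aln$seq[aln$usable & aln$qname %in% bp$members[[1L]] &
                       aln$chrom == bp$chrom]
    seqs2 <- if (n2 > 0L) {
      aln$seq[aln$usable & aln$qname %in% sup2$qnames &
                aln$chrom == pair$bp2$chrom]
    } else character()
    area1 <- compute_area(pair$contig, seqs1)
    area2 <- if (length(seqs2)) compute_area(pair$contig, seqs2) else area1
    evid <- list(n1 = n1, n2 = if (n2 > 0L) n2 else n1,
                 taf1 = taf1, taf2 = taf2, area1 = area1, area2 = area2,
                 read_length = read_length, source = "softclip")
    cand_rows[[length(cand_rows) + 1L]] <- candidate_row(cfg, pair, fr, evid)
  }

  # splice-junction rescue path
  junctions <- harvest_novel_junctions(aln, models)
  rescued <- rescue_candidates(junctions, models,
                               min_span = cfg$rescue_min_span,
                               min_taf = cfg$rescue_min_taf)
  logmsg("%d novel splice junctions, %d rescued", nrow(junctions),
         nrow(rescued))
  flank <- 100L
  for (i in seq_len(nrow(rescued))) {
    j <- rescued[i]
    chrseq <- models$reference[[j$chrom]]
    lo <- max(1L, j$donor_pos - flank + 1L)
    hi <- min(length(chrseq), j$acceptor_pos + flank - 1L)
    left <- as.character(Biostrings::subseq(chrseq, lo, j$donor_pos))
    right <- as.character(Biostrings::subseq(chrseq, j$acceptor_pos, hi))
    contig <- paste0(left, right)
    h1 <- align_contig(left, index, min_score = cfg$min_align_score,
                       max_hits = cfg$max_hits)
    h2 <- align_contig(right, index, min_score = cfg$min_align_score,
                       max_hits = cfg$max_hits)
    if (nrow(h1) == 0L || nrow(h2) == 0L) next
    pair <- structure(list(
      bp1 = list(chrom = j$chrom, pos = j$donor_pos, side = "right"),
      bp2 = list(chrom = j$chrom, pos = j$acceptor_pos, side = "left"),
      contig = contig, s2 = right,
      repeat1 = compute_repeat_score(h1[1L], h1),
      repeat2 = compute_repeat_score(h2[1L], h2),
      # junction reads are fully mapped: full matched length on both sides
      match1 = nchar(left), match2 = nchar(right),
      strand1 = "+", strand2 = "+",
      q_interval1 = c(1L, nchar(left)),
      q_interval2 = c(nchar(left) + 1L, nchar(contig))
    ), class = "BreakpointPair")
    pair <- classify_event(pair, models,
                           rt_max_distance = cfg$rt_max_distance)
    fr <- annotate_frame(pair, models)
    jseqs <- aln$seq[aln$usable & aln$qname %in% j$members[[1L]]]
    area <- compute_area(contig, jseqs)
    depth_acc <- depth_at(aln, j$chrom, j$acceptor_pos)
    taf2 <- if (depth_acc > 0L) j$junction_read_cnt / depth_acc
            else j$junction_TAF
    evid <- list(n1 = j$junction_read_cnt, n2 = j$junction_read_cnt,
                 taf1 = j$junction_TAF, taf2 = taf2,
                 area1 = area, area2 = area,
                 read_length = read_length, source = "splice")
    cand_rows[[length(cand_rows) + 1L]] <- candidate_row(cfg, pair, fr, evid)
  }

  cand <- if (length(cand_rows)) rbindlist(cand_rows)
          else empty_candidate_table()
  n_before <- nrow(cand)
  cand <- merge_candidates(cand, tol = cfg$merge_tol)
  logmsg("%d candidate pairs (%d after merging)", n_before, nrow(cand))

  ret <- apply_retention_filters(
    cand, fusion_blacklist = read_pair_list(cfg$fusion_blacklist),
    min_score = cfg$retention_min_score,
    max_repeat = cfg$retention_max_repeat,
    min_taf = cfg$retention_min_taf)
  ranked <- grade_and_rank(ret$retained, models, raw_mode = cfg$raw_mode)
  logmsg("%d retained, %d rejected at retention; %d ranked",
         nrow(ret$retained), nrow(ret$rejected), nrow(ranked))

  fusions <- ranked[, fusion_output_columns, with = FALSE]
  rejected <- rbindlist(list(
    if (length(rejections)) rbindlist(rejections) else NULL,
    if (nrow(ret$rejected)) ret$rejected[, .(
      chrom = chrA, pos = posA, side = sideA,
      contig = contig, reason = reject_reason)] else NULL
  ), fill = TRUE)

  counts <- list(
    alignments = nrow(aln), softclips = nrow(screads),
    clusters = nrow(clusters), breakpoints = nrow(bps),
    candidates = n_before, merged = nrow(cand),
    retained = nrow(ret$retained), rescued = nrow(rescued))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(fusions, file.path(cfg$out_dir, "fusions.tsv"),
                       sep = "\t")
    if (!is.null(rejected) && nrow(rejected)) {
      data.table::fwrite(rejected, file.path(cfg$out_dir, "rejected.tsv"),
                         sep = "\t")
    }
    scal <- Filter(function(x) is.atomic(x) && length(x) == 1L,
                   unclass(cfg))
    yaml::write_yaml(scal, file.path(cfg$out_dir, "config.yaml"))
  }
  logmsg("done in %.1f s",
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(fusions = fusions, rejected = rejected, counts = counts,
                 config = cfg))
}
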