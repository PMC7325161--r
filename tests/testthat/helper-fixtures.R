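# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fx$cohort)) {
    .fx$cohort <- fixture_cohort(file.path(tempdir(), "clipfuse-cohort"),
                                 seed = 1L)
  }
  .fx$cohort
}

shared_models <- function() {
  if (is.null(.fx$models)) {
    co <- shared_cohort()
    .fx$models <- suppressMessages(load_gene_model(
      co$paths$refflat, co$paths$reference, proteins = co$paths$proteins,
      known_fusions = co$paths$known_fusions))
  }
  .fx$models
}

shared_index <- function() {
  if (is.null(.fx$index)) .fx$index <- build_kmer_index(shared_models()$reference)
  .fx$index
}

shared_aln <- function() {
  if (is.null(.fx$aln)) .fx$aln <- read_alignments(shared_cohort()$paths$sam)
  .fx$aln
}

shared_run <- function(raw = FALSE) {
  key <- if (raw) "run_raw" else "run_default"
  if (is.null(.fx[[key]])) {
    co <- shared_cohort()
    cfg <- run_config(bam = co$paths$sam, reference = co$paths$reference,
                      refflat = co$paths$refflat,
                      proteins = co$paths$proteins,
                      known_fusions = co$paths$known_fusions,
                      raw_mode = raw)
    .fx[[key]] <- suppressMessages(run_pipeline(cfg))
  }
  .fx[[key]]
}

## Minimal one-gene model on a bare CDS chromosome: protein of
## `n_aa` residues, single exon, no UTRs.
mini_cds_model <- function(n_aa = 100L, cds = NULL) {
  if (is.null(cds)) {
    set.seed(7)
    cds <- paste0("ATG", paste(replicate((n_aa - 1L), {
      repeat {
        c3 <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                    collapse = "")
        if (!(c3 %in% c("TAA", "TAG", "TGA"))) break
      }
      c3
    }), collapse = ""), "TAA")
  }
  ref <- Biostrings::DNAStringSet(c(chrT = cds))
  prot <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  tx <- data.table::data.table(
    gene = "T1", name = "TX_T1", chrom = "chrT", strand = "+",
    tx_start = 1L, tx_end = nchar(cds), cds_start = 1L,
    cds_end = nchar(cds), exons = list(cbind(start = 1L,
                                             end = nchar(cds))))
  rf <- tempfile(fileext = ".refflat")
  write_refflat(tx, rf)
  suppressMessages(load_gene_model(rf, ref,
                                   proteins = c(TX_T1 = prot)))
}

## Substitute `k` residues of a protein (cyclic positions, deterministic).
substitute_aa <- function(protein, k) {
  if (k == 0L) return(protein)
  n <- nchar(protein)
  pos <- ((seq_len(k) - 1L) * 13L) %% n + 1L
  chars <- strsplit(protein, "")[[1L]]
  for (p in pos) chars[p] <- if (chars[p] == "G") "P" else "G"
  paste(chars, collapse = "")
}

## Write a small SAM file from parallel record vectors.
write_mini_sam <- function(path, chrom_lens, qname, flag, rname, pos,
                           cigar, seq, rnext = "=", pnext = pos,
                           mapq = 60L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  n <- length(qname)
  flag <- rep_len(flag, n); rname <- rep_len(rname, n)
  pos <- rep_len(pos, n); cigar <- rep_len(cigar, n)
  seq <- rep_len(seq, n)
  rnext <- rep_len(rnext, n); pnext <- rep_len(pnext, n)
  mapq <- rep_len(mapq, n)
  ord <- order(match(rname, names(chrom_lens)), pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  qname[ord], flag[ord], rname[ord], pos[ord], mapq[ord],
                  cigar[ord], rnext[ord], pnext[ord], seq[ord],
                  strrep("I", nchar(seq[ord])))
  writeLines(c(hdr, body), path)
  path
}

## Brute-force Smith-Waterman oracle (match +1, mismatch -1, no gaps
## allowed) over every chromosome of a reference; returns the best
## chromosome, subject start and matched bases.
sw_oracle <- function(query, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  best <- NULL
  for (chr in names(reference)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), reference[[chr]], type = "local",
      substitutionMatrix = mat, gapOpening = 1e6, gapExtension = 1e6)
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$score) {
      best <- list(chrom = chr, score = sc,
                   start = Biostrings::start(Biostrings::subject(pa)),
                   matches = Biostrings::nmatch(pa))
    }
  }
  best
}

## Deterministic per-test RNG seed without disturbing global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
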