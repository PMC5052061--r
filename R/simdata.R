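# Synthetic fixture generation with planted ground truth, plus the
# brute-force scan-statistic oracle used to validate the analytic p-value.
#
# The simulator emits aligned reads directly as SAM records (no
# sequence-level alignment is simulated); CIGARs are plain matches, which
# is sufficient to exercise counting-position and assignment arithmetic.
# Planted features mirror the failure modes end-sequencing analysis must
# handle: read pileups on internal genomically-encoded poly(A) stretches,
# expressed 3' ends downstream of the annotated end, multimapped reads,
# and PCR-duplicated barcoded reads in single-cell mode.

#' Specification of a synthetic end-sequencing data set
#'
#' @param n_genes Number of genes to lay out.
#' @param seed RNG seed (mandatory; all generators are deterministic).
#' @param reads_per_gene Reads emitted per gene per experiment.
#' @param read_len Read length in bases.
#' @param frac_novel Fraction of reads placed at a planted unannotated 3'
#'   end downstream of the annotated end.
#' @param frac_polya Fraction of internal-priming artifact reads: placed
#'   mid-transcript, with a >= 10 base A run in their sequence.
#' @param frac_multimap Fraction of multimapped decoy reads (NH = 2); half
#'   have their second locus intergenic (rescuable by the `proper`
#'   policy), half inside another gene (never rescuable).
#' @param novel_end_offset Distance (bases) of the planted novel end past
#'   the annotated 3' end, truncated to fit the intergenic gap.
#' @param end_sd Standard deviation (bases) of read counting positions
#'   around their target end; on the order of an observed 3'-pileup width.
#' @param close_pair_frac Fraction of genes immediately followed by a
#'   same-strand neighbour only `close_pair_gap` bases away, to exercise
#'   extension truncation.
#' @param close_pair_gap Gap (bases) within a close pair.
#' @param isoform_frac Fraction of genes given a second isoform, so union
#'   models differ from every constituent isoform.
#' @param experiments Experiment identifiers (one SAM file each).
#' @param sc `NULL` for bulk mode, or a list with `n_cells`,
#'   `umis_per_cell`, `pcr_factor`, `n_ambient`, `ambient_mean` for
#'   single-cell mode.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 50, seed = 1, reads_per_gene = 200,
                     read_len = 25, frac_novel = 0.1, frac_polya = 0.1,
                     frac_multimap = 0.1, novel_end_offset = 2000,
                     end_sd = 30, close_pair_frac = 0.1,
                     close_pair_gap = 2000, isoform_frac = 0.3,
                     experiments = c("expA", "expB"), sc = NULL) {
  stopifnot(n_genes >= 1, reads_per_gene >= 1, read_len >= 10,
            frac_novel + frac_polya + frac_multimap <= 1,
            frac_novel >= 0, frac_polya >= 0, frac_multimap >= 0,
            !is.null(seed))
  structure(list(n_genes = as.integer(n_genes), seed = as.integer(seed),
                 reads_per_gene = as.integer(reads_per_gene),
                 read_len = as.integer(read_len), frac_novel = frac_novel,
                 frac_polya = frac_polya, frac_multimap = frac_multimap,
                 novel_end_offset = as.integer(novel_end_offset),
                 end_sd = end_sd, close_pair_frac = close_pair_frac,
                 close_pair_gap = as.integer(close_pair_gap),
                 isoform_frac = isoform_frac, experiments = experiments,
                 sc = sc),
            class = "sim_spec")
}

# Random sequences with A/T homopolymer runs capped at 2: bases are drawn
# as dinucleotides from the 16-mer alphabet minus AA and TT, so the filter
# threshold (>= 10) can never fire on a clean read.
random_clean_seq <- function(n, len) {
  dints <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  dints <- setdiff(dints, c("AA", "TT"))
  k <- ceiling(len / 2)
  vapply(seq_len(n), function(i) {
    s <- paste(sample(dints, k, replace = TRUE), collapse = "")
    substr(s, 1, len)
  }, character(1))
}

random_polya_seq <- function(n, len, run = 12) {
  base <- random_clean_seq(n, len)
  vapply(base, function(s) {
    paste0(substr(s, 1, 5), strrep("A", run), substr(s, 6 + run, len))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an annotated transcriptome
#'
#' Lays `n_genes` genes left to right on one synthetic chromosome with
#' randomized strands, 1-3 exons per gene and wide intergenic gaps; a
#' fraction of genes is followed by a close same-strand neighbour (to
#' exercise extension truncation) and a fraction receives a second isoform
#' whose exon set differs from the first. Each gene records a planted
#' unannotated 3'-end position downstream of its annotated end where the
#' intergenic gap allows one.
#'
#' @param spec A [sim_spec()].
#' @param dir If non-NULL, write `annotation.bed`, `genes.txt` (UCSC-style
#'   table) and `truth_genes.txt` into this directory.
#' @return List with `transcripts` (a `transcripts` data frame),
#'   `truth_genes` (gene, chrom, strand, span, annotated 3'-end counting
#'   position `end3_cpos`, planted `novel_cpos` or NA, extension room
#'   `gap3`), `chrom_len`, and any file paths written.
#' @export
simulate_transcriptome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  chrom <- "simchr1"
  cursor <- 10000L
  rows <- list()
  force_strand <- NA_character_
  for (i in seq_len(spec$n_genes)) {
    gene <- sprintf("GENE%04d", i)
    strand <- if (!is.na(force_strand)) force_strand else
      sample(c("+", "-"), 1)
    n_ex <- sample(1:3, 1)
    widths <- sample(200:600, n_ex, replace = TRUE)
    introns <- if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE)
      else integer(0)
    ex_s <- integer(n_ex); ex_e <- integer(n_ex)
    p <- cursor
    for (k in seq_len(n_ex)) {
      ex_s[k] <- p; ex_e[k] <- p + widths[k]
      p <- ex_e[k] + if (k < n_ex) introns[k] else 0L
    }
    rows[[length(rows) + 1L]] <- list(
      transcript_id = paste0(gene, ".1"), gene = gene, chrom = chrom,
      strand = strand, tx_start = ex_s[1], tx_end = ex_e[n_ex],
      exon_starts = ex_s, exon_ends = ex_e)
    if (stats::runif(1) < spec$isoform_frac) {
      if (n_ex > 1) {
        s2 <- ex_s[-1]; e2 <- ex_e[-1]
        e2[length(e2)] <- e2[length(e2)] + 150L
      } else {
        s2 <- ex_s + 150L; e2 <- ex_e + 150L
      }
      rows[[length(rows) + 1L]] <- list(
        transcript_id = paste0(gene, ".2"), gene = gene, chrom = chrom,
        strand = strand, tx_start = s2[1], tx_end = e2[length(e2)],
        exon_starts = s2, exon_ends = e2)
    }
    close_next <- i < spec$n_genes && stats::runif(1) < spec$close_pair_frac
    force_strand <- if (close_next) strand else NA_character_
    gap <- if (close_next) spec$close_pair_gap else
      sample(12000:20000, 1)
    # the +150 isoform shift may have pushed the gene end slightly
    cursor <- max(ex_e[n_ex], p) + 200L + as.integer(gap)
  }
  tx <- data.frame(
    transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    chrom = chrom,
    strand = vapply(rows, `[[`, character(1), "strand"),
    tx_start = vapply(rows, `[[`, integer(1), "tx_start"),
    tx_end = vapply(rows, `[[`, integer(1), "tx_end"),
    stringsAsFactors = FALSE)
  tx$exon_starts <- lapply(rows, `[[`, "exon_starts")
  tx$exon_ends <- lapply(rows, `[[`, "exon_ends")
  tx <- validate_transcripts(tx, "simulated")
  chrom_len <- cursor + 20000L

  models <- build_gene_models(tx, "metatranscript")
  span_s <- vapply(models$block_start, min, numeric(1))
  span_e <- vapply(models$block_end, max, numeric(1))
  n <- nrow(models)
  gap3 <- numeric(n); end3 <- integer(n); novel <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    same <- setdiff(which(models$strand == models$strand[j]), j)
    if (models$strand[j] == "+") {
      end3[j] <- as.integer(span_e[j]) - 1L
      nb <- same[span_e[same] > span_e[j]]
      gap3[j] <- if (length(nb) == 0) Inf else
        min(pmax(0, span_s[nb] - span_e[j]))
      d <- min(spec$novel_end_offset, gap3[j] - 300)
      if (d >= 200) novel[j] <- as.integer(span_e[j] + d)
    } else {
      end3[j] <- as.integer(span_s[j])
      nb <- same[span_s[same] < span_s[j]]
      gap3[j] <- if (length(nb) == 0) Inf else
        min(pmax(0, span_s[j] - span_e[nb]))
      d <- min(spec$novel_end_offset, gap3[j] - 300)
      if (d >= 200) novel[j] <- as.integer(span_s[j] - d)
    }
  }
  truth_genes <- data.frame(gene = models$gene, chrom = models$chrom,
                            strand = models$strand,
                            span_start = as.integer(span_s),
                            span_end = as.integer(span_e),
                            end3_cpos = end3, novel_cpos = novel,
                            gap3 = gap3, stringsAsFactors = FALSE)
  out <- list(transcripts = tx, truth_genes = truth_genes,
              chrom = chrom, chrom_len = chrom_len)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$bed_path <- file.path(dir, "annotation.bed")
    write_bed12(tx, out$bed_path)
    out$table_path <- file.path(dir, "genes.txt")
    write_gene_table(tx, out$table_path)
    out$truth_genes_path <- file.path(dir, "truth_genes.txt")
    utils::write.table(truth_genes, out$truth_genes_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

write_bed12 <- function(tx, path) {
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    paste(tx$chrom[i], tx$tx_start[i], tx$tx_end[i], tx$transcript_id[i],
          0, tx$strand[i], tx$tx_start[i], tx$tx_end[i], "0",
          length(s), paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - tx$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

write_gene_table <- function(tx, path) {
  df <- data.frame(
    name = tx$transcript_id, chrom = tx$chrom, strand = tx$strand,
    txStart = tx$tx_start, txEnd = tx$tx_end,
    exonStarts = vapply(tx$exon_starts, function(v)
      paste0(paste(v, collapse = ","), ","), character(1)),
    exonEnds = vapply(tx$exon_ends, function(v)
      paste0(paste(v, collapse = ","), ","), character(1)),
    name2 = tx$gene, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_sam <- function(path, chrom, chrom_len, rec) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  body <- paste(rec$qname, rec$flag, chrom, rec$pos + 1L, 255L, rec$cigar,
                "*", 0L, 0L, rec$seq, "*",
                paste0("NH:i:", rec$nh), sep = "\t")
  writeLines(c(header, body), path)
}

# Read record targeting a given counting position on a given strand.
rec_for_cpos <- function(cpos, strand, read_len) {
  pos <- ifelse(strand == "-", cpos - (read_len - 1L), cpos)
  list(pos = as.integer(pos), flag = ifelse(strand == "-", 16L, 0L),
       cigar = paste0(read_len, "M"))
}

#' Simulate aligned end-sequencing reads with planted truth
#'
#' Emits SAM files (one per experiment, or a single barcoded file in
#' single-cell mode) whose counting positions are drawn around the
#' annotated 3' end, a planted unannotated end, or an internal poly(A)
#' artifact site, plus NH=2 multimapped decoys; every read carries exactly
#' one origin label in the returned truth table.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param spec The same [sim_spec()].
#' @param dir Directory for the SAM and truth files.
#' @return List with `sam_paths` (named by experiment), `truth_reads`
#'   (qname, experiment, origin, gene, cpos, n_genic, barcode, umi), and
#'   in single-cell mode `truth_molecules` (barcode, gene, molecules) and
#'   `true_cells`.
#' @export
simulate_end_reads <- function(sim, spec, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- build_gene_models(sim$transcripts, "metatranscript")
  tg <- sim$truth_genes
  if (is.null(spec$sc)) {
    simulate_bulk_reads(sim, spec, dir, models, tg)
  } else {
    simulate_sc_reads(sim, spec, dir, models, tg)
  }
}

# Transcript-space placement near the annotated 3' end (offset ~ |N(0,sd)|)
ann_end_tpos <- function(n, L, end_sd) {
  off <- pmin(abs(round(stats::rnorm(n, 0, end_sd))), L - 1)
  as.integer(L - 1 - off)
}

simulate_bulk_reads <- function(sim, spec, dir, models, tg) {
  read_len <- spec$read_len
  sam_paths <- character(0)
  truth_blocks <- list()
  rec_blocks <- list()
  qid <- 0L
  # intergenic decoy sites: midpoints of wide gaps, never reachable by a
  # 5 kb extension
  o <- order(tg$span_start)
  span_e <- tg$span_end[o]
  span_s <- tg$span_start[o]
  gaps_l <- utils::head(span_e, -1); gaps_r <- utils::tail(span_s, -1)
  wide <- which(gaps_r - gaps_l > 11000)
  decoy_sites <- as.integer((gaps_l[wide] + gaps_r[wide]) / 2)
  emit <- function(e, origin, gene, cpos, n_genic, strand, nh, clean) {
    m <- length(cpos)
    qn <- sprintf("r%07d", qid + seq_len(m))
    qid <<- qid + m
    truth_blocks[[length(truth_blocks) + 1L]] <<- data.frame(
      qname = qn, experiment = e, origin = origin, gene = gene,
      cpos = as.integer(cpos), n_genic = n_genic,
      stringsAsFactors = FALSE)
    rec_blocks[[length(rec_blocks) + 1L]] <<- data.frame(
      qname = qn, strand = strand, cpos = as.integer(cpos), nh = nh,
      clean = clean, secondary = FALSE, stringsAsFactors = FALSE)
    qn
  }
  for (e in spec$experiments) {
    first_block <- length(rec_blocks) + 1L
    for (j in seq_len(nrow(models))) {
      n <- spec$reads_per_gene
      L <- as.integer(models$L[j])
      strand <- models$strand[j]
      has_novel <- !is.na(tg$novel_cpos[j])
      probs <- c(novel = if (has_novel) spec$frac_novel else 0,
                 polya = spec$frac_polya, mm = spec$frac_multimap)
      probs <- c(ann = 1 - sum(probs), probs)
      cat_n <- stats::rmultinom(1, n, probs)[, 1]
      if (cat_n["ann"] > 0) {
        tp <- ann_end_tpos(cat_n["ann"], L, spec$end_sd)
        emit(e, "annotated_end", models$gene[j],
             tpos_to_genomic(models, j, tp), 1L, strand, 1L, TRUE)
      }
      if (cat_n["novel"] > 0) {
        jit <- abs(round(stats::rnorm(cat_n["novel"], 0, 10)))
        cp <- tg$novel_cpos[j] + if (strand == "+") -jit else jit
        emit(e, "novel_end", models$gene[j], cp, 1L, strand, 1L, TRUE)
      }
      if (cat_n["polya"] > 0) {
        tp <- pmax(0L, pmin(L - 1L,
          as.integer(round(L / 2 + stats::rnorm(cat_n["polya"], 0, 10)))))
        emit(e, "internal_polyA", models$gene[j],
             tpos_to_genomic(models, j, tp), 1L, strand, 1L, FALSE)
      }
      # multimapped decoys: genic locus near the 3' end plus a second
      # locus, alternately intergenic (rescuable) or in another gene
      if (cat_n["mm"] > 0 && nrow(models) >= 2) {
        m <- cat_n["mm"]
        tp <- ann_end_tpos(m, L, spec$end_sd)
        cp <- tpos_to_genomic(models, j, tp)
        rescuable <- (seq_len(m) %% 2L == 0L) & length(decoy_sites) > 0
        cp2 <- integer(m); strand2 <- character(m)
        if (any(rescuable)) {
          cp2[rescuable] <- sample(decoy_sites, sum(rescuable),
                                   replace = TRUE)
          strand2[rescuable] <- sample(c("+", "-"), sum(rescuable),
                                       replace = TRUE)
        }
        if (any(!rescuable)) {
          j2 <- sample(setdiff(seq_len(nrow(models)), j), sum(!rescuable),
                       replace = TRUE)
          cp2[!rescuable] <- vapply(j2, function(jj)
            as.integer(tpos_to_genomic(models, jj,
                                       as.integer(models$L[jj] %/% 2))),
            integer(1))
          strand2[!rescuable] <- models$strand[j2]
        }
        qn <- emit(e, "multimap_decoy", models$gene[j], cp,
                   ifelse(rescuable, 1L, 2L), strand, 2L, TRUE)
        rec_blocks[[length(rec_blocks) + 1L]] <- data.frame(
          qname = qn, strand = strand2, cpos = cp2, nh = 2L,
          clean = TRUE, secondary = TRUE, stringsAsFactors = FALSE)
      }
    }
    recs <- do.call(rbind, rec_blocks[first_block:length(rec_blocks)])
    rec <- build_sam_records(recs, read_len)
    sam <- file.path(dir, paste0(e, ".sam"))
    write_sam(sam, sim$chrom, sim$chrom_len, rec)
    sam_paths[e] <- sam
  }
  truth_reads <- do.call(rbind, truth_blocks)
  truth_reads$barcode <- NA_character_
  truth_reads$umi <- NA_character_
  rownames(truth_reads) <- NULL
  utils::write.table(truth_reads, file.path(dir, "truth_reads.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(sam_paths = sam_paths, truth_reads = truth_reads)
}

build_sam_records <- function(recs, read_len) {
  geom <- rec_for_cpos(recs$cpos, recs$strand, read_len)
  seq <- character(nrow(recs))
  seq[recs$clean] <- random_clean_seq(sum(recs$clean), read_len)
  if (any(!recs$clean))
    seq[!recs$clean] <- random_polya_seq(sum(!recs$clean), read_len)
  list(qname = recs$qname,
       flag = geom$flag + ifelse(recs$secondary, 256L, 0L),
       pos = geom$pos, cigar = geom$cigar, seq = seq, nh = recs$nh)
}

random_umis <- function(n, len = 8) {
  stopifnot(n <= 4^len)
  umis <- character(0)
  while (length(umis) < n) {
    need <- n - length(umis)
    new <- vapply(seq_len(need), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    umis <- unique(c(umis, new))
  }
  umis[seq_len(n)]
}

simulate_sc_reads <- function(sim, spec, dir, models, tg) {
  sc <- spec$sc
  read_len <- spec$read_len
  cells <- vapply(seq_len(sc$n_cells), function(i)
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
          collapse = ""), character(1))
  while (anyDuplicated(cells)) cells[duplicated(cells)] <-
    vapply(seq_len(sum(duplicated(cells))), function(i)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
            collapse = ""), character(1))
  recs <- list(); truth <- list(); mol <- list()
  qid <- 0L
  for (bc in cells) {
    gene_draw <- sample(seq_len(nrow(models)), sc$umis_per_cell,
                        replace = TRUE)
    per_gene <- table(gene_draw)
    for (gs in names(per_gene)) {
      j <- as.integer(gs)
      m <- as.integer(per_gene[[gs]])
      umis <- random_umis(m)
      L <- as.integer(models$L[j])
      tp <- ann_end_tpos(m, L, spec$end_sd)
      cp <- tpos_to_genomic(models, j, tp)
      mol[[length(mol) + 1L]] <- data.frame(
        barcode = bc, gene = models$gene[j], molecules = m,
        stringsAsFactors = FALSE)
      for (k in seq_len(m)) {
        copies <- 1L + stats::rpois(1, max(0, sc$pcr_factor - 1))
        for (cc in seq_len(copies)) {
          qid <- qid + 1L
          qn <- sprintf("r%07d:%s:%s", qid, bc, umis[k])
          truth[[length(truth) + 1L]] <- list(
            qname = qn, experiment = "sc",
            origin = if (cc == 1L) "sc_molecule" else "pcr_duplicate",
            gene = models$gene[j], cpos = cp[k], n_genic = 1L,
            barcode = bc, umi = umis[k])
          recs[[length(recs) + 1L]] <- list(
            qname = qn, strand = models$strand[j], cpos = cp[k],
            nh = 1L, clean = TRUE)
        }
      }
    }
  }
  # ambient barcodes: a few stray reads each
  if (sc$n_ambient > 0) {
    amb <- vapply(seq_len(sc$n_ambient), function(i)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
            collapse = ""), character(1))
    amb <- setdiff(unique(amb), cells)
    for (bc in amb) {
      nr <- stats::rpois(1, sc$ambient_mean)
      if (nr == 0) next
      js <- sample(seq_len(nrow(models)), nr, replace = TRUE)
      for (j in js) {
        qid <- qid + 1L
        L <- as.integer(models$L[j])
        tp <- ann_end_tpos(1L, L, spec$end_sd)
        cp <- tpos_to_genomic(models, j, tp)
        umi <- random_umis(1)
        qn <- sprintf("r%07d:%s:%s", qid, bc, umi)
        truth[[length(truth) + 1L]] <- list(
          qname = qn, experiment = "sc", origin = "ambient",
          gene = models$gene[j], cpos = cp, n_genic = 1L,
          barcode = bc, umi = umi)
        recs[[length(recs) + 1L]] <- list(qname = qn,
                                          strand = models$strand[j],
                                          cpos = cp, nh = 1L, clean = TRUE)
      }
    }
  }
  recs_df <- data.frame(
    qname = vapply(recs, `[[`, character(1), "qname"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    cpos = vapply(recs, function(r) as.integer(r$cpos), integer(1)),
    nh = 1L, clean = TRUE, secondary = FALSE, stringsAsFactors = FALSE)
  rec <- build_sam_records(recs_df, read_len)
  sam <- file.path(dir, "sc.sam")
  write_sam(sam, sim$chrom, sim$chrom_len, rec)
  truth_reads <- do.call(rbind, lapply(truth, function(t)
    data.frame(t, stringsAsFactors = FALSE)))
  truth_molecules <- do.call(rbind, mol)
  utils::write.table(truth_reads, file.path(dir, "truth_reads.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(sam_paths = c(sc = sam), truth_reads = truth_reads,
       truth_molecules = truth_molecules, true_cells = cells)
}

#' Simulate a bimodal barcode count table
#'
#' Emulates the barcode-rank structure of a droplet experiment: a small
#' population of true cells with high UMI-filtered read counts over a
#' large population of ambient barcodes with low counts.
#'
#' @param n_cells,cell_mean True cells and their Poisson mean count.
#' @param n_ambient,ambient_mean Ambient barcodes and their mean.
#' @param seed RNG seed.
#' @return Data frame `barcode`, `count`, `is_cell`, sorted by decreasing
#'   count.
#' @export
simulate_barcode_table <- function(n_cells = 200, cell_mean = 5000,
                                   n_ambient = 5000, ambient_mean = 50,
                                   seed = 1) {
  set.seed(seed)
  bt <- data.frame(
    barcode = c(sprintf("CELL%05d", seq_len(n_cells)),
                sprintf("AMB%05d", seq_len(n_ambient))),
    count = c(stats::rpois(n_cells, cell_mean),
              stats::rpois(n_ambient, ambient_mean)),
    is_cell = rep(c(TRUE, FALSE), c(n_cells, n_ambient)),
    stringsAsFactors = FALSE)
  bt <- bt[order(-bt$count, bt$barcode), , drop = FALSE]
  rownames(bt) <- NULL
  bt
}

#' Simulate a window table with a planted end-usage shift
#'
#' Generates a two-window window table for `n_genes` genes and a set of
#' samples. For each gene the reference fraction of reads outside the
#' terminal window is drawn uniformly from `f0_range`; every non-reference
#' sample shifts that fraction by `delta` (capped at 0.98). Window counts
#' are binomial draws with `n_reads` trials, so sampling noise matches a
#' real window table.
#'
#' @param n_genes,n_reads Genes and reads per gene.
#' @param delta Additive shift of the outside-terminal fraction in the
#'   non-reference samples.
#' @param f0_range Range of the reference fraction; kept well inside the
#'   eligibility region so selection on the reference sample stays
#'   non-binding.
#' @param samples Sample names; the first is the reference.
#' @param seed RNG seed.
#' @return A window table data frame (see [read_window_table()]).
#' @export
simulate_end_usage <- function(n_genes = 500, n_reads = 300, delta = 0.1,
                               f0_range = c(0.45, 0.55),
                               samples = c("t0", "t1"), seed = 1) {
  set.seed(seed)
  stopifnot(length(samples) >= 2)
  genes <- sprintf("G%04d", seq_len(n_genes))
  wt <- data.frame(
    gene = rep(genes, each = 2),
    chrom = "simchr1",
    start = as.vector(rbind(seq_len(n_genes) * 1000L,
                            seq_len(n_genes) * 1000L + 200L)),
    end = as.vector(rbind(seq_len(n_genes) * 1000L + 100L,
                          seq_len(n_genes) * 1000L + 300L)),
    strand = "+", pvalue = 0.001, stringsAsFactors = FALSE)
  f0 <- stats::runif(n_genes, f0_range[1], f0_range[2])
  for (si in seq_along(samples)) {
    f <- if (si == 1) f0 else pmin(f0 + delta, 0.98)
    terminal <- stats::rbinom(n_genes, n_reads, 1 - f)
    other <- n_reads - terminal
    # window 2 (higher start) is terminal for these + strand genes
    wt[[samples[si]]] <- as.vector(rbind(other, terminal))
  }
  wt
}

#' Brute-force oracle for the scan-statistic null distribution
#'
#' Places `N` reads independently and uniformly on `L` discrete positions
#' and records the maximum `w`-window count, either by exhaustive
#' enumeration of all `L^N` placements (exact; used when that count is at
#' most `1e6`) or by Monte-Carlo simulation. The resulting tail
#' probabilities `P(max >= k)` are the reference that [scan_pvalue()] is
#' validated against; the oracle shares no code with it.
#'
#' @param N,L,w Reads, positions and window length.
#' @param reps Monte-Carlo replicates (ignored when enumerating).
#' @param seed RNG seed.
#' @param exhaustive Force enumeration on/off; default auto (`L^N <= 1e6`).
#' @return A `scan_oracle` object; query it with [tail_prob()].
#' @export
mc_scan_oracle <- function(N, L, w, reps = 10000, seed = 1,
                           exhaustive = NULL) {
  stopifnot(N >= 1, L >= 1, w >= 1, w <= L)
  if (is.null(exhaustive)) exhaustive <- L^N <= 1e6
  W <- L - w + 1L
  if (exhaustive) {
    pos <- as.matrix(expand.grid(rep(list(0:(L - 1)), N)))
    mx <- rep(0L, nrow(pos))
    for (s in 0:(W - 1)) {
      inwin <- rowSums(pos >= s & pos < s + w)
      mx <- pmax(mx, inwin)
    }
    tb <- tabulate(mx + 1L, nbins = N + 1L)
    tail <- rev(cumsum(rev(tb))) / nrow(pos)
    method <- "exhaustive"
    reps <- nrow(pos)
  } else {
    set.seed(seed)
    maxima <- integer(reps)
    ix <- seq_len(N) - 1L
    # the maximising window starts at one of the points, so the max count
    # is max_j #{i : p_j <= p_i <= p_j + w - 1} over the sorted points
    for (r in seq_len(reps)) {
      p <- sort.int(sample.int(L, N, replace = TRUE), method = "radix")
      maxima[r] <- max(findInterval(p + w - 1L, p) - ix)
    }
    tb <- tabulate(maxima + 1L, nbins = N + 1L)
    tail <- rev(cumsum(rev(tb))) / reps
    method <- "monte-carlo"
  }
  structure(list(N = N, L = L, w = w, reps = reps, method = method,
                 k = 0:N, tail = tail),
            class = "scan_oracle")
}

#' Empirical tail probability from a scan oracle
#'
#' @param oracle A `scan_oracle` from [mc_scan_oracle()].
#' @param k Threshold(s).
#' @return `P(max window count >= k)` for each `k` (1 for `k <= 0`, 0
#'   beyond `N`).
#' @export
tail_prob <- function(oracle, k) {
  stopifnot(inherits(oracle, "scan_oracle"))
  vapply(k, function(ki) {
    if (ki <= 0) return(1)
    if (ki > oracle$N) return(0)
    oracle$tail[ki + 1L]
  }, numeric(1))
}

#' @export
print.scan_oracle <- function(x, ...) {
  cat("Scan-statistic oracle (", x$method, "): N=", x$N, " L=", x$L,
      " w=", x$w, ", ", x$reps, " placements\n", sep = "")
  invisible(x)
}
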