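# In-code fixture builders shared across the suite.

# One-call transcripts data frame: each element of `defs` is
# list(id, gene, chrom, strand, starts, ends).
make_transcripts <- function(defs) {
  tx <- data.frame(
    transcript_id = vapply(defs, `[[`, character(1), 1),
    gene = vapply(defs, `[[`, character(1), 2),
    chrom = vapply(defs, `[[`, character(1), 3),
    strand = vapply(defs, `[[`, character(1), 4),
    tx_start = vapply(defs, function(d) as.integer(min(d[[5]])), integer(1)),
    tx_end = vapply(defs, function(d) as.integer(max(d[[6]])), integer(1)),
    stringsAsFactors = FALSE)
  tx$exon_starts <- lapply(defs, function(d) as.integer(d[[5]]))
  tx$exon_ends <- lapply(defs, function(d) as.integer(d[[6]]))
  class(tx) <- c("transcripts", "data.frame")
  tx
}

# Minimal SAM writer for hand-built records. `rec` is a data frame with
# qname, flag, pos1 (1-based), cigar, seq (optional, default "*") and nh
# (optional NH tag).
write_test_sam <- function(path, rec, chrom = "chr1", chrom_len = 1000000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  seqs <- if (is.null(rec$seq)) rep("*", nrow(rec)) else rec$seq
  quals <- rep("*", nrow(rec))
  lines <- paste(rec$qname, rec$flag, chrom, rec$pos1, 255L, rec$cigar,
                 "*", 0L, 0L, seqs, quals, sep = "\t")
  if (!is.null(rec$nh)) lines <- paste0(lines, "\tNH:i:", rec$nh)
  writeLines(c(header, lines), path)
  path
}

# Hand-built reads data frame bypassing SAM I/O (for assignment and
# multimap tests). cpos-centred: emits pos/ref_width consistent with a
# 25-base unspliced read.
make_reads <- function(qname, chrom, strand, cpos, nh = 1L, seq = NA_character_) {
  n <- length(cpos)
  strand <- rep_len(strand, n)
  rw <- rep(25L, n)
  pos <- ifelse(strand == "-", cpos - 24L, cpos)
  df <- data.frame(qname = qname, chrom = chrom, strand = strand,
                   pos = as.integer(pos), ref_width = rw,
                   nh = as.integer(nh), seq = seq,
                   stringsAsFactors = FALSE)
  df$cpos <- counting_position(df)
  df
}

# Two well separated + strand genes and one - strand gene, pre-extended.
simple_models <- function(w_ext = 0, task = "score3p") {
  tx <- make_transcripts(list(
    list("G1.1", "G1", "chr1", "+", c(1000), c(2000)),
    list("G2.1", "G2", "chr1", "+", c(50000, 52000), c(51000, 53000)),
    list("G3.1", "G3", "chr1", "-", c(100000), c(101000))))
  extend_gene_models(build_gene_models(tx, "metatranscript"), w_ext, task)
}
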