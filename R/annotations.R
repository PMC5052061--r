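# Transcript annotation parsing and union gene-model construction.
#
# All coordinates are handled internally as 0-based half-open intervals,
# the native convention of BED and UCSC table files; SAM positions are
# converted on ingest.

#' Read transcript annotations from a BED file
#'
#' Each BED line becomes one transcript record. BED6 lines (no block
#' definition) yield a single exon spanning the whole feature; BED12 lines
#' yield one exon per block. In per-transcript ("annotations") mode each
#' record later becomes its own gene model, so isoforms are *not*
#' collapsed.
#'
#' @param path Path to a BED6 or BED12 file.
#' @return A `transcripts` data frame with columns `transcript_id`, `gene`,
#'   `chrom`, `strand`, `tx_start`, `tx_end` and list columns
#'   `exon_starts` / `exon_ends` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  nf <- vapply(strsplit(lines[body], "\t"), length, integer(1))
  if (any(nf < 6)) {
    bad <- which(body)[which(nf < 6)[1]]
    stop("malformed BED line ", bad, " in ", path, ": fewer than 6 fields")
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED file ", path,
                                          ": ", conditionMessage(e)))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("strand is required for end-sequencing; BED line(s) ",
         paste(which(body)[which(strand == "*")], collapse = ", "),
         " have no strand")
  }
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name) || anyNA(name)) {
    name <- ifelse(rep(is.null(name), length(gr)) | is.na(name),
                   paste0("tx", seq_along(gr)), name)
  }
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) {
    ex_s <- as.list(start0)
    ex_e <- as.list(end0)
  } else {
    # rtracklayer reports blocks 1-based relative to the feature start
    ex_s <- mapply(function(s0, bl) s0 + BiocGenerics::start(bl) - 1L,
                   start0, blocks, SIMPLIFY = FALSE)
    ex_e <- mapply(function(s0, bl) s0 + BiocGenerics::end(bl),
                   start0, blocks, SIMPLIFY = FALSE)
  }
  tx <- data.frame(transcript_id = name, gene = name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = strand, tx_start = start0, tx_end = end0,
                   stringsAsFactors = FALSE)
  tx$exon_starts <- lapply(ex_s, as.integer)
  tx$exon_ends <- lapply(ex_e, as.integer)
  validate_transcripts(tx, path)
}

#' Read a UCSC Table Browser style transcript table
#'
#' Tab-delimited with a header row; required columns are `name`, `chrom`,
#' `strand`, `txStart`, `txEnd`, `exonStarts`, `exonEnds` and `name2` (the
#' gene symbol). Column order is free, extra columns are ignored, and the
#' UCSC trailing-comma dialect in the exon lists is tolerated.
#'
#' @param path Path to the tab-delimited table.
#' @return A `transcripts` data frame (see [read_bed()]) with `gene` taken
#'   from `name2`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "")
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  req <- c("name", "chrom", "strand", "txStart", "txEnd",
           "exonStarts", "exonEnds", "name2")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop("gene table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  split_coords <- function(x) {
    lapply(strsplit(as.character(x), ","), function(v) {
      v <- v[nzchar(v)]
      as.integer(v)
    })
  }
  ex_s <- split_coords(tab$exonStarts)
  ex_e <- split_coords(tab$exonEnds)
  bad <- which(lengths(ex_s) != lengths(ex_e))
  if (length(bad) > 0) {
    stop("gene table row ", bad[1], " (", tab$name[bad[1]],
         "): exonStarts and exonEnds have different lengths")
  }
  tx <- data.frame(transcript_id = as.character(tab$name),
                   gene = as.character(tab$name2),
                   chrom = as.character(tab$chrom),
                   strand = as.character(tab$strand),
                   tx_start = as.integer(tab$txStart),
                   tx_end = as.integer(tab$txEnd),
                   stringsAsFactors = FALSE)
  tx$exon_starts <- ex_s
  tx$exon_ends <- ex_e
  validate_transcripts(tx, path)
}

validate_transcripts <- function(tx, src = "input") {
  if (any(!tx$strand %in% c("+", "-"))) {
    bad <- which(!tx$strand %in% c("+", "-"))[1]
    stop("transcript ", tx$transcript_id[bad], " in ", src,
         " has invalid strand '", tx$strand[bad], "' (must be + or -)")
  }
  if (any(tx$tx_start >= tx$tx_end)) {
    bad <- which(tx$tx_start >= tx$tx_end)[1]
    stop("transcript ", tx$transcript_id[bad], " in ", src,
         " has txStart >= txEnd")
  }
  for (i in seq_len(nrow(tx))) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    if (length(s) == 0 || any(is.na(s)) || any(is.na(e)))
      stop("transcript ", tx$transcript_id[i], " in ", src,
           ": empty or non-numeric exon list")
    if (any(s >= e) || is.unsorted(s, strictly = TRUE) ||
        any(e[-length(e)] > s[-1]))
      stop("transcript ", tx$transcript_id[i], " in ", src,
           ": exons must be sorted, non-empty and non-overlapping")
  }
  class(tx) <- c("transcripts", "data.frame")
  tx
}

#' Collapse transcripts into gene models
#'
#' In `"metatranscript"` mode all isoforms sharing a gene symbol are
#' collapsed into a single union model whose exonic blocks are the interval
#' union of all isoform exons. The first transcript seen for a gene fixes
#' its chromosome and strand; later isoforms that disagree are dropped with
#' a `"New isoform mismatch for <gene>"` warning giving their coordinates.
#' In `"per_transcript"` mode every transcript becomes its own model, keyed
#' by transcript id.
#'
#' @param tx A `transcripts` data frame from [read_bed()] or
#'   [read_gene_table()].
#' @param collapse `"metatranscript"` (gene-level union, the `-geneMapping`
#'   behaviour) or `"per_transcript"` (the `-annotations` behaviour).
#' @return A `gene_models` data frame with one row per model: `gene`,
#'   `chrom`, `strand`, list columns `block_start` / `block_end` holding
#'   the sorted disjoint exonic blocks, extension fields `ext_start` /
#'   `ext_end` (NA until [extend_gene_models()] is applied) and the
#'   effective scanned length `L`.
#' @export
build_gene_models <- function(tx, collapse = c("metatranscript",
                                               "per_transcript")) {
  collapse <- match.arg(collapse)
  stopifnot(is.data.frame(tx), nrow(tx) > 0)
  if (collapse == "per_transcript") {
    keys <- tx$transcript_id
    groups <- split(seq_len(nrow(tx)), factor(keys, levels = unique(keys)))
  } else {
    groups <- split(seq_len(nrow(tx)),
                    factor(tx$gene, levels = unique(tx$gene)))
  }
  n <- length(groups)
  gene <- names(groups)
  chrom <- character(n); strand <- character(n)
  bs <- vector("list", n); be <- vector("list", n)
  for (j in seq_len(n)) {
    idx <- groups[[j]]
    first <- idx[1]
    chrom[j] <- tx$chrom[first]
    strand[j] <- tx$strand[first]
    keep <- idx[tx$chrom[idx] == chrom[j] & tx$strand[idx] == strand[j]]
    drop <- setdiff(idx, keep)
    for (d in drop) {
      warning("New isoform mismatch for ", gene[j], ": ", tx$chrom[d], ":",
              tx$tx_start[d], "-", tx$tx_end[d], "(", tx$strand[d], ")",
              call. = FALSE)
    }
    ir <- IRanges::reduce(IRanges::IRanges(
      start = unlist(tx$exon_starts[keep]) + 1L,
      end = unlist(tx$exon_ends[keep])))
    bs[[j]] <- BiocGenerics::start(ir) - 1L
    be[[j]] <- BiocGenerics::end(ir)
  }
  models <- data.frame(gene = gene, chrom = chrom, strand = strand,
                       stringsAsFactors = FALSE)
  models$block_start <- bs
  models$block_end <- be
  models$ext_start <- rep(NA_integer_, n)
  models$ext_end <- rep(NA_integer_, n)
  models$L <- vapply(seq_len(n),
                     function(j) sum(be[[j]] - bs[[j]]), numeric(1))
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Extend gene models past the annotated transcript end
#'
#' Appends an extension of up to `w_ext` bases past the 3' end
#' (`task = "score3p"`) or 5' end (`task = "score5p"`) of each model, in
#' the strand-appropriate genomic direction, to capture reads from
#' unannotated termini. The extension is truncated at the annotated span of
#' the nearest gene model on the same strand and chromosome; opposite-strand
#' neighbours never truncate. Exact abutment yields a zero-length extension.
#'
#' @param models A `gene_models` data frame.
#' @param w_ext Maximum extension length in bases (>= 0).
#' @param task `"score3p"` or `"score5p"`: which transcript end to extend.
#' @return The models with `ext_start` / `ext_end` filled in where an
#'   extension of positive length was possible, and `L` updated.
#' @export
extend_gene_models <- function(models, w_ext, task = c("score3p", "score5p")) {
  task <- match.arg(task)
  stopifnot(w_ext >= 0)
  # reset any previous extension so the operation is idempotent
  models$ext_start <- rep(NA_integer_, nrow(models))
  models$ext_end <- rep(NA_integer_, nrow(models))
  span_s <- vapply(models$block_start, min, numeric(1))
  span_e <- vapply(models$block_end, max, numeric(1))
  models$L <- vapply(seq_len(nrow(models)), function(j) {
    sum(models$block_end[[j]] - models$block_start[[j]])
  }, numeric(1))
  if (w_ext == 0) return(models)
  # extend on the high-coordinate side for (+, 3') and (-, 5'),
  # on the low-coordinate side otherwise
  high_side <- (models$strand == "+") == (task == "score3p")
  for (j in seq_len(nrow(models))) {
    same <- which(models$chrom == models$chrom[j] &
                  models$strand == models$strand[j])
    same <- setdiff(same, j)
    if (high_side[j]) {
      nb <- same[span_e[same] > span_e[j]]
      gap <- if (length(nb) == 0) Inf else
        min(pmax(0, span_s[nb] - span_e[j]))
      len <- min(w_ext, gap)
      if (len > 0) {
        models$ext_start[j] <- as.integer(span_e[j])
        models$ext_end[j] <- as.integer(span_e[j] + len)
      }
    } else {
      nb <- same[span_s[same] < span_s[j]]
      gap <- if (length(nb) == 0) Inf else
        min(pmax(0, span_s[j] - span_e[nb]))
      len <- min(w_ext, gap)
      if (len > 0) {
        models$ext_start[j] <- as.integer(span_s[j] - len)
        models$ext_end[j] <- as.integer(span_s[j])
      }
    }
    if (!is.na(models$ext_start[j]))
      models$L[j] <- models$L[j] + models$ext_end[j] - models$ext_start[j]
  }
  models
}

# All blocks of model i (annotated exonic blocks plus extension), sorted.
model_all_blocks <- function(models, i) {
  s <- models$block_start[[i]]
  e <- models$block_end[[i]]
  if (!is.na(models$ext_start[i])) {
    s <- c(s, models$ext_start[i])
    e <- c(e, models$ext_end[i])
  }
  o <- order(s)
  cbind(start = s[o], end = e[o])
}

# Genome-wide block index as a GRanges: one range per (possibly extended)
# block, with the owning model row and the cumulative transcript-left
# offset of the block start. Used for read assignment and coordinate
# mapping.
model_index <- function(models) {
  blk <- lapply(seq_len(nrow(models)), function(i) model_all_blocks(models, i))
  nb <- vapply(blk, nrow, integer(1))
  mi <- rep(seq_len(nrow(models)), nb)
  s <- unlist(lapply(blk, function(b) b[, "start"]), use.names = FALSE)
  e <- unlist(lapply(blk, function(b) b[, "end"]), use.names = FALSE)
  cum0 <- unlist(lapply(blk, function(b) {
    w <- b[, "end"] - b[, "start"]
    c(0, cumsum(w))[seq_along(w)]
  }), use.names = FALSE)
  chroms <- unique(models$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(models$chrom[mi], levels = chroms),
    ranges = IRanges::IRanges(start = s + 1L, end = e),
    strand = models$strand[mi])
  S4Vectors::mcols(gr)$model <- mi
  S4Vectors::mcols(gr)$cum0 <- cum0
  S4Vectors::mcols(gr)$bstart <- s
  gr
}

# Map transcript-space coordinates (0-based, oriented 5'->3' along the
# model strand, extension included) back to genomic 0-based positions.
tpos_to_genomic <- function(models, i, tpos) {
  b <- model_all_blocks(models, i)
  w <- b[, "end"] - b[, "start"]
  cum <- c(0, cumsum(w))
  L <- sum(w)
  off <- if (models$strand[i] == "+") tpos else L - 1 - tpos
  j <- findInterval(off, cum, rightmost.closed = FALSE)
  b[j, "start"] + (off - cum[j])
}
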