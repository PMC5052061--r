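# Alignment ingest: SAM/BAM streaming, CIGAR block arithmetic,
# low-complexity filtering and strand-aware counting positions.

#' Read an experiment list file
#'
#' Each line holds an experiment identifier, a tab, and the path of one
#' SAM/BAM alignment file. Multiple lines may share an experiment id; their
#' reads are pooled as if concatenated. Only the first tab separates the
#' two fields, so both may contain spaces.
#'
#' @param path Path to the tab-separated list file.
#' @return A named list mapping experiment id to a character vector of
#'   alignment file paths.
#' @export
read_alignment_list <- function(path) {
  if (!file.exists(path)) stop("alignment list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("alignment list file ", path, " is empty")
  tab <- regexpr("\t", lines, fixed = TRUE)
  if (any(tab < 0)) {
    stop("alignment list line ", which(tab < 0)[1],
         " has no tab separator: ", lines[tab < 0][1])
  }
  ids <- substr(lines, 1L, tab - 1L)
  paths <- substring(lines, tab + 1L)
  out <- split(paths, factor(ids, levels = unique(ids)))
  lapply(out, unname)
}

#' Parse CIGAR strings into reference-space alignment blocks
#'
#' Splits each alignment at N (skipped region / intron) operations;
#' M, =, X and D consume reference within a block, I/S/H/P do not.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos0 Integer vector of 0-based leftmost reference positions.
#' @return A list of two-column matrices (`start`, `end`), one per
#'   alignment, 0-based half-open.
#' @export
cigar_ref_blocks <- function(cigar, pos0) {
  stopifnot(length(cigar) == length(pos0))
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  mapply(function(op, p) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", op))
    typ <- substr(op, nchar(op), nchar(op))
    starts <- integer(0); ends <- integer(0)
    cur <- p; open <- NA_integer_
    for (k in seq_along(typ)) {
      t <- typ[k]
      if (t %in% c("M", "=", "X", "D")) {
        if (is.na(open)) open <- cur
        cur <- cur + len[k]
      } else if (t == "N") {
        if (!is.na(open)) {
          starts <- c(starts, open); ends <- c(ends, cur)
          open <- NA_integer_
        }
        cur <- cur + len[k]
      }
      # I, S, H, P: no reference consumed
    }
    if (!is.na(open)) {
      starts <- c(starts, open); ends <- c(ends, cur)
    }
    cbind(start = starts, end = ends)
  }, ops, pos0, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Reference-space width consumed by each CIGAR (M/=/X/D/N ops).
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MDN=X]", cigar))
  vapply(ops, function(op)
    sum(as.integer(sub("[MDN=X]$", "", op))), numeric(1))
}

#' Read aligned reads from a SAM or BAM file
#'
#' Unmapped records are skipped. The NH optional tag supplies the
#' multimapping multiplicity and defaults to 1 when absent (in which case
#' multimapped reads cannot be identified and the multimap policies cannot
#' act on them). In single-cell mode the cell barcode and UMI are parsed
#' from the read name (`<name>:<barcode>:<UMI>`); records with fewer than
#' three colon-separated name fields are skipped with an
#' `"Improper read name"` warning.
#'
#' @param path A SAM (`.sam`) or BAM file.
#' @param sc_prep Logical; parse barcodes/UMIs from read names.
#' @param keep_seq Logical; retain the read sequence (needed for
#'   [at_run_filter()]).
#' @param keep_blocks Logical; attach a list column of spliced
#'   reference-space blocks per read.
#' @return A data frame with one row per mapped alignment record: `qname`,
#'   `chrom`, `strand`, `pos` (0-based leftmost), `ref_width`, `cpos` (the
#'   strand-aware counting position, see [counting_position()]), `nh`,
#'   `seq`, and in single-cell mode `barcode` / `umi`.
#' @export
read_alignments <- function(path, sc_prep = FALSE, keep_seq = TRUE,
                            keep_blocks = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to read SAM file ", path, ": ",
                               conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
    tag = "NH")
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) stop("failed to read alignments from ",
                                           path, ": ", conditionMessage(e)))
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  seqs[!nzchar(seqs)] <- NA_character_
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  nh[is.na(nh)] <- 1L
  reads <- data.frame(
    qname = res$qname,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    pos = res$pos - 1L,
    ref_width = as.integer(cigar_ref_width(res$cigar)),
    nh = as.integer(nh),
    seq = if (keep_seq) seqs else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (keep_blocks) reads$blocks <- cigar_ref_blocks(res$cigar, reads$pos)
  reads$cpos <- counting_position(reads)
  if (sc_prep) {
    parsed <- parse_barcoded_name(reads$qname)
    ok <- !is.na(parsed$barcode)
    reads <- reads[ok, , drop = FALSE]
    reads$qname <- parsed$base[ok]
    reads$barcode <- parsed$barcode[ok]
    reads$umi <- parsed$umi[ok]
    rownames(reads) <- NULL
  }
  reads
}

#' Strand-aware counting position of an aligned read
#'
#' Reduces each alignment to the genomic coordinate of its biological 5'
#' terminus: the first aligned base for `+` strand alignments and the last
#' aligned base for `-` strand alignments, so that read pileups at
#' homologous transcript ends accumulate at mirrored positions on the two
#' strands. The position is independent of whether a 3' or 5' library is
#' being scored; the `task` only selects which transcript end is extended
#' and scanned.
#'
#' @param reads A data frame from [read_alignments()] (columns `pos`,
#'   `ref_width`, `strand`).
#' @return Integer vector of 0-based genomic counting positions.
#' @export
counting_position <- function(reads) {
  ifelse(reads$strand == "-", reads$pos + reads$ref_width - 1L, reads$pos)
}

#' Low-complexity A/T homopolymer filter
#'
#' Flags reads whose sequence contains a continuous run of As, or of Ts,
#' of at least `threshold` bases (case-insensitive). Such reads are
#' typically internal priming artifacts on genomically encoded poly(A)
#' stretches. Reads without a stored sequence cannot be tested and are
#' kept, with a warning.
#'
#' @param x A reads data frame (column `seq`) or a character vector of
#'   sequences.
#' @param threshold Minimum run length (>= 1) that triggers removal.
#' @return Logical vector, `TRUE` for reads to keep.
#' @export
at_run_filter <- function(x, threshold) {
  stopifnot(threshold >= 1)
  seqs <- if (is.data.frame(x)) x$seq else x
  pat <- sprintf("A{%d,}|T{%d,}", as.integer(threshold),
                 as.integer(threshold))
  hit <- grepl(pat, toupper(seqs))
  if (anyNA(seqs)) {
    warning(sum(is.na(seqs)), " read(s) have no sequence; ",
            "A/T filter not applied to them", call. = FALSE)
    hit[is.na(seqs)] <- FALSE
  }
  !hit
}
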