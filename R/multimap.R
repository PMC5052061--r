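# Read-to-gene assignment and the four multimapped-read policies.

#' Assign reads to gene models by counting position
#'
#' A read is assigned to a gene when its counting position falls inside the
#' gene's exonic blocks or extension (introns spliced out). Strand matching
#' is protocol dependent: `"same"` requires the read's genomic strand to
#' equal the gene strand, `"opposite"` requires the reverse (for
#' reverse-stranded protocols), `"ignore"` assigns regardless of strand.
#'
#' @param reads Data frame from [read_alignments()].
#' @param models A `gene_models` data frame (extended as desired).
#' @param strand_mode `"same"`, `"opposite"` or `"ignore"`.
#' @param index Optional pre-built block index from repeated calls.
#' @return An assignment data frame with one row per (alignment, gene) hit:
#'   `read` (row in `reads`), `qname`, `model` (row in `models`), `gene`,
#'   `tpos` (0-based transcript-space coordinate, oriented 5'->3' along the
#'   gene, extension included), `nh`, and `barcode` / `umi` when present.
#' @export
assign_reads <- function(reads, models,
                         strand_mode = c("same", "opposite", "ignore"),
                         index = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(index)) index <- model_index(models)
  if (nrow(reads) == 0) {
    return(data.frame(read = integer(0), qname = character(0),
                      model = integer(0), gene = character(0),
                      tpos = integer(0), nh = integer(0),
                      stringsAsFactors = FALSE))
  }
  rs <- reads$strand
  if (strand_mode == "opposite") rs <- ifelse(rs == "+", "-", "+")
  if (strand_mode == "ignore") rs <- "*"
  lv <- union(GenomeInfoDb::seqlevels(index), unique(reads$chrom))
  GenomeInfoDb::seqlevels(index) <- lv
  q <- GenomicRanges::GRanges(
    seqnames = factor(reads$chrom, levels = lv),
    ranges = IRanges::IRanges(start = reads$cpos + 1L, width = 1L),
    strand = rs)
  hits <- GenomicRanges::findOverlaps(q, index,
                                      ignore.strand = strand_mode == "ignore")
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  mi <- S4Vectors::mcols(index)$model[si]
  off <- S4Vectors::mcols(index)$cum0[si] +
    reads$cpos[qi] - S4Vectors::mcols(index)$bstart[si]
  tpos <- ifelse(models$strand[mi] == "+", off, models$L[mi] - 1 - off)
  out <- data.frame(read = qi, qname = reads$qname[qi], model = mi,
                    gene = models$gene[mi], tpos = as.integer(tpos),
                    nh = reads$nh[qi], stringsAsFactors = FALSE)
  if (!is.null(reads$barcode)) {
    out$barcode <- reads$barcode[qi]
    out$umi <- reads$umi[qi]
  }
  out
}

#' Apply a multimapped-read policy
#'
#' Multimapped reads are those whose NH tag exceeds one. The four policies:
#' \describe{
#'   \item{normal}{every alignment counts with weight 1 at each gene it
#'     hits, so a read mapped to N loci can count up to N times;}
#'   \item{scale}{each alignment contributes a fractional weight of 1/N;}
#'   \item{ignore}{multimapped reads are discarded entirely;}
#'   \item{proper}{alignments of each multimapped read are grouped by read
#'     id; if exactly one (alignment, gene) hit lies inside a gene model
#'     (extension included, introns spliced out) the read is rescued and
#'     assigned there with weight 1, otherwise it is discarded.}
#' }
#'
#' @param assign Assignment data frame from [assign_reads()].
#' @param mode One of `"normal"`, `"scale"`, `"ignore"`, `"proper"`.
#' @return The assignment rows retained under the policy, with a `weight`
#'   column added.
#' @export
apply_multimap_policy <- function(assign, mode = c("normal", "scale",
                                                   "ignore", "proper")) {
  if (length(mode) != 1 || !mode %in% c("normal", "scale", "ignore", "proper"))
    stop("unknown multimap mode: ", paste(mode, collapse = ","),
         " (use normal, scale, ignore or proper)")
  if (mode == "normal") {
    assign$weight <- rep(1, nrow(assign))
  } else if (mode == "scale") {
    assign$weight <- 1 / assign$nh
  } else if (mode == "ignore") {
    assign <- assign[assign$nh == 1L, , drop = FALSE]
    assign$weight <- rep(1, nrow(assign))
  } else {
    uniq <- assign$nh == 1L
    multi <- assign[!uniq, , drop = FALSE]
    nhit <- table(multi$qname)
    rescued <- multi$qname %in% names(nhit)[nhit == 1L]
    assign <- rbind(assign[uniq, , drop = FALSE],
                    multi[rescued, , drop = FALSE])
    assign$weight <- rep(1, nrow(assign))
  }
  rownames(assign) <- NULL
  assign
}
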