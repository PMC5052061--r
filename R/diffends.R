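# Differential end-usage analysis over window-level output: a global test
# for a shift towards shorter (or longer) isoforms, quantified per gene as
# the fraction of reads falling outside the terminal significant window.

#' Read a window-level output table
#'
#' @param path A `<prefix>.window.txt` written by [esat_quantify()].
#' @return Data frame with the fixed columns (`gene`, `chrom`, `start`,
#'   `end`, `strand`, `pvalue`) and one count column per experiment.
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) stop("window table not found: ", path)
  wt <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene", "chrom", "start", "end", "strand", "pvalue")
  missing <- setdiff(req, names(wt))
  if (length(missing) > 0)
    stop("window table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  wt
}

window_sample_columns <- function(wt) {
  setdiff(names(wt), c("gene", "chrom", "start", "end", "strand",
                       "pvalue", "model", "tstart", "tend", "count"))
}

# Index (within a per-gene window subset) of the terminal window: the most
# 3' window in transcript orientation for score3p, the most 5' for
# score5p. Ties on start position go to the window with the larger
# genomic extent.
terminal_window_index <- function(starts, ends, strand, task) {
  want_high <- (strand == "+") == (task == "score3p")
  o <- order(if (want_high) -starts else starts,
             -(ends - starts))
  o[1]
}

#' Eligibility thresholds for the end-usage shift test
#'
#' Defaults follow the reference-sample filters used for differential
#' 3'-end usage: at least 250 reads in total, at least two significant
#' windows, at least 20% of reads in the terminal window, and a
#' maximum-to-minimum window count ratio of at most 1.5 (so that a
#' reduction of terminal-window usage is measurable).
#'
#' @param min_total_reads,min_windows,min_final_fraction,max_window_ratio
#'   The four thresholds.
#' @return An `eligibility_config` list.
#' @export
eligibility_config <- function(min_total_reads = 250, min_windows = 2,
                               min_final_fraction = 0.20,
                               max_window_ratio = 1.5) {
  stopifnot(min_total_reads > 0, min_windows > 0,
            min_final_fraction > 0, min_final_fraction <= 1,
            max_window_ratio > 0)
  structure(list(min_total_reads = min_total_reads,
                 min_windows = min_windows,
                 min_final_fraction = min_final_fraction,
                 max_window_ratio = max_window_ratio),
            class = "eligibility_config")
}

#' Select genes testable for an end-usage shift
#'
#' Applies the eligibility filters to the reference (untreated) sample's
#' window counts only: total reads, number of significant windows,
#' terminal-window fraction, and the max/min window count ratio.
#'
#' @param wt Window table (see [read_window_table()]).
#' @param reference Name of the reference sample column.
#' @param config An [eligibility_config()].
#' @param task `"score3p"` or `"score5p"` (fixes which window is terminal).
#' @return Character vector of testable gene symbols.
#' @export
select_testable_genes <- function(wt, reference,
                                  config = eligibility_config(),
                                  task = c("score3p", "score5p")) {
  task <- match.arg(task)
  if (!reference %in% names(wt))
    stop("reference sample '", reference, "' not found in window table")
  keep <- vapply(split(seq_len(nrow(wt)), wt$gene), function(idx) {
    cnt <- wt[[reference]][idx]
    tot <- sum(cnt)
    if (tot < config$min_total_reads) return(FALSE)
    if (length(idx) < config$min_windows) return(FALSE)
    ti <- terminal_window_index(wt$start[idx], wt$end[idx],
                                wt$strand[idx][1], task)
    if (cnt[ti] / tot < config$min_final_fraction) return(FALSE)
    if (min(cnt) <= 0 || max(cnt) / min(cnt) > config$max_window_ratio)
      return(FALSE)
    TRUE
  }, logical(1))
  names(keep)[keep]
}

#' Per-gene, per-sample end-usage fractions
#'
#' For each gene and sample, the fraction of the gene's windowed reads that
#' fall *outside* the terminal window (the most 3' window for a 3' library;
#' the most 5' for a 5' library): `1 - terminal / total`. A sample with no
#' reads on a gene yields NA.
#'
#' @param wt Window table.
#' @param genes Genes to evaluate (typically from
#'   [select_testable_genes()]).
#' @param samples Sample columns to evaluate (default: all).
#' @param task `"score3p"` or `"score5p"`.
#' @return Numeric matrix, genes in rows, samples in columns, entries in
#'   `[0, 1]` or NA.
#' @export
end_usage_matrix <- function(wt, genes = unique(wt$gene), samples = NULL,
                             task = c("score3p", "score5p")) {
  task <- match.arg(task)
  if (is.null(samples)) samples <- window_sample_columns(wt)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  by_gene <- split(seq_len(nrow(wt)), wt$gene)
  for (g in intersect(genes, names(by_gene))) {
    idx <- by_gene[[g]]
    ti <- terminal_window_index(wt$start[idx], wt$end[idx],
                                wt$strand[idx][1], task)
    for (s in samples) {
      tot <- sum(wt[[s]][idx])
      if (tot > 0) m[g, s] <- 1 - wt[[s]][idx][ti] / tot
    }
  }
  m
}

#' Test for a global shift in end usage
#'
#' Compares the distribution of end-usage fractions of each non-reference
#' sample against the reference. The primary test is the paired Wilcoxon
#' signed-rank test, matching fractions by gene; `paired = FALSE` gives the
#' unpaired Mann-Whitney rank-sum alternative. Distribution summaries
#' (median and quartiles) suitable for boxplots are returned alongside the
#' p-values.
#'
#' @param m End-usage matrix from [end_usage_matrix()].
#' @param reference Reference sample (column) name.
#' @param paired Logical; match genes between samples (default TRUE).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return Data frame with one row per sample: `sample`, `n`, `median`,
#'   `mean`, `q25`, `q75`, `pvalue` (NA for the reference row).
#' @export
shift_test <- function(m, reference, paired = TRUE,
                       alternative = "two.sided") {
  if (!reference %in% colnames(m))
    stop("reference sample '", reference, "' not found")
  if (ncol(m) < 2) stop("need at least two samples to test for a shift")
  out <- lapply(colnames(m), function(s) {
    x <- m[, s]
    p <- NA_real_
    if (s != reference) {
      ok <- stats::complete.cases(m[, c(s, reference)])
      if (!any(ok)) stop("no genes with data in both '", s, "' and '",
                         reference, "'")
      xs <- m[ok, s]; xr <- m[ok, reference]
      p <- if (all(xs == xr)) 1 else
        stats::wilcox.test(xs, xr, paired = paired, exact = FALSE,
                           alternative = alternative)$p.value
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(sample = s, n = sum(!is.na(x)), median = q[2],
               mean = mean(x, na.rm = TRUE), q25 = q[1], q75 = q[3],
               pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
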