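# Single-cell preprocessing: barcode/UMI read names, PCR duplicate
# removal, barcode thresholding (knee or explicit minimum) and the
# cell / gene quality filters.

#' Parse barcode and UMI from read names
#'
#' Single-cell reads carry the cell barcode and UMI appended to the read
#' name as `<read name>:<cell barcode>:<UMI>`. The last two colon-separated
#' fields are taken as barcode and UMI (in that order), so read names that
#' themselves contain colons are handled; no assumption is made about
#' barcode or UMI length. Names with fewer than three fields are flagged
#' with an `"Improper read name"` warning and return NA (callers skip such
#' reads).
#'
#' @param names Character vector of read names.
#' @return Data frame with columns `base`, `barcode`, `umi` (NA for
#'   improper names).
#' @export
parse_barcoded_name <- function(names) {
  parts <- strsplit(names, ":", fixed = TRUE)
  nf <- lengths(parts)
  ok <- nf >= 3L
  if (any(!ok)) {
    warning("Improper read name: ",
            paste(utils::head(names[!ok], 5L), collapse = ", "),
            if (sum(!ok) > 5L) sprintf(" (and %d more)", sum(!ok) - 5L),
            "; read(s) skipped", call. = FALSE)
  }
  base <- barcode <- umi <- rep(NA_character_, length(names))
  base[ok] <- vapply(parts[ok], function(p)
    paste(p[seq_len(length(p) - 2L)], collapse = ":"), character(1))
  barcode[ok] <- vapply(parts[ok], function(p) p[length(p) - 1L],
                        character(1))
  umi[ok] <- vapply(parts[ok], function(p) p[length(p)], character(1))
  data.frame(base = base, barcode = barcode, umi = umi,
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicates by (barcode, UMI, gene)
#'
#' Reads sharing a cell barcode and UMI that map to the same gene are PCR
#' copies of one original molecule: a single instance is sufficient to
#' count it, so the first occurrence (in input stream order) is retained
#' and all later occurrences are dropped. The same (barcode, UMI) pair
#' mapping to two different genes counts once per gene. Retained reads per
#' barcode are tallied into the barcode table used for cell calling.
#'
#' @param assign Assignment data frame carrying `barcode`, `umi` and
#'   `model` columns (see [assign_reads()]).
#' @return List with `assignments` (the retained rows) and `barcode_table`
#'   (data frame `barcode`, `count`, sorted by decreasing count).
#' @export
dedup_umis <- function(assign) {
  stopifnot(!is.null(assign$barcode), !is.null(assign$umi))
  key <- paste(assign$barcode, assign$umi, assign$model, sep = "\r")
  keep <- !duplicated(key)
  retained <- assign[keep, , drop = FALSE]
  rownames(retained) <- NULL
  counts <- table(retained$barcode)
  bt <- data.frame(barcode = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  bt <- bt[order(-bt$count, bt$barcode), , drop = FALSE]
  rownames(bt) <- NULL
  list(assignments = retained, barcode_table = bt)
}

#' Threshold barcodes into valid cells and ambient noise
#'
#' With an explicit `bc_min`, barcodes with at least that many UMI-filtered
#' reads are valid. Without one, the threshold is found automatically at
#' the knee of the barcode-rank curve: barcodes are sorted by decreasing
#' count, the point of maximum distance above the chord of the
#' (log10 rank, log10 count) curve locates the knee region, and the
#' threshold is placed at the geometric midpoint of the steepest
#' single-step count drop near the knee, i.e. inside the gap that
#' separates true cells from ambient barcodes.
#'
#' @param barcode_table Data frame with `barcode` and `count` columns (or a
#'   named count vector).
#' @param bc_min Explicit minimum count, or `NULL` for the automatic knee.
#' @return List with `threshold` (minimum count considered a cell) and
#'   `valid` (character vector of valid barcodes, decreasing count order).
#' @export
barcode_threshold <- function(barcode_table, bc_min = NULL) {
  if (!is.data.frame(barcode_table)) {
    barcode_table <- data.frame(barcode = names(barcode_table),
                                count = as.integer(barcode_table),
                                stringsAsFactors = FALSE)
  }
  stopifnot(nrow(barcode_table) > 0)
  bt <- barcode_table[order(-barcode_table$count, barcode_table$barcode), ,
                      drop = FALSE]
  if (!is.null(bc_min)) {
    threshold <- as.integer(bc_min)
  } else if (nrow(bt) < 3) {
    threshold <- min(bt$count)
  } else {
    x <- log10(seq_len(nrow(bt)))
    y <- log10(pmax(bt$count, 1L))
    dx <- x[length(x)] - x[1]
    dy <- y[length(y)] - y[1]
    # signed area cross-product; positive above the (falling) chord
    cross <- dx * (y - y[1]) - dy * (x - x[1])
    r_knee <- which.max(cross)
    # the cliff: steepest one-step log-count drop in the knee
    # neighbourhood; the threshold sits mid-gap, robust to the order-
    # statistics noise of the cell plateau
    lo <- max(1L, r_knee %/% 2L)
    hi <- min(nrow(bt) - 1L, 2L * r_knee + 10L)
    drops <- y[lo:hi] - y[(lo + 1L):(hi + 1L)]
    r_cliff <- lo + which.max(drops) - 1L
    threshold <- as.integer(ceiling(sqrt(
      as.numeric(bt$count[r_cliff]) * max(1, bt$count[r_cliff + 1L]))))
  }
  valid <- bt$barcode[bt$count >= threshold]
  if (length(valid) == 0) stop("no valid cells: all ", nrow(bt),
                               " barcodes fall below threshold ", threshold)
  list(threshold = threshold, valid = valid)
}

#' Build a cell x gene UMI count matrix
#'
#' @param assign Deduplicated, barcode-filtered assignments.
#' @param models The `gene_models` the assignments refer to (fixes row
#'   order; genes without reads get zero rows).
#' @param barcodes Optional barcode ordering (defaults to decreasing total).
#' @return Integer-valued matrix, genes in rows, cell barcodes in columns.
#' @export
cell_gene_matrix <- function(assign, models, barcodes = NULL) {
  if (is.null(barcodes)) {
    tot <- sort(table(assign$barcode), decreasing = TRUE)
    barcodes <- names(tot)
  }
  m <- matrix(0, nrow = nrow(models), ncol = length(barcodes),
              dimnames = list(models$gene, barcodes))
  if (nrow(assign) > 0) {
    agg <- rowsum(assign$weight,
                  paste(assign$model, assign$barcode, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    mi <- as.integer(vapply(key, `[`, character(1), 1L))
    bc <- vapply(key, `[`, character(1), 2L)
    sel <- bc %in% barcodes
    m[cbind(mi[sel], match(bc[sel], barcodes))] <- agg[sel, 1]
  }
  m
}

#' Cell and gene quality filters
#'
#' First removes cells (columns) with fewer than `min_cell_umis` total
#' UMI-filtered reads, then keeps genes (rows) with at least `min_reads`
#' reads in at least `min_cells` of the remaining cells.
#'
#' @param mat Genes x cells count matrix.
#' @param min_cell_umis Minimum total UMI-filtered reads per cell
#'   (default 1000).
#' @param min_reads,min_cells Gene retention rule: `>= min_reads` reads in
#'   `>= min_cells` cells (defaults 3 and 2).
#' @return The filtered matrix.
#' @export
qc_filter <- function(mat, min_cell_umis = 1000, min_reads = 3,
                      min_cells = 2) {
  stopifnot(is.matrix(mat))
  keep_cells <- colSums(mat) >= min_cell_umis
  mat <- mat[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(mat >= min_reads) >= min_cells
  mat <- mat[keep_genes, , drop = FALSE]
  if (nrow(mat) == 0 || ncol(mat) == 0)
    stop("QC filtering removed all ",
         if (ncol(mat) == 0) "cells" else "genes")
  mat
}

#' Write a cell x gene matrix as TSV and MatrixMarket triplet text
#'
#' Writes `<prefix>.matrix.txt` (tab-delimited, genes in rows),
#' `<prefix>.mtx` (MatrixMarket coordinate format) plus `<prefix>.genes.txt`
#' and `<prefix>.barcodes.txt` naming the MTX rows and columns.
#'
#' @param mat Genes x cells matrix.
#' @param prefix Output file prefix.
#' @return Invisibly, the written file paths.
#' @export
write_cell_gene_matrix <- function(mat, prefix) {
  tsv <- paste0(prefix, ".matrix.txt")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                              "generalMatrix"), mtx)
  gpath <- paste0(prefix, ".genes.txt")
  bpath <- paste0(prefix, ".barcodes.txt")
  writeLines(rownames(mat), gpath)
  writeLines(colnames(mat), bpath)
  invisible(c(tsv, mtx, gpath, bpath))
}

#' Single-cell quantification pipeline
#'
#' Convenience wrapper: reads barcoded alignments, assigns reads to gene
#' models, applies the multimap policy, removes PCR duplicates, thresholds
#' barcodes and returns the cell x gene UMI matrix together with the
#' barcode table.
#'
#' @inheritParams esat_quantify
#' @param qc Logical; apply [qc_filter()] with its defaults.
#' @return List with `matrix` (genes x cells), `barcode_table`,
#'   `threshold` and `models`.
#' @export
sc_quantify <- function(alignments, annotation, config = NULL,
                        bc_min = NULL, qc = FALSE, out_prefix = NULL, ...) {
  if (is.null(config)) config <- scan_config(...)
  if (is.character(alignments)) alignments <-
      stats::setNames(list(alignments), "sc")
  if (is.character(annotation)) {
    annotation <- if (grepl("\\.bed$", annotation, ignore.case = TRUE))
      read_bed(annotation) else read_gene_table(annotation)
  }
  models <- build_gene_models(annotation, "metatranscript")
  models <- extend_gene_models(models, config$w_ext, config$task)
  index <- model_index(models)
  per_exp <- lapply(alignments, prepare_experiment, models = models,
                    config = config, index = index, sc_prep = TRUE)
  combined <- do.call(rbind, c(per_exp, list(make.row.names = FALSE)))
  dd <- dedup_umis(combined)
  thr <- barcode_threshold(dd$barcode_table, bc_min)
  kept <- dd$assignments[dd$assignments$barcode %in% thr$valid, ,
                         drop = FALSE]
  mat <- cell_gene_matrix(kept, models, barcodes = thr$valid)
  if (qc) mat <- qc_filter(mat)
  if (!is.null(out_prefix)) write_cell_gene_matrix(mat, out_prefix)
  list(matrix = mat, barcode_table = dd$barcode_table,
       threshold = thr$threshold, models = models)
}
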