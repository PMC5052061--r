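test_that("BED reading preserves blocks, handles 6-column lines, enforces strand", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\ttxA\t0\t+\t100\t500\t0\t2\t50,100,\t0,300,",
    "chr2\t2000\t2600\ttxB\t0\t-\t2000\t2600\t0\t1\t600,\t0,"), bed)
  tx <- read_bed(bed)
  expect_equal(nrow(tx), 2)
  expect_equal(tx$exon_starts[[1]], c(100L, 400L))
  expect_equal(tx$exon_ends[[1]], c(150L, 500L))
  expect_equal(tx$exon_starts[[2]], 2000L)
  expect_equal(tx$exon_ends[[2]], 2600L)
  expect_equal(tx$strand, c("+", "-"))

  # BED6 without block definition: single exon spanning the feature
  bed6 <- tempfile(fileext = ".bed")
  writeLines("chr2\t2000\t2600\ttxB\t0\t-", bed6)
  tx6 <- read_bed(bed6)
  expect_equal(tx6$exon_starts[[1]], 2000L)
  expect_equal(tx6$exon_ends[[1]], 2600L)

  nostrand <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t500\ttxA\t0\t.", nostrand)
  expect_error(read_bed(nostrand), "strand")

  malformed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\ttxA\t0\t+", "chr1\t9"), malformed)
  expect_error(read_bed(malformed), "line 2")
})

test_that("gene table reading is header-driven and tolerates trailing commas", {
  tab <- tempfile(fileext = ".txt")
  writeLines(c(
    "name\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds\tname2\tscore",
    "nm1\tchr1\t+\t100\t600\t100,500,\t200,600,\tGENEA\t7",
    "nm2\tchr1\t+\t100\t650\t100,\t650,\tGENEA\t7"), tab)
  tx <- read_gene_table(tab)
  expect_equal(tx$exon_starts[[1]], c(100L, 500L))
  expect_equal(tx$exon_ends[[1]], c(200L, 600L))
  expect_equal(tx$gene, c("GENEA", "GENEA"))
  expect_equal(tx$transcript_id, c("nm1", "nm2"))

  missing <- tempfile(fileext = ".txt")
  writeLines(c("name\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               "nm1\tchr1\t+\t100\t600\t100,\t600,"), missing)
  expect_error(read_gene_table(missing), "name2")

  bad <- tempfile(fileext = ".txt")
  writeLines(c(
    "name\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds\tname2",
    "nm1\tchr1\t+\t100\t600\t100,500,\t600,\tGENEA"), bad)
  expect_error(read_gene_table(bad), "different lengths")
})

test_that("metatranscript collapse takes interval unions and warns on conflicts", {
  tx <- make_transcripts(list(
    list("A", "G", "chr1", "+", c(0, 200), c(100, 300)),
    list("B", "G", "chr1", "+", c(50, 200), c(120, 350))))
  m <- build_gene_models(tx, "metatranscript")
  expect_equal(nrow(m), 1)
  expect_equal(m$block_start[[1]], c(0L, 200L))
  expect_equal(m$block_end[[1]], c(120L, 350L))
  expect_equal(m$L, 120 + 150)

  # second isoform on the other strand is dropped with a warning
  tx2 <- make_transcripts(list(
    list("A", "G", "chr1", "+", c(0), c(100)),
    list("B", "G", "chr1", "-", c(50), c(120))))
  expect_warning(m2 <- build_gene_models(tx2, "metatranscript"),
                 "New isoform mismatch for G")
  expect_equal(m2$block_start[[1]], 0L)
  expect_equal(m2$block_end[[1]], 100L)
  expect_equal(m2$strand, "+")

  # single-isoform gene: model identical to the transcript
  tx3 <- make_transcripts(list(list("A", "G", "chr1", "-", c(10, 50), c(20, 80))))
  m3 <- build_gene_models(tx3, "metatranscript")
  expect_equal(m3$block_start[[1]], c(10L, 50L))
  expect_equal(m3$block_end[[1]], c(20L, 80L))

  # per-transcript mode keeps isoforms separate
  m4 <- build_gene_models(tx, "per_transcript")
  expect_equal(nrow(m4), 2)
  expect_equal(m4$gene, c("A", "B"))
})

test_that("union model length dominates isoforms; collapse order-insensitive", {
  set.seed(42)
  for (rep in 1:20) {
    n_iso <- sample(2:4, 1)
    defs <- lapply(seq_len(n_iso), function(i) {
      ns <- sample(1:3, 1)
      s <- sort(sample(seq(0, 900, by = 10), ns))
      e <- s + sample(5:9, ns, replace = TRUE)
      list(paste0("iso", i), "G", "chr1", "+", s, e)
    })
    tx <- make_transcripts(defs)
    m <- build_gene_models(tx, "metatranscript")
    iso_len <- vapply(defs, function(d) sum(d[[6]] - d[[5]]), numeric(1))
    expect_true(all(m$L >= iso_len))
    m_rev <- build_gene_models(tx[rev(seq_len(nrow(tx))), ], "metatranscript")
    expect_equal(m$block_start, m_rev$block_start)
    expect_equal(m$block_end, m_rev$block_end)
  }
})

test_that("end extension is strand-aware, truncated at same-strand neighbours", {
  tx <- make_transcripts(list(
    list("A", "GA", "chr1", "+", c(0), c(1000)),
    list("B", "GB", "chr1", "+", c(3000), c(4000)),
    list("C", "GC", "chr1", "-", c(1500), c(1600))))
  m <- extend_gene_models(build_gene_models(tx, "metatranscript"),
                          5000, "score3p")
  # + strand gene ends at 1000; nearest same-strand neighbour starts at
  # 3000 (the - strand gene in between does not truncate)
  expect_equal(m$ext_start[1], 1000L)
  expect_equal(m$ext_end[1], 3000L)
  expect_equal(m$L[1], 1000 + 2000)
  # GB extends freely to the right
  expect_equal(m$ext_end[2] - m$ext_start[2], 5000L)
  # - strand 3' extension goes to lower coordinates, truncated by nothing
  expect_equal(m$ext_end[3], 1500L)
  expect_equal(m$ext_start[3], 1500L - 5000L)

  # w_ext 0 leaves models unchanged
  m0 <- extend_gene_models(build_gene_models(tx, "metatranscript"),
                           0, "score3p")
  expect_true(all(is.na(m0$ext_start)))
  expect_equal(m0$L[1], 1000)

  # exact abutment: extension length 0, not an error
  tx2 <- make_transcripts(list(
    list("A", "GA", "chr1", "+", c(0), c(1000)),
    list("B", "GB", "chr1", "+", c(1000), c(2000))))
  m2 <- extend_gene_models(build_gene_models(tx2, "metatranscript"),
                           5000, "score3p")
  expect_true(is.na(m2$ext_start[1]))

  # score5p extends the other end
  m5 <- extend_gene_models(build_gene_models(tx, "metatranscript"),
                           400, "score5p")
  expect_equal(m5$ext_start[1], -400L)
  expect_equal(m5$ext_end[1], 0L)
  expect_equal(m5$ext_start[3], 1600L)

  # extension is idempotent
  m_twice <- extend_gene_models(m, 5000, "score3p")
  expect_equal(m_twice$L, m$L)
  expect_equal(m_twice$ext_start, m$ext_start)
})

test_that("extended same-strand models stay pairwise disjoint", {
  set.seed(7)
  for (rep in 1:10) {
    starts <- sort(sample(seq(0, 50000, by = 100), 6))
    defs <- lapply(seq_along(starts), function(i)
      list(paste0("t", i), paste0("g", i), "chr1",
           sample(c("+", "-"), 1), starts[i], starts[i] + 80))
    m <- extend_gene_models(build_gene_models(make_transcripts(defs),
                                              "metatranscript"),
                            sample(c(500, 5000), 1), "score3p")
    for (s in c("+", "-")) {
      idx <- which(m$strand == s)
      if (length(idx) < 2) next
      spans <- lapply(idx, function(i) {
        b <- rbind(cbind(m$block_start[[i]], m$block_end[[i]]),
                   if (!is.na(m$ext_start[i]))
                     cbind(m$ext_start[i], m$ext_end[i]))
        b
      })
      ir <- IRanges::IRanges(
        start = unlist(lapply(spans, function(b) b[, 1])) + 1L,
        end = unlist(lapply(spans, function(b) b[, 2])))
      expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                   sum(IRanges::width(ir)))
    }
  }
})
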