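# Scan-statistic p-value and the two-pass window discovery.

test_that("scan p-value edge cases and monotonicity", {
  expect_equal(scan_pvalue(0, 10, 1000, 50), 1)
  expect_equal(scan_pvalue(11, 10, 1000, 50), 0)
  expect_equal(scan_pvalue(3, 0, 1000, 50), 1)
  # window spanning the whole gene holds every read
  expect_equal(scan_pvalue(10, 10, 50, 50), 1)
  # monotone non-increasing in k
  for (N in c(5, 50, 500)) {
    p <- scan_pvalue(0:N, N, 2000, 50)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
  # monotone non-decreasing in N at fixed k
  for (k in c(2, 5, 10)) {
    p <- vapply(seq(k, 300, by = 7), function(N)
      scan_pvalue(k, N, 2000, 50), numeric(1))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("exhaustive oracle is exact on the enumerable case", {
  or <- mc_scan_oracle(N = 2, L = 4, w = 2)
  expect_equal(or$method, "exhaustive")
  # 10 of the 16 equally likely placements put both reads in one window
  expect_equal(tail_prob(or, 2), 10 / 16)
  expect_equal(tail_prob(or, 0), 1)
  expect_equal(tail_prob(or, 3), 0)
  # analytic approximation within a factor of 2 of the exact value
  expect_lt(abs(log10(scan_pvalue(2, 2, 4, 2)) - log10(0.625)), log10(2))
})

test_that("Monte-Carlo oracle agrees with enumeration on a small case", {
  ex <- mc_scan_oracle(N = 3, L = 6, w = 2)
  mc <- mc_scan_oracle(N = 3, L = 6, w = 2, reps = 20000, seed = 4,
                       exhaustive = FALSE)
  for (k in 1:3) {
    expect_lt(abs(tail_prob(mc, k) - tail_prob(ex, k)), 0.02)
  }
})

test_that("pooled scan finds pileups and respects window geometry", {
  m <- simple_models()
  cfg <- scan_config(w_len = 100, w_olap = 50, sig_test = 0.05)
  # all reads of G1 piled at one position
  r <- make_reads(sprintf("p%02d", 1:40), "chr1", "+", rep(1500L, 40))
  asn <- apply_multimap_policy(assign_reads(r, m), "normal")
  cand <- pooled_scan(m, asn, cfg)
  expect_true(all(cand$gene == "G1"))
  # windows step by w_len - w_olap and the pileup windows hold all reads
  expect_true(all(diff(unique(cand$tstart)) %% 50 == 0))
  expect_equal(max(cand$count), 40)
  covering <- cand[cand$tstart <= 500 & cand$tend > 500, ]
  expect_true(all(covering$count == 40))

  # sig_test = 1 retains every window containing at least one read
  cfg1 <- scan_config(w_len = 100, w_olap = 0, sig_test = 1)
  r2 <- make_reads(c("a", "b"), "chr1", "+", c(1010L, 1990L))
  cand2 <- pooled_scan(m, apply_multimap_policy(assign_reads(r2, m),
                                                "normal"), cfg1)
  expect_equal(nrow(cand2), 2)
  expect_equal(sum(cand2$count), 2)
})

test_that("consolidation slides one-base windows to the spike, leftmost tie", {
  m <- simple_models()
  cfg <- scan_config(w_len = 100, w_olap = 50, sig_test = 0.05)
  # spike at transcript position 530 of G1 plus scattered companions
  r <- make_reads(sprintf("s%02d", 1:50), "chr1", "+",
                  c(rep(1530L, 40), seq(1480L, 1578L, length.out = 10)))
  asn <- apply_multimap_policy(assign_reads(r, m), "normal")
  cand <- pooled_scan(m, asn, cfg)
  expect_gt(nrow(cand), 1)  # overlapping significant windows
  win <- consolidate_windows(cand, m, asn, cfg)
  expect_equal(nrow(win), 1)
  # representative window covers the spike
  expect_true(win$tstart <= 530 && win$tend > 530)
  expect_equal(win$end - win$start, 100)
  # exact tie: two isolated one-read positions inside one candidate run;
  # leftmost maximising start wins
  r2 <- make_reads(c("a", "b"), "chr1", "+", c(1200L, 1210L))
  asn2 <- apply_multimap_policy(assign_reads(r2, m), "normal")
  cfg2 <- scan_config(w_len = 50, w_olap = 25, sig_test = 1)
  win2 <- consolidate_windows(pooled_scan(m, asn2, cfg2), m, asn2, cfg2)
  # both reads fit in one 50-base window; max count 2 first reached at
  # the smallest start inside the merged region covering both
  expect_equal(win2$count[1], 2)
  expect_equal(win2$tstart[1], 175L)

  # isolated candidate passes through unchanged
  r3 <- make_reads("solo", "chr1", "+", 1005L)
  asn3 <- apply_multimap_policy(assign_reads(r3, m), "normal")
  cfg3 <- scan_config(w_len = 50, w_olap = 0, sig_test = 1)
  cand3 <- pooled_scan(m, asn3, cfg3)
  win3 <- consolidate_windows(cand3, m, asn3, cfg3)
  expect_equal(win3$tstart, cand3$tstart)
  expect_equal(win3$count, cand3$count)
})

test_that("windows map back to genomic coordinates strand-aware", {
  m <- simple_models()
  cfg <- scan_config(w_len = 50, w_olap = 0, sig_test = 1)
  # G3 is - strand [100000,101000): its 3' end is at genomic 100000
  r <- make_reads(sprintf("m%02d", 1:20), "chr1", "-", rep(100010L, 20))
  asn <- apply_multimap_policy(assign_reads(r, m), "normal")
  win <- consolidate_windows(pooled_scan(m, asn, cfg), m, asn, cfg)
  expect_equal(win$strand, "-")
  expect_true(win$start <= 100010 && win$end > 100010)
})

test_that("per-experiment quantification is additive and covers extensions", {
  m <- simple_models(w_ext = 5000)
  cfg <- scan_config(w_len = 100, w_olap = 0, sig_test = 1, w_ext = 5000)
  # expA reads in annotated G1; expB reads only in the G1 extension
  rA <- make_reads(sprintf("a%02d", 1:15), "chr1", "+", rep(1400L, 15))
  rB <- make_reads(sprintf("b%02d", 1:10), "chr1", "+", rep(2400L, 10))
  aA <- apply_multimap_policy(assign_reads(rA, m), "normal")
  aB <- apply_multimap_policy(assign_reads(rB, m), "normal")
  pooled <- rbind(aA, aB)
  win <- consolidate_windows(pooled_scan(m, pooled, cfg), m, pooled, cfg)
  tab <- quantify(m, win, list(expA = aA, expB = aB))
  g1 <- tab$genes[tab$genes$gene == "G1", ]
  expect_equal(g1$expA, 15)
  expect_equal(g1$expB, 10)  # all reads in the extension still count
  # pooled window counts equal the sum of per-experiment counts
  expect_equal(win$count, tab$windows$expA + tab$windows$expB)
  # an experiment with no surviving reads warns and reports zeros
  expect_warning(tab0 <- quantify(m, win, list(empty = aA[0, ], expA = aA)),
                 "no surviving reads")
  expect_true(all(tab0$genes$empty == 0))
})

test_that("few genes get significant windows under a uniform null", {
  set.seed(99)
  tx <- make_transcripts(lapply(1:150, function(i)
    list(paste0("t", i), paste0("g", i), "chr1", "+",
         (i - 1) * 20000, (i - 1) * 20000 + 2000)))
  m <- build_gene_models(tx, "metatranscript")
  cfg <- scan_config(w_len = 50, w_olap = 0, sig_test = 0.05)
  hits <- 0
  reads <- do.call(rbind, lapply(1:150, function(i) {
    cp <- (i - 1) * 20000 + sample.int(2000, 60, replace = TRUE) - 1L
    make_reads(sprintf("g%dr%02d", i, seq_along(cp)), "chr1", "+", cp)
  }))
  asn <- apply_multimap_policy(assign_reads(reads, m), "normal")
  cand <- pooled_scan(m, asn, cfg)
  frac <- length(unique(cand$gene)) / 150
  # nominal FWER per gene is 0.05; allow generous sampling slack
  expect_lt(frac, 0.15)
})

test_that("the full run is deterministic and writes well-formed tables", {
  spec <- sim_spec(n_genes = 10, seed = 21, reads_per_gene = 80,
                   experiments = c("e1", "e2"))
  d <- tempfile(); sim <- simulate_transcriptome(spec, d)
  rds <- simulate_end_reads(sim, spec, d)
  p1 <- file.path(d, "run1"); p2 <- file.path(d, "run2")
  res1 <- esat_quantify(as.list(rds$sam_paths), sim$table_path,
                        w_len = 100, w_olap = 50, w_ext = 1000,
                        sig_test = 0.05, filt_at = 10,
                        multimap = "ignore", out_prefix = p1)
  res2 <- esat_quantify(as.list(rds$sam_paths), sim$table_path,
                        w_len = 100, w_olap = 50, w_ext = 1000,
                        sig_test = 0.05, filt_at = 10,
                        multimap = "ignore", out_prefix = p2)
  for (suffix in c(".gene.txt", ".window.txt")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
  g <- utils::read.delim(paste0(p1, ".gene.txt"))
  expect_equal(names(g), c("gene", "chrom", "strand", "e1", "e2"))
  expect_equal(nrow(g), 10)
  w <- utils::read.delim(paste0(p1, ".window.txt"))
  expect_true(all(c("gene", "chrom", "start", "end", "strand", "pvalue",
                    "e1", "e2") %in% names(w)))
  expect_true(all(w$pvalue <= 0.05))
  # gene count >= any single window count of that gene
  for (i in seq_len(nrow(w))) {
    expect_gte(g$e1[match(w$gene[i], g$gene)], w$e1[i])
  }
})
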