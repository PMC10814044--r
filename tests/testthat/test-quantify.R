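test_that("reads containing a published probe are counted with grep semantics", {
  probes <- c(v1 = "CATCAATGACAAAAGTTACAAGGAGAACAT")
  read <- paste0("GGGTT", probes[["v1"]], "ACCGT")
  sc <- scan_reads(read, probes, strand_mode = "forward")
  expect_equal(sc$raw[["v1"]], 1L)
  expect_equal(sc$total_reads, 1L)
  # reverse-complemented read: invisible in forward mode, found in both mode
  rc <- revcomp(read)
  expect_equal(scan_reads(rc, probes, strand_mode = "forward")$raw[["v1"]], 0L)
  expect_equal(scan_reads(rc, probes, strand_mode = "both")$raw[["v1"]], 1L)
  # presence, not occurrences: a doubled probe still counts once
  expect_equal(scan_reads(paste0(read, probes[["v1"]]), probes,
                          strand_mode = "forward")$raw[["v1"]], 1L)
  # a single substitution inside the probe window breaks the match
  mut <- read
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "C" else "A"
  expect_equal(scan_reads(mut, probes, strand_mode = "both")$raw[["v1"]], 0L)
  # N never matches
  withN <- read
  substr(withN, 10, 10) <- "N"
  expect_equal(scan_reads(withN, probes, strand_mode = "both")$raw[["v1"]], 0L)
})

test_that("quantification equals the truth manifest exactly on error-free reads", {
  locus <- test_locus()
  probes <- test_probes()
  for (seed in c(3, 17)) {
    sim <- simulate_sample(locus, c(v1 = 8, v2 = 2, v3 = 1, vE5c = 0.5),
                           sim_params(n_reads = 10000L), seed = seed,
                           probes = probes)
    sc <- scan_reads(sim$reads$r1, probes, strand_mode = "both")
    expect_equal(sc$raw, sim$truth$expected_counts + 0L,
                 ignore_attr = FALSE)
  }
  # paired mode: both mates scanned, truth tallied per mate orientation
  simp <- simulate_sample(locus, c(v1 = 5, v3 = 1),
                          sim_params(n_reads = 5000L, paired = TRUE,
                                     fragment_len_mean = 160,
                                     fragment_len_sd = 15),
                          seed = 9, probes = probes)
  scp <- scan_reads(c(simp$reads$r1, simp$reads$r2), probes,
                    strand_mode = "both")
  expect_equal(scp$raw, simp$truth$expected_counts + 0L)
  expect_equal(scp$total_reads, 10000L)
})

test_that("counting is linear under file concatenation", {
  locus <- test_locus()
  probes <- test_probes()
  a <- simulate_sample(locus, c(v1 = 3, v2 = 1), sim_params(n_reads = 3000L),
                       seed = 1, probes = probes)
  b <- simulate_sample(locus, c(v1 = 1, v3 = 2), sim_params(n_reads = 2000L),
                       seed = 2, probes = probes)
  sa <- scan_reads(a$reads$r1, probes)
  sb <- scan_reads(b$reads$r1, probes)
  sab <- scan_reads(c(a$reads$r1, b$reads$r1), probes)
  expect_equal(sab$raw, sa$raw + sb$raw)
  expect_equal(sab$total_reads, sa$total_reads + sb$total_reads)
})

test_that("normalisation and v2 deconvolution follow their contracts", {
  expect_equal(normalize_count(5, 1e6), 5000)
  expect_equal(normalize_count(0, 1e9), 0)
  expect_equal(normalize_count(7, 7e9), 1)
  expect_error(normalize_count(1, 0), "total_reads")
  expect_equal(deconvolve_v2(10, 4), list(v2_raw = 6L, flagged = FALSE))
  expect_equal(deconvolve_v2(3, 5), list(v2_raw = 0L, flagged = TRUE))
  # normalising the raw difference equals differencing normalised values when
  # totals are shared
  total <- 25000
  expect_equal(normalize_count(10 - 4, total),
               normalize_count(10, total) - normalize_count(4, total))
})

test_that("v2 deconvolution recovers a simulated 1:1 v2:v3 mixture within 3 Poisson sd", {
  locus <- test_locus()
  probes <- test_probes()
  sim <- simulate_sample(locus, c(v1 = 5, v2 = 1, v3 = 1),
                         sim_params(n_reads = 50000L), seed = 13,
                         probes = probes)
  sc <- scan_reads(sim$reads$r1, probes, strand_mode = "forward")
  v2 <- deconvolve_v2(sc$raw[["v2v3"]], sc$raw[["v3"]])
  lam <- ugtsplice:::expected_probe_counts(locus, c(v1 = 5, v2 = 1, v3 = 1),
                                           50000L, 100L, probes = probes)
  lam_v2 <- lam[["v2v3"]] - lam[["v3"]]
  expect_lt(abs(v2$v2_raw - lam_v2),
            3 * sqrt(lam[["v2v3"]] + lam[["v3"]]))
})

test_that("FASTQ files, gzipped or plain, quantify identically; empty input errors at normalisation", {
  locus <- test_locus()
  probes <- test_probes()
  d <- withr::local_tempdir()
  sim <- simulate_sample(locus, c(v1 = 2, v3 = 1), sim_params(n_reads = 2000L),
                         seed = 4, out_prefix = file.path(d, "s"),
                         probes = probes)
  simgz <- simulate_sample(locus, c(v1 = 2, v3 = 1), sim_params(n_reads = 2000L),
                           seed = 4, out_prefix = file.path(d, "sgz"),
                           probes = probes, gzip = TRUE)
  q1 <- quantify_sample(sim$files, probes, sample_id = "plain")
  q2 <- quantify_sample(simgz$files, probes, sample_id = "gz")
  expect_equal(q1$raw, q2$raw)
  expect_equal(q1$normalized, q2$normalized)
  expect_equal(q1$raw[["v1"]] + 0L, sim$truth$expected_counts[["v1"]])
  # empty FASTQ: zero counts, rejected when normalising
  empty_fq <- file.path(d, "empty.fastq")
  writeLines(character(0), empty_fq)
  expect_equal(scan_reads(empty_fq, probes)$total_reads, 0L)
  expect_error(quantify_sample(empty_fq, probes), "total_reads")
})

test_that("expression tables validate pairing and reject duplicate ids", {
  mk <- function(id, group, pair, v1 = 100L) {
    ugtsplice:::counts_from_raw(c(v1 = v1, v2v3 = 10L, v3 = 5L), 10000L,
                                id, group, pair)
  }
  samples <- list(mk("n1", "normal", 1), mk("t1", "tumor", 1),
                  mk("n2", "normal", 2), mk("t2", "tumor", 2),
                  mk("n3", "normal", 3), mk("t3", "tumor", 3),
                  mk("orphan", "normal", 4))
  expect_warning(tab <- build_expression_table(samples), "complete")
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("raw_v1", "norm_v1", "raw_v2", "norm_v2") %in% names(tab)))
  expect_error(build_expression_table(list(mk("x", "normal", 1),
                                           mk("x", "tumor", 1))),
               "duplicate")
  expect_equal(nrow(build_expression_table(list())), 0L)
  # a 65-pair cohort gives a 130-row table
  cache <- ugtsplice:::sim_count_cache(test_locus(), test_probes())
  coh <- simulate_cohort(test_locus(), cohort_design(n_pairs = 65L), seed = 6,
                         emit = "counts", probes = test_probes(),
                         cache = cache)
  tab65 <- cohort_truth_table(coh)
  expect_equal(nrow(tab65), 130L)
})
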