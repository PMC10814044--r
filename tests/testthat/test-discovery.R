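test_that("pair merging reconstructs fragments and respects quality at mismatches", {
  set.seed(101)
  frag <- rand_dna(150)
  r1 <- substr(frag, 1, 100)
  r2 <- revcomp(substr(frag, 51, 150))
  m <- merge_pair(r1, r2, min_overlap = 10)
  expect_true(m$merged)
  expect_equal(m$overlap_len, 50L)
  expect_equal(m$mismatches_in_overlap, 0L)
  expect_equal(m$sequence, frag)
  # one low-quality error in r2's overlap: consensus recovers the truth
  r2seq <- substr(frag, 51, 150)
  bad <- 30L  # within the overlap region of r2 (positions 1..50 of r2seq)
  substr(r2seq, bad, bad) <- setdiff(c("A", "C", "G", "T"),
                                     substr(r2seq, bad, bad))[1]
  r2err <- revcomp(r2seq)
  q1 <- paste(rep("I", 100), collapse = "")        # Q40
  q2 <- paste(rep("#", 100), collapse = "")        # Q2
  merr <- merge_pair(r1, r2err, q1, q2, min_overlap = 10,
                     max_mismatch_rate = 0.1)
  expect_true(merr$merged)
  expect_equal(merr$mismatches_in_overlap, 1L)
  expect_equal(merr$sequence, frag)
  # disjoint fragments stay unmerged
  a <- rand_dna(100)
  b <- rand_dna(100)
  expect_false(merge_pair(a, revcomp(b), min_overlap = 10)$merged)
  expect_error(merge_pair(a, revcomp(b), min_overlap = 3), "min_overlap")
})

test_that("vectorised merging agrees with the single-pair reference", {
  set.seed(42)
  frags <- vapply(sample(130:190, 30, replace = TRUE),
                  function(n) rand_dna(n), character(1))
  r1 <- substr(frags, 1, 100)
  r2 <- revcomp(substr(frags, nchar(frags) - 99, nchar(frags)))
  mv <- ugtsplice:::merge_pairs(r1, r2, min_overlap = 10)
  expect_true(all(mv$merged))
  expect_equal(mv$sequence, frags)
  for (i in c(1, 7, 30)) {
    expect_equal(merge_pair(r1[i], r2[i], min_overlap = 10)$sequence, frags[i])
  }
})

test_that("anchored flank extraction follows the 15-nt downstream/upstream rule", {
  locus <- test_locus()
  anchors <- locus_anchors(locus)
  e5a <- exon_seq(locus, "E5a")
  # canonical v1 continuation after the exon-4 anchor
  read <- paste0("ACGT", anchors$E4_end, substr(e5a, 1, 20))
  obs <- find_anchored_flanks(read, anchors, strand_mode = "forward")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$side, "downstream_of_E4")
  expect_equal(obs$flank_seq, "TTACAAGGAGAACAT")
  # insufficient downstream sequence: observation dropped
  short <- paste0(anchors$E4_end, substr(e5a, 1, 10))
  expect_equal(nrow(find_anchored_flanks(short, anchors,
                                         strand_mode = "forward")), 0L)
  # upstream flank before the exon-5a anchor
  e4 <- exon_seq(locus, "E4")
  read2 <- paste0(substr(e4, nchar(e4) - 29, nchar(e4)), e5a)
  obs2 <- find_anchored_flanks(read2, anchors, strand_mode = "forward")
  up <- obs2[obs2$side == "upstream_of_E5a", ]
  expect_equal(up$flank_seq, substr(e4, nchar(e4) - 14, nchar(e4)))
  # reverse-complemented reads are only seen in both-strand mode
  expect_equal(nrow(find_anchored_flanks(revcomp(read), anchors,
                                         strand_mode = "forward")), 0L)
  expect_equal(find_anchored_flanks(revcomp(read), anchors,
                                    strand_mode = "both")$flank_seq,
               "TTACAAGGAGAACAT")
})

test_that("flank aggregation groups exact sequences and orders by support", {
  obs <- data.frame(
    read_id = 1:7,
    anchor_name = c(rep("E4_end", 5), "E5a_start", "E5a_start"),
    side = c(rep("downstream_of_E4", 5), rep("upstream_of_E5a", 2)),
    flank_seq = c("AAA", "AAA", "CCC", "AAA", "CCC", "TTT", "TTT"),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_flanks(obs)
  expect_equal(agg$support, c(3L, 2L, 2L))
  expect_equal(agg$flank_seq, c("AAA", "CCC", "TTT"))
  empty <- aggregate_flanks(obs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("junction classification round-trips every junction spec", {
  locus <- test_locus()
  cand <- ugtsplice:::discovery_candidates(locus)
  # every candidate flank classifies back to its own class and offset
  for (i in seq_len(nrow(cand))) {
    call <- classify_junction(cand$anchor_name[i], cand$expected_flank[i],
                              locus, cand)
    expect_equal(call$class_label, cand$class_label[i])
    expect_equal(call$offset, cand$offset[i])
  }
  # all 13 junction specs are reachable from at least one anchor side
  expect_setequal(intersect(cand$class_label, locus$junctions$name),
                  locus$junctions$name)
  # an arbitrary unique genomic flank is unclassified but located
  fl <- substr(locus$genome, 12001, 12015)
  res <- classify_junction("E4_end", fl, locus, cand)
  expect_equal(res$class_label, "unclassified")
  # a non-genomic flank is unclassified with no location
  res2 <- classify_junction("E4_end", paste(rep("A", 15), collapse = ""),
                            locus, cand)
  expect_equal(res2$class_label, "unclassified")
})

test_that("discovery on error-free reads calls all ten novel classes with exact offsets", {
  locus <- test_locus()
  sim <- test_discovery_sample()
  calls <- discover(list(r1 = sim$reads$r1, r2 = sim$reads$r2), locus,
                    paired = TRUE)
  expect_equal(sum(calls$category == "unclassified"), 0L)
  novel <- calls[calls$category == "novel", ]
  expect_setequal(novel$class_label,
                  c("v3down1", "v3down2", "v2v3up", "v2v3down", "vE5a1",
                    "vE5a2", "vE5a3", "vE2E5a", "vE5c", "vE5d"))
  off <- setNames(novel$offset, novel$class_label)
  expect_equal(off[["vE5a1"]], 8L)
  expect_equal(off[["vE5a2"]], 18L)
  expect_equal(off[["vE5a3"]], 31L)
  expect_equal(off[["vE5c"]], 7054L)
  expect_equal(off[["vE5d"]], 7405L)
  expect_equal(off[["v2v3up"]], -14L)
  expect_equal(off[["v2v3down"]], 4L)
  expect_equal(off[["v3down1"]], 8L)
  expect_equal(off[["v3down2"]], 10L)
  expect_true(all(novel$supporting_reads >= 5L))
})

test_that("a sample expressing only known transcripts yields no novel calls", {
  locus <- test_locus()
  probes <- test_probes()
  sim <- simulate_sample(locus, c(v1 = 3, v2 = 1, v3 = 1),
                         sim_params(n_reads = 8000L, paired = TRUE,
                                    fragment_len_mean = 150,
                                    fragment_len_sd = 15),
                         seed = 19, probes = probes)
  calls <- discover(list(r1 = sim$reads$r1, r2 = sim$reads$r2), locus,
                    paired = TRUE)
  expect_equal(sum(calls$category == "novel"), 0L)
  expect_setequal(calls$class_label[calls$category == "known"],
                  c("v1", "v2v3", "v3"))
})

test_that("discovery tolerates sequencing errors: all classes called, noise has low support", {
  locus <- test_locus()
  probes <- test_probes()
  sim <- simulate_sample(locus, all_class_abundance(),
                         sim_params(n_reads = 25000L, paired = TRUE,
                                    fragment_len_mean = 150,
                                    fragment_len_sd = 15,
                                    error_rate = 0.001),
                         seed = 23, probes = probes)
  calls <- discover(list(r1 = sim$reads$r1, r2 = sim$reads$r2), locus,
                    paired = TRUE, max_mismatch_rate = 0.05)
  novel <- calls[calls$category == "novel", ]
  expect_length(setdiff(c("v3down1", "v3down2", "v2v3up", "v2v3down", "vE5a1",
                          "vE5a2", "vE5a3", "vE2E5a", "vE5c", "vE5d"),
                        novel$class_label), 0L)
  # error-induced flanks are isolated events: far below the class signal
  spurious <- calls[calls$category == "unclassified", ]
  expect_true(nrow(spurious) == 0L ||
                max(spurious$supporting_reads) <
                  0.1 * min(novel$supporting_reads))
})

test_that("calls export to TSV and BED", {
  locus <- test_locus()
  sim <- test_discovery_sample()
  calls <- discover(list(r1 = sim$reads$r1, r2 = sim$reads$r2), locus,
                    paired = TRUE)
  d <- withr::local_tempdir()
  tsv <- write_calls_tsv(calls, file.path(d, "calls.tsv"))
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(calls))
  bed <- write_calls_bed(calls, locus, file.path(d, "calls.bed"))
  bt <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(sort(bt$V4), sort(calls$class_label[calls$category %in%
                                                     c("known", "novel")]))
  expect_true(all(bt$V2 < bt$V3))
})
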