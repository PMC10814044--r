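test_that("sample ratios follow their arithmetic and undefined conventions", {
  r <- sample_ratios(c(v1 = 100, v2 = 10, v3 = 10))
  expect_equal(r[["v2v3_vs_v1"]], 0.2)
  expect_equal(r[["v2_vs_v3"]], 1)
  expect_equal(r[["v2_vs_v1"]] + r[["v3_vs_v1"]], r[["v2v3_vs_v1"]])
  r0 <- sample_ratios(c(v1 = 0, v2 = 10, v3 = 10))
  expect_true(all(is.na(r0[c("v2_vs_v1", "v3_vs_v1", "v2v3_vs_v1")])))
  expect_false(is.na(r0[["v2_vs_v3"]]))
  r3 <- sample_ratios(c(v1 = 5, v2 = 2, v3 = 0))
  expect_true(is.na(r3[["v2_vs_v3"]]))
})

test_that("cohort summary computes fold variability over expressed samples only", {
  mk <- function(id, v1raw, total = 1e6) {
    ugtsplice:::counts_from_raw(c(v1 = v1raw, v2v3 = 4L, v3 = 2L),
                                total, id, "normal", NA)
  }
  tab <- build_expression_table(list(mk("a", 10L), mk("b", 1500L), mk("c", 0L)),
                                require_pairs = FALSE)
  cs <- cohort_summary(tab, types = "v1")
  row <- cs$expression[cs$expression$type == "v1", ]
  expect_equal(row$n_expressed, 2L)
  expect_equal(row$fold_variability, 150)
  # all-identical samples collapse the range
  tab2 <- build_expression_table(list(mk("a", 7L), mk("b", 7L)),
                                 require_pairs = FALSE)
  row2 <- cohort_summary(tab2, types = "v1")$expression
  expect_equal(row2$fold_variability, 1)
  expect_equal(row2$min, row2$max)
  # fold variability is invariant to global rescaling of normalised values
  tab3 <- build_expression_table(list(mk("a", 10L, 1e6), mk("b", 1500L, 1e6)),
                                 require_pairs = FALSE)
  tab4 <- build_expression_table(list(mk("a", 10L, 1e8), mk("b", 1500L, 1e8)),
                                 require_pairs = FALSE)
  expect_equal(cohort_summary(tab3, "v1")$expression$fold_variability,
               cohort_summary(tab4, "v1")$expression$fold_variability)
})

test_that("cohort medians recover the design medians within 10% at 100 pairs", {
  locus <- test_locus()
  probes <- test_probes()
  cache <- ugtsplice:::sim_count_cache(locus, probes)
  types <- data.frame(type = c("v1", "v2", "v3"), median = c(100, 5, 5),
                      sdlog = c(0.6, 0.9, 0.9), tumor_fold = 1,
                      sdlog_within = 0, zero_p = 0)
  coh <- simulate_cohort(locus, cohort_design(n_pairs = 100L, types = types,
                                              n_reads = 200000L),
                         seed = 77, emit = "counts", probes = probes,
                         cache = cache)
  tab <- cohort_truth_table(coh)
  # oracle: expected normalised v1 count at the design median abundance
  lam <- ugtsplice:::expected_probe_counts(locus, c(v1 = 100, v2 = 5, v3 = 5),
                                           200000L, 100L, probes = probes)
  expected_norm_v1 <- lam[["v1"]] / 200000 * 1e9
  med <- median(tab$norm_v1[tab$group == "normal"])
  expect_lt(abs(med - expected_norm_v1) / expected_norm_v1, 0.10)
})

test_that("the signed-rank test matches the exhaustive sign-flip oracle for n <= 10", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    normal <- round(rlnorm(n, 3, 1), if (rep %% 2) 2 else 0)  # force ties sometimes
    tumor <- round(normal * rlnorm(n, 0, 0.5), if (rep %% 2) 2 else 0)
    res <- wilcoxon_signed_rank(normal, tumor)
    expect_equal(res$p_value, oracle_signed_rank_p(normal, tumor),
                 tolerance = 1e-12)
  }
  # identical vectors: p = 1, no direction
  same <- wilcoxon_signed_rank(1:5, 1:5)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  expect_equal(same$n_effective, 0L)
})

test_that("the exact signed-rank p equals wilcox.test on tie-free data", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    a <- rnorm(n)
    b <- a + rnorm(n)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                               exact = TRUE, correct = FALSE))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("the large-sample signed-rank approximation is close to the exact tail", {
  set.seed(3)
  a <- rnorm(13)
  b <- a + rnorm(13, 0.8, 0.6)
  ours <- wilcoxon_signed_rank(a, b)
  expect_equal(ours$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("spearman_cor equals rank-then-Pearson with ties and exact/approximate p-values", {
  expect_equal(spearman_cor(1:8, 1:8)$rho, 1)
  expect_equal(spearman_cor(1:8, 8:1)$rho, -1)
  x <- c(3, 1, 4, 1, 5, 9, 2)   # ties in x
  y <- c(2, 7, 1, 8, 2, 8, 1)   # ties in y
  res <- spearman_cor(x, y)
  expect_equal(res$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
  expect_equal(res$rho, suppressWarnings(
    unname(stats::cor.test(x, y, method = "spearman")$estimate)),
    tolerance = 1e-12)
  # tie-free small n: exact permutation p equals cor.test's exact p
  set.seed(5)
  x2 <- rnorm(7); y2 <- rnorm(7)
  res2 <- spearman_cor(x2, y2)
  ref2 <- stats::cor.test(x2, y2, method = "spearman", exact = TRUE)
  expect_equal(res2$p_value, unname(ref2$p.value), tolerance = 1e-10)
  # large n: t approximation
  set.seed(6)
  x3 <- rnorm(40); y3 <- x3 + rnorm(40)
  res3 <- spearman_cor(x3, y3)
  ref3 <- stats::cor.test(x3, y3, method = "spearman", exact = FALSE)
  expect_equal(res3$p_value, unname(ref3$p.value), tolerance = 1e-8)
  # constant input: undefined rho
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
})

test_that("the deregulation report detects designed fold-changes and survives one pair", {
  locus <- test_locus()
  probes <- test_probes()
  cache <- ugtsplice:::sim_count_cache(locus, probes)
  types <- data.frame(type = c("v1", "v2", "v3"), median = c(100, 5, 5),
                      sdlog = c(0.6, 0.9, 0.9),
                      tumor_fold = c(0.1, 2, 1),
                      sdlog_within = 0.3, zero_p = 0)
  coh <- simulate_cohort(locus, cohort_design(n_pairs = 60L, types = types),
                         seed = 41, emit = "counts", probes = probes,
                         cache = cache)
  rep60 <- deregulation_report(cohort_truth_table(coh))
  dir <- setNames(rep60$tests$direction, rep60$tests$metric)
  expect_equal(dir[["v1"]], "down")
  expect_equal(dir[["v2"]], "up")
  # single pair: tests report as underpowered, no crash
  coh1 <- simulate_cohort(locus, cohort_design(n_pairs = 1L, types = types),
                          seed = 42, emit = "counts", probes = probes,
                          cache = cache)
  rep1 <- deregulation_report(cohort_truth_table(coh1))
  expect_true(all(rep1$tests$direction == "NA (underpowered)" |
                    rep1$tests$n_pairs <= 1L))
})
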