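# Cohort-level ratios, summaries and paired deregulation statistics.
#
# Conventions follow the source workflow: a transcript type is "expressed" in
# a sample when its raw junction count is >= 1; fold variability is max/min of
# normalised values over expressed samples; ratios with zero denominators are
# undefined (NA) and excluded from medians; paired deregulation uses the
# Wilcoxon matched-pairs signed-rank test and correlations use Spearman rank
# correlation; p-values are reported raw (alpha = 0.05, no multiplicity
# adjustment).

RATIO_NAMES <- c("v2_vs_v1", "v3_vs_v1", "v2v3_vs_v1", "v2_vs_v3")

#' Per-sample transcript-ratio set
#'
#' Ratios of normalised values: `v2_vs_v1`, `v3_vs_v1`, `v2v3_vs_v1`
#' (`(v2+v3)/v1`), `v2_vs_v3`.  A zero denominator yields `NA` (undefined),
#' never 0 or infinity.
#'
#' @param norm Named numeric vector with at least `v1`, `v2`, `v3` normalised
#'   values (e.g. the `normalized` element of a `sample_counts`).
#' @return Named numeric vector of the four ratios.
#' @export
sample_ratios <- function(norm) {
  rat <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_
  v1 <- norm[["v1"]]; v2 <- norm[["v2"]]; v3 <- norm[["v3"]]
  c(v2_vs_v1 = rat(v2, v1), v3_vs_v1 = rat(v3, v1),
    v2v3_vs_v1 = rat(v2 + v3, v1), v2_vs_v3 = rat(v2, v3))
}

# Ratio matrix for every sample of an expression table.
table_ratios <- function(tab) {
  out <- t(vapply(seq_len(nrow(tab)), function(i) {
    sample_ratios(c(v1 = tab$norm_v1[i], v2 = tab$norm_v2[i],
                    v3 = tab$norm_v3[i]))
  }, numeric(4)))
  colnames(out) <- RATIO_NAMES
  out
}

#' Cohort summary: expression, variability and ratio statistics
#'
#' Per transcript type and group: number of expressed samples (raw count >=
#' 1), median and range of normalised values over expressed samples, and fold
#' variability (max/min over expressed samples).  Per ratio and group: median
#' and range over samples where the ratio is defined.
#'
#' @param tab An `expression_table`.
#' @param types Transcript types to summarise (default `v1`, `v2`, `v3`).
#' @return List of class `cohort_summary` with data frames `expression` and
#'   `ratios`.
#' @export
cohort_summary <- function(tab, types = c("v1", "v2", "v3")) {
  stopifnot(nrow(tab) >= 1L)
  groups <- unique(tab$group)
  expr_rows <- list()
  for (ty in types) {
    raw <- tab[[paste0("raw_", ty)]]
    norm <- tab[[paste0("norm_", ty)]]
    for (g in groups) {
      in_g <- tab$group == g
      expressed <- in_g & raw >= 1L
      vals <- norm[expressed]
      expr_rows[[paste(ty, g)]] <- data.frame(
        type = ty, group = g, n = sum(in_g), n_expressed = sum(expressed),
        median = if (length(vals)) stats::median(vals) else NA_real_,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        fold_variability = if (length(vals) && min(vals) > 0)
          max(vals) / min(vals) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  ratios <- table_ratios(tab)
  ratio_rows <- list()
  for (rn in colnames(ratios)) {
    for (g in groups) {
      vals <- ratios[tab$group == g, rn]
      vals <- vals[!is.na(vals)]
      ratio_rows[[paste(rn, g)]] <- data.frame(
        ratio = rn, group = g, n_defined = length(vals),
        median = if (length(vals)) stats::median(vals) else NA_real_,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(expression = do.call(rbind, c(expr_rows, list(make.row.names = FALSE))),
                 ratios = do.call(rbind, c(ratio_rows, list(make.row.names = FALSE)))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Expression summary:\n")
  print.data.frame(x$expression, row.names = FALSE, digits = 4)
  cat("Ratio summary:\n")
  print.data.frame(x$ratios, row.names = FALSE, digits = 4)
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W (sum of positive
# ranks) for a given rank vector, via shift convolution over doubled ranks
# (doubling keeps average ranks integral).
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s+1] = number of sign assignments with 2W = s
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  probs <- f / 2^length(r2)
  support <- 0:total
  mu <- total / 2
  dev <- abs(support - mu)
  obs_dev <- abs(2 * w_obs - mu)
  sum(probs[dev >= obs_dev - 1e-9])
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; absolute differences receive average ranks
#' under ties.  For `n_effective <= 12` the two-sided p-value is exact:
#' `Pr(|W - mu| >= |w - mu|)` under the sign-flip null (the null distribution
#' of W is symmetric about `mu = sum(ranks)/2` even with ties).  Above 12 a
#' normal approximation with continuity correction and the general tie-robust
#' variance `sum(ranks^2)/4` is used.  Direction is the sign of the median
#' difference when p < 0.05.
#'
#' @param normal,tumor Paired value vectors (`tumor - normal` differences are
#'   tested).
#' @return A list of class `paired_test`: `statistic` (W), `p_value`,
#'   `n_effective`, `direction` (`"up"`, `"down"`, `"none"`), `method`.
#' @export
wilcoxon_signed_rank <- function(normal, tumor) {
  if (length(normal) != length(tumor)) stopf("paired vectors must have equal length")
  keep <- !is.na(normal) & !is.na(tumor)
  d <- tumor[keep] - normal[keep]
  d <- d[d != 0]
  n <- length(d)
  if (length(normal[keep]) < 1L) stopf("at least one pair is required")
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n_effective = 0L,
                          direction = "none", method = "exact"),
                     class = "paired_test"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= 12L) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu)
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal-approximation"
  }
  direction <- if (p < 0.05) {
    md <- stats::median(d)
    if (md > 0) "up" else if (md < 0) "down" else "none"
  } else {
    "none"
  }
  structure(list(statistic = w, p_value = p, n_effective = n,
                 direction = direction, method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("signed-rank W = %g, n = %d, p = %.4g (%s), direction: %s\n",
              x$statistic, x$n_effective, x$p_value, x$method, x$direction))
  invisible(x)
}

# All permutations of 1..n as an (n! x n) integer matrix, built by insertion.
permutations <- function(n) {
  m <- matrix(1L, 1L, 1L)
  if (n == 1L) return(m)
  for (k in 2:n) {
    nr <- nrow(m)
    out <- matrix(0L, nr * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * nr + seq_len(nr)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- m[, seq_len(pos - 1L), drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1L):k] <- m[, pos:(k - 1L), drop = FALSE]
    }
    m <- out
  }
  m
}

#' Spearman rank correlation
#'
#' `rho` is the product-moment correlation of average ranks.  For `n > 10`
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`; for `n <= 10` it is computed by exact
#' enumeration of all permutations of one rank vector (valid under ties).
#' Constant input yields an undefined `rho` (NA).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list of class `correlation_test`: `rho`, `p_value`, `n`,
#'   `method`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "undefined (constant input)"),
                     class = "correlation_test"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    perm <- permutations(n)
    ry_perm <- matrix(ry[perm], nrow(perm), n)
    rxc <- rx - mean(rx)
    denom_x <- sqrt(sum(rxc^2))
    ryc <- ry_perm - mean(ry)
    sds <- sqrt(rowSums(ryc^2))
    rho_all <- as.vector(ryc %*% rxc) / (denom_x * sds)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, n = %d, p = %.4g (%s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' Paired deregulation report
#'
#' For each transcript type (`v1`, `v2`, `v3`) and each ratio: the paired
#' signed-rank test (tumour vs normal), group medians and the call direction;
#' plus all pairwise Spearman correlations among the types within the normal
#' and within the tumour group.  Raw p-values, no multiplicity adjustment.
#'
#' @param tab A paired `expression_table`.
#' @param types Transcript types to test.
#' @return List of class `deregulation_report` with data frames `tests` and
#'   `correlations`.
#' @export
deregulation_report <- function(tab, types = c("v1", "v2", "v3")) {
  nrm <- tab[tab$group == "normal", ]
  tum <- tab[tab$group == "tumor", ]
  if (nrow(nrm) == 0L || nrow(tum) == 0L)
    stopf("a paired table with both groups is required")
  tum <- tum[match(nrm$pair_id, tum$pair_id), ]
  ratios_n <- table_ratios(nrm)
  ratios_t <- table_ratios(tum)

  metrics <- c(types, RATIO_NAMES)
  test_rows <- lapply(metrics, function(m) {
    if (m %in% types) {
      a <- nrm[[paste0("norm_", m)]]
      b <- tum[[paste0("norm_", m)]]
    } else {
      a <- ratios_n[, m]
      b <- ratios_t[, m]
    }
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 2L) {
      return(data.frame(metric = m, n_pairs = sum(keep),
                        median_normal = stats::median(a[keep]),
                        median_tumor = stats::median(b[keep]),
                        statistic = NA_real_, p_value = NA_real_,
                        direction = "NA (underpowered)",
                        stringsAsFactors = FALSE))
    }
    tst <- wilcoxon_signed_rank(a[keep], b[keep])
    data.frame(metric = m, n_pairs = sum(keep),
               median_normal = stats::median(a[keep]),
               median_tumor = stats::median(b[keep]),
               statistic = tst$statistic, p_value = tst$p_value,
               direction = tst$direction, stringsAsFactors = FALSE)
  })

  pairs <- utils::combn(types, 2L, simplify = FALSE)
  cor_rows <- list()
  for (g in c("normal", "tumor")) {
    gt <- if (g == "normal") nrm else tum
    for (pr in pairs) {
      a <- gt[[paste0("norm_", pr[1L])]]
      b <- gt[[paste0("norm_", pr[2L])]]
      res <- tryCatch(spearman_cor(a, b), error = function(e) NULL)
      cor_rows[[paste(g, pr[1L], pr[2L])]] <- data.frame(
        group = g, a = pr[1L], b = pr[2L],
        rho = if (is.null(res)) NA_real_ else res$rho,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        n = if (is.null(res)) sum(!is.na(a) & !is.na(b)) else res$n,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(tests = do.call(rbind, c(test_rows, list(make.row.names = FALSE))),
                 correlations = do.call(rbind, c(cor_rows, list(make.row.names = FALSE)))),
            class = "deregulation_report")
}

#' @export
print.deregulation_report <- function(x, ...) {
  cat("Paired deregulation tests (tumour vs normal):\n")
  print.data.frame(x$tests, row.names = FALSE, digits = 4)
  cat("Spearman correlations:\n")
  print.data.frame(x$correlations, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a deregulation report as TSV (tests) and JSON (full report)
#' @param report A `deregulation_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$tests, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(tests = report$tests,
                              correlations = report$correlations),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
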