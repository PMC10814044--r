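# Exact-match junction-probe quantification.
#
# A probe counts a read at most once (presence, not occurrences), mirroring
# line-wise exact grep over dumped FASTQ.  Counts are normalised to reads per
# 1e9 total reads, and v2 is derived by deducting the v3-specific junction
# count from the count of the junction shared by v2 and v3.

#' Scan reads for exact probe matches
#'
#' @param reads FASTQ path(s) (optionally gzipped; mates are counted as
#'   independent reads) or a character vector of read sequences.
#' @param probes A `ugt_probe_set` or named character vector of probe
#'   sequences.
#' @param strand_mode `"forward"` matches probes as given; `"both"` also
#'   matches the reverse complement of each probe.
#' @return List with `raw` (named integer counts, one per probe) and
#'   `total_reads`.
#' @export
scan_reads <- function(reads, probes, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  probes <- probe_sequences(probes)
  if (length(probes) == 0L) stopf("probe set is empty")
  if (is.character(reads) && length(reads) > 0L &&
      all(file.exists(reads))) {
    reads <- unlist(lapply(reads, function(f) as.character(read_fastq(f))))
    if (is.null(reads)) reads <- character(0)
  }
  reads <- toupper(reads)
  raw <- vapply(probes, function(p) {
    hit <- grepl(p, reads, fixed = TRUE)
    if (strand_mode == "both") hit <- hit | grepl(revcomp(p), reads, fixed = TRUE)
    sum(hit)
  }, integer(1))
  list(raw = raw, total_reads = length(reads))
}

#' Normalise a raw count to reads per 1e9 total reads
#' @param raw Raw count(s).
#' @param total_reads Total reads scanned (> 0).
#' @return `raw / total_reads * 1e9`.
#' @export
normalize_count <- function(raw, total_reads) {
  if (any(total_reads <= 0)) stopf("total_reads must be > 0 for normalisation")
  raw / total_reads * 1e9
}

#' Derive the v2 count from shared and v3-specific junction counts
#'
#' `v2 = max(v2v3 - v3, 0)`; a negative difference (sampling-noise inversion)
#' is clamped to zero and flagged for QC.
#'
#' @param v2v3_raw Count of the junction shared by v2 and v3.
#' @param v3_raw Count of the v3-specific junction.
#' @return List with `v2_raw` and `flagged`.
#' @export
deconvolve_v2 <- function(v2v3_raw, v3_raw) {
  d <- v2v3_raw - v3_raw
  list(v2_raw = max(d, 0L), flagged = d < 0L)
}

#' Quantify one sample
#'
#' Scan, deconvolve v2, normalise.  Derived v2 is normalised from its raw
#' difference, not as a difference of normalised values (equivalent when the
#' totals are shared).
#'
#' @inheritParams scan_reads
#' @param sample_id,group,pair_id Sample metadata (`group` one of `"normal"`,
#'   `"tumor"`, `"none"`).
#' @return A list of class `sample_counts`: `sample_id`, `group`, `pair_id`,
#'   `total_reads`, `raw` (per probe, plus derived `v2`), `normalized`,
#'   `v2_flagged`.
#' @export
quantify_sample <- function(reads, probes, sample_id = "sample",
                            group = c("none", "normal", "tumor"),
                            pair_id = NA, strand_mode = c("both", "forward")) {
  group <- match.arg(group)
  sc <- scan_reads(reads, probes, strand_mode = match.arg(strand_mode))
  raw <- sc$raw
  v2 <- if (all(c("v2v3", "v3") %in% names(raw))) {
    deconvolve_v2(raw[["v2v3"]], raw[["v3"]])
  } else {
    list(v2_raw = NA_integer_, flagged = FALSE)
  }
  raw_all <- c(raw, v2 = v2$v2_raw)
  structure(list(
    sample_id = sample_id, group = group, pair_id = pair_id,
    total_reads = sc$total_reads,
    raw = raw_all,
    normalized = normalize_count(raw_all, sc$total_reads),
    v2_flagged = v2$flagged
  ), class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("sample %s (%s, pair %s): %d reads\n", x$sample_id, x$group,
              as.character(x$pair_id), x$total_reads))
  print(data.frame(probe = names(x$raw), raw = unname(x$raw),
                   per_1e9 = unname(round(x$normalized, 2))), row.names = FALSE)
  invisible(x)
}

# Build a sample_counts object directly from known raw counts (used for
# truth-manifest counts and count-level cohort simulations).
counts_from_raw <- function(raw, total_reads, sample_id, group = "none",
                            pair_id = NA) {
  v2 <- if (all(c("v2v3", "v3") %in% names(raw))) {
    deconvolve_v2(raw[["v2v3"]], raw[["v3"]])
  } else {
    list(v2_raw = NA_integer_, flagged = FALSE)
  }
  raw_all <- c(raw, v2 = v2$v2_raw)
  structure(list(sample_id = sample_id, group = group, pair_id = pair_id,
                 total_reads = total_reads, raw = raw_all,
                 normalized = normalize_count(raw_all, total_reads),
                 v2_flagged = v2$flagged),
            class = "sample_counts")
}

#' Assemble an expression table from per-sample counts
#'
#' Rows are samples; columns are raw and normalised values per transcript
#' type.  Pairing is validated: a complete pair is one normal and one tumour
#' sample sharing a `pair_id`; samples in incomplete pairs are excluded with a
#' warning (unpaired analyses can pass `require_pairs = FALSE`).
#'
#' @param samples List of `sample_counts`.
#' @param require_pairs Drop samples without a complete pair?
#' @return A data frame of class `expression_table` with columns `sample_id`,
#'   `group`, `pair_id`, `total_reads`, then `raw_*` and `norm_*` per type.
#' @export
build_expression_table <- function(samples, require_pairs = TRUE) {
  if (length(samples) == 0L) {
    out <- data.frame(sample_id = character(0), group = character(0),
                      pair_id = integer(0), total_reads = integer(0))
    class(out) <- c("expression_table", "data.frame")
    return(out)
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stopf("duplicate sample id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  probe_names <- names(samples[[1L]]$raw)
  rows <- lapply(samples, function(s) {
    if (!identical(names(s$raw), probe_names))
      stopf("sample %s has a different probe set", s$sample_id)
    df <- data.frame(sample_id = s$sample_id, group = s$group,
                     pair_id = s$pair_id, total_reads = s$total_reads,
                     stringsAsFactors = FALSE)
    for (p in probe_names) {
      df[[paste0("raw_", p)]] <- unname(s$raw[[p]])
      df[[paste0("norm_", p)]] <- unname(s$normalized[[p]])
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (require_pairs) {
    paired <- out[!is.na(out$pair_id) & out$group %in% c("normal", "tumor"), ]
    n_norm <- tapply(paired$group == "normal", as.character(paired$pair_id), sum)
    n_tum <- tapply(paired$group == "tumor", as.character(paired$pair_id), sum)
    complete <- names(n_norm)[n_norm == 1L & n_tum == 1L]
    keep <- !is.na(out$pair_id) & as.character(out$pair_id) %in% complete &
      out$group %in% c("normal", "tumor")
    if (any(!keep)) {
      warning(sprintf("excluding %d sample(s) without a complete normal/tumor pair",
                      sum(!keep)), call. = FALSE)
      out <- out[keep, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "types") <- probe_names
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Expression table from a simulated cohort's truth counts
#'
#' Turns a `sim_cohort` truth manifest into an [build_expression_table()]
#' result without rescanning reads.
#'
#' @param cohort A `sim_cohort`.
#' @return An `expression_table`.
#' @export
cohort_truth_table <- function(cohort) {
  samples <- lapply(cohort$samples, function(s) {
    counts_from_raw(s$expected_counts, s$n_reads, s$sample_id, s$group,
                    s$pair_id)
  })
  build_expression_table(samples)
}

#' Write an expression table as TSV
#' @param table An `expression_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
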