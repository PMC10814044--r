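# Seeded RNA-seq read simulation with ground truth.
#
# Reads are drawn from transcript sequences with probability proportional to
# molar abundance x transcript length (plus an optional background decoy), with
# uniform start positions, optional paired-end fragments, and independent
# per-base substitution errors.  The truth manifest records, per read, its
# transcript of origin and whether it covers each junction-probe window
# error-free — the exact-match semantics the quantifier uses — so quantification
# on error-free reads must reproduce the truth counts exactly.

#' Simulation parameters
#'
#' @param read_len Read length in nt.
#' @param paired Emit paired-end reads (mate 2 reverse-complemented)?
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution
#'   (normal, truncated to `[read_len, transcript length]`); paired mode only.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param n_reads Number of reads (fragments in paired mode; each mate is
#'   counted as an independent read by the quantifier).
#' @param background_fraction Proportion of reads drawn from the locus decoy
#'   sequence (screened to contain no probe or anchor).
#' @param strand_mode_truth Orientation assumed when tallying truth probe
#'   counts: `"both"` counts any covering mate, `"forward"` only mates emitted
#'   in probe orientation, `"reverse"` only reverse-complemented mates.
#' @param qual_char Constant Phred+33 quality character (default "?", Q30).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(read_len = 100L, paired = FALSE,
                       fragment_len_mean = 180, fragment_len_sd = 20,
                       error_rate = 0, n_reads = 10000L,
                       background_fraction = 0,
                       strand_mode_truth = c("both", "forward", "reverse"),
                       qual_char = "?") {
  strand_mode_truth <- match.arg(strand_mode_truth)
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  if (background_fraction < 0 || background_fraction >= 1)
    stopf("background_fraction must be in [0, 1)")
  if (n_reads < 0) stopf("n_reads must be >= 0")
  structure(list(read_len = as.integer(read_len), paired = isTRUE(paired),
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 background_fraction = background_fraction,
                 strand_mode_truth = strand_mode_truth,
                 qual_char = qual_char),
            class = "sim_params")
}

# Locate each probe's window in each transcript sequence.
# Returns a data.frame: transcript index, probe name, window start/end.
probe_windows <- function(seqs, probes) {
  probes <- probe_sequences(probes)
  out <- list()
  for (p in names(probes)) {
    hits <- lapply(seq_along(seqs), function(i) {
      m <- Biostrings::matchPattern(probes[[p]], Biostrings::DNAString(seqs[[i]]))
      if (length(m) == 0L) return(NULL)
      data.frame(tx = i, probe = p, start = BiocGenerics::start(m),
                 end = BiocGenerics::end(m), stringsAsFactors = FALSE)
    })
    out <- c(out, hits)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(tx = integer(0), probe = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

# Apply substitution errors in place; returns list(reads, err_pos) where
# err_pos is a list (per read) of error positions within the read.
apply_errors <- function(reads, error_rate, read_len) {
  n <- length(reads)
  err_pos <- vector("list", n)
  if (error_rate <= 0 || n == 0L) return(list(reads = reads, err_pos = err_pos))
  k <- stats::rbinom(n, read_len, error_rate)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sort(sample.int(read_len, k[i]))
    s <- strsplit(reads[i], "")[[1L]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    reads[i] <- paste(s, collapse = "")
    err_pos[[i]] <- pos
  }
  list(reads = reads, err_pos = err_pos)
}

#' Simulate one RNA-seq sample with ground truth
#'
#' @param locus A `ugt_locus`.
#' @param abundance Named numeric vector of relative molar abundances over
#'   transcript type labels (`v1`, `v2`, `v3` and/or the ten novel class
#'   names).  A type's abundance is split equally across its transcripts.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param out_prefix Optional file prefix; when given, FASTQ files are written
#'   (`<prefix>.fastq` or `<prefix>_1.fastq` / `<prefix>_2.fastq`; add `.gz`
#'   via `gzip = TRUE`).
#' @param probes Probe set used for truth expected counts (default
#'   [default_probe_set()]).
#' @param gzip Compress FASTQ output?
#' @param sample_id Sample identifier recorded in the truth entry.
#' @return A list of class `sim_sample`: `sample_id`, `files`, `reads` (ids,
#'   sequences kept in memory), `truth` (abundance, `n_reads`,
#'   `expected_counts` per probe under `strand_mode_truth`, `total_reads`
#'   scanned) and `provenance` (per-read transcript of origin).
#' @export
simulate_sample <- function(locus, abundance, params = sim_params(),
                            seed = 1L, out_prefix = NULL,
                            probes = default_probe_set(locus),
                            gzip = FALSE, sample_id = "sample") {
  stopifnot(inherits(params, "sim_params"))
  types <- names(abundance)
  if (params$n_reads > 0L && all(abundance <= 0) &&
      params$background_fraction <= 0) {
    stopf("n_reads > 0 with all-zero abundances")
  }
  if (any(abundance < 0)) stopf("abundances must be >= 0")

  tx <- enumerate_all_transcripts(locus)
  tx_types <- vapply(tx, function(t) sub("^novel:", "", t$type_label), character(1))
  unknown <- setdiff(types, unique(tx_types))
  if (length(unknown) > 0L)
    stopf("unknown transcript types in abundance vector: %s",
          paste(unknown, collapse = ", "))

  # per-transcript molar abundance
  mol <- vapply(seq_along(tx), function(i) {
    a <- abundance[match(tx_types[i], types)]
    if (is.na(a)) 0 else a / sum(tx_types == tx_types[i])
  }, numeric(1))
  seqs <- vapply(tx, function(t) transcript_sequence(locus, t), character(1))
  lens <- nchar(seqs)
  w <- mol * lens
  src_names <- vapply(tx, `[[`, character(1), "transcript_id")

  # append decoy as background source
  seqs <- c(seqs, decoy = locus$decoy)
  lens <- c(lens, nchar(locus$decoy))
  src_names <- c(src_names, "background")
  if (sum(w) > 0) {
    w <- w / sum(w) * (1 - params$background_fraction)
    w <- c(w, params$background_fraction)
  } else {
    w <- c(w * 0, 1)
  }

  pw <- probe_windows(seqs[-length(seqs)], probes)
  probe_names <- probe_sequences(probes)
  probe_names <- names(probe_names)

  res <- with_seed(seed, {
    n <- params$n_reads
    rl <- params$read_len
    if (n == 0L) {
      list(ids = character(0), r1 = character(0), r2 = character(0),
           src = integer(0), start = integer(0), frag = integer(0),
           err1 = list(), err2 = list())
    } else {
      src <- sample.int(length(seqs), n, replace = TRUE, prob = w)
      Ls <- lens[src]
      if (any(Ls < rl)) stopf("source sequence shorter than read length")
      if (params$paired) {
        frag <- as.integer(round(stats::rnorm(n, params$fragment_len_mean,
                                              params$fragment_len_sd)))
        frag <- pmax(rl, pmin(frag, Ls))
      } else {
        frag <- rep(rl, n)
      }
      start <- 1L + as.integer(floor(stats::runif(n) * (Ls - frag + 1)))
      r1 <- unname(substr(seqs[src], start, start + rl - 1L))
      e1 <- apply_errors(r1, params$error_rate, rl)
      if (params$paired) {
        m2 <- unname(substr(seqs[src], start + frag - rl, start + frag - 1L))
        r2 <- revcomp(m2)
        e2 <- apply_errors(r2, params$error_rate, rl)
      } else {
        e2 <- list(reads = character(0), err_pos = list())
      }
      list(ids = sprintf("%s.read%06d", sample_id, seq_len(n)),
           r1 = e1$reads, r2 = e2$reads, src = src, start = start, frag = frag,
           err1 = e1$err_pos, err2 = e2$err_pos)
    }
  })

  # ---- truth expected probe counts ----------------------------------------
  rl <- params$read_len
  expected <- stats::setNames(integer(length(probe_names)), probe_names)
  count_mate <- function(mate) {
    # mate 1 covers [start, start+rl-1]; mate 2 covers the fragment 3' end.
    if (mate == 1L) {
      ivs <- cbind(res$start, res$start + rl - 1L)
      errs <- res$err1
      # mate-1 error positions are already transcript-relative offsets
      err_tx <- lapply(seq_along(res$src), function(i) {
        if (is.null(errs[[i]])) NULL else res$start[i] + errs[[i]] - 1L
      })
    } else {
      s2 <- res$start + res$frag - rl
      ivs <- cbind(s2, res$start + res$frag - 1L)
      errs <- res$err2
      # mate 2 is reverse-complemented: read position p maps to transcript
      # coordinate (fragment end) - p + 1
      err_tx <- lapply(seq_along(res$src), function(i) {
        if (is.null(errs[[i]])) NULL else (res$start[i] + res$frag[i] - 1L) - errs[[i]] + 1L
      })
    }
    out <- stats::setNames(integer(length(probe_names)), probe_names)
    if (nrow(pw) == 0L || length(res$src) == 0L) return(out)
    has_err <- !vapply(err_tx, is.null, logical(1))
    for (k in seq_len(nrow(pw))) {
      sel <- which(res$src == pw$tx[k] & ivs[, 1L] <= pw$start[k] &
                     ivs[, 2L] >= pw$end[k])
      if (length(sel) > 0L && any(has_err[sel])) {
        bad <- vapply(sel, function(i) {
          ep <- err_tx[[i]]
          !is.null(ep) && any(ep >= pw$start[k] & ep <= pw$end[k])
        }, logical(1))
        sel <- sel[!bad]
      }
      out[pw$probe[k]] <- out[pw$probe[k]] + length(sel)
    }
    out
  }
  if (params$n_reads > 0L) {
    if (params$strand_mode_truth %in% c("both", "forward")) {
      expected <- expected + count_mate(1L)
    }
    if (params$paired && params$strand_mode_truth %in% c("both", "reverse")) {
      expected <- expected + count_mate(2L)
    }
  }

  files <- character(0)
  if (!is.null(out_prefix)) {
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    if (params$paired) {
      f1 <- paste0(out_prefix, "_1", ext)
      f2 <- paste0(out_prefix, "_2", ext)
      write_fastq(res$r1, paste0(res$ids, "/1"), f1, params$qual_char)
      write_fastq(res$r2, paste0(res$ids, "/2"), f2, params$qual_char)
      files <- c(f1, f2)
    } else {
      f <- paste0(out_prefix, ext)
      write_fastq(res$r1, res$ids, f, params$qual_char)
      files <- f
    }
  }

  total_reads <- length(res$r1) + length(res$r2)
  structure(list(
    sample_id = sample_id,
    files = files,
    reads = list(ids = res$ids, r1 = res$r1,
                 r2 = if (params$paired) res$r2 else NULL),
    truth = list(abundance = abundance, n_reads = params$n_reads,
                 total_reads = total_reads,
                 expected_counts = expected,
                 strand_mode = params$strand_mode_truth),
    provenance = data.frame(read_id = res$ids,
                            source = src_names[res$src],
                            start = res$start, fragment_len = res$frag,
                            stringsAsFactors = FALSE),
    params = params, seed = seed
  ), class = "sim_sample")
}

#' Cohort design for paired tumour-normal simulation
#'
#' Per transcript type: the normal-tissue abundance is log-normal with the
#' given median and between-pair dispersion (`sdlog`); the tumour member of a
#' pair shares the pair's random effect and is scaled by `tumor_fold`;
#' independent within-pair noise (`sdlog_within`) is added to both members, so
#' a design with `tumor_fold = 1` is exchangeable within pairs.  Zero-inflation
#' independently zeroes a sample's abundance for that type with probability
#' `zero_p`.
#'
#' Defaults emulate the liver (hepatocellular carcinoma) cohort: 65 pairs;
#' combined variant-to-wildtype abundance near 0.05 with v2:v3 near 1 in
#' normal tissue; wildtype and v3 down- and v2 up-regulated about two-fold in
#' tumours; strong interindividual log-normal variability.
#'
#' @param n_pairs Number of tumour-normal pairs.
#' @param types Data frame with columns `type`, `median`, `sdlog`,
#'   `tumor_fold`, `sdlog_within`, `zero_p`.
#' @param n_reads Reads per simulated sample.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n_pairs = 65L,
                          types = data.frame(
                            type = c("v1", "v2", "v3"),
                            median = c(100, 2.5, 2.5),
                            sdlog = c(0.6, 0.9, 0.9),
                            tumor_fold = c(0.5, 2, 0.5),
                            sdlog_within = c(0.3, 0.3, 0.3),
                            zero_p = c(0, 0, 0.05),
                            stringsAsFactors = FALSE),
                          n_reads = 50000L) {
  if (n_pairs < 1L) stopf("n_pairs must be >= 1")
  if (any(types$tumor_fold <= 0)) stopf("tumor fold-changes must be > 0")
  if (any(types$zero_p < 0 | types$zero_p > 1))
    stopf("zero-inflation probabilities must be in [0, 1]")
  structure(list(n_pairs = as.integer(n_pairs), types = types,
                 n_reads = as.integer(n_reads)),
            class = "cohort_design")
}

#' Simulate a paired tumour-normal cohort
#'
#' Draws per-pair abundances under the design's log-normal model and either
#' simulates full FASTQ samples ([simulate_sample()]) or, with
#' `emit = "counts"`, generates per-probe counts directly by Poisson sampling
#' of the closed-form expected junction coverage (fast path for statistical
#' calibration studies; no reads are written).
#'
#' @param locus A `ugt_locus`.
#' @param design A [cohort_design()].
#' @param seed Integer seed (propagated to every sample).
#' @param emit `"reads"` for FASTQ + truth, `"counts"` for count-level truth
#'   only.
#' @param params [sim_params()] used in `"reads"` mode.
#' @param out_dir Directory for FASTQ files (`"reads"` mode with output).
#' @param probes Probe set (default [default_probe_set()]).
#' @param gzip Compress FASTQ output?
#' @param cache Optional precomputed probe-window cache (internal; reused
#'   across repeated count-level simulations).
#' @return A list of class `sim_cohort`: `samples` (per-sample truth entries
#'   with `sample_id`, `group`, `pair_id`, abundances, expected/drawn counts),
#'   `design`, `seed`.
#' @export
simulate_cohort <- function(locus, design = cohort_design(), seed = 1L,
                            emit = c("reads", "counts"),
                            params = sim_params(), out_dir = NULL,
                            probes = default_probe_set(locus), gzip = FALSE,
                            cache = NULL) {
  emit <- match.arg(emit)
  stopifnot(inherits(design, "cohort_design"))
  ty <- design$types
  if (is.null(ty$sdlog_within)) ty$sdlog_within <- 0
  if (is.null(ty$zero_p)) ty$zero_p <- 0

  ab <- with_seed(seed, {
    out <- list()
    for (p in seq_len(design$n_pairs)) {
      pair_effect <- stats::rnorm(nrow(ty), 0, ty$sdlog)
      for (grp in c("normal", "tumor")) {
        noise <- stats::rnorm(nrow(ty), 0, ty$sdlog_within)
        fold <- if (grp == "tumor") ty$tumor_fold else 1
        a <- ty$median * fold * exp(pair_effect + noise)
        a[stats::runif(nrow(ty)) < ty$zero_p] <- 0
        out[[paste0(grp, "_", p)]] <- list(
          sample_id = sprintf("P%03d_%s", p, grp),
          group = grp, pair_id = p,
          abundance = stats::setNames(a, ty$type)
        )
      }
    }
    out
  })

  if (is.null(cache) && emit == "counts") cache <- sim_count_cache(locus, probes)

  samples <- vector("list", length(ab))
  names(samples) <- names(ab)
  for (i in seq_along(ab)) {
    s <- ab[[i]]
    s_seed <- (as.integer(seed) + 104729L * i) %% .Machine$integer.max
    if (emit == "reads") {
      prefix <- if (!is.null(out_dir)) file.path(out_dir, s$sample_id) else NULL
      sim <- simulate_sample(locus, s$abundance, params, seed = s_seed,
                             out_prefix = prefix, probes = probes,
                             gzip = gzip, sample_id = s$sample_id)
      s$files <- sim$files
      s$n_reads <- sim$truth$total_reads
      s$expected_counts <- sim$truth$expected_counts
      s$reads <- sim$reads
    } else {
      s$n_reads <- design$n_reads
      s$expected_counts <- with_seed(s_seed, {
        lam <- expected_probe_counts(locus, s$abundance, design$n_reads,
                                     params$read_len, cache = cache)
        stats::setNames(stats::rpois(length(lam), lam), names(lam))
      })
    }
    samples[[i]] <- s
  }
  structure(list(samples = samples, design = design, seed = seed, emit = emit),
            class = "sim_cohort")
}

# Precomputed transcript sequences, type labels and probe-window locations
# shared across the samples of a count-level cohort simulation.
sim_count_cache <- function(locus, probes = default_probe_set(locus)) {
  tx <- enumerate_all_transcripts(locus)
  seqs <- vapply(tx, function(t) transcript_sequence(locus, t), character(1))
  tx_types <- vapply(tx, function(t) sub("^novel:", "", t$type_label),
                     character(1))
  list(seqs = seqs, tx_types = tx_types, lens = nchar(seqs),
       pw = probe_windows(seqs, probes),
       probe_names = names(probe_sequences(probes)))
}

# Closed-form expected probe counts for a single-end error-free sample:
# a read from transcript T covers a 30-nt window with probability
# (read_len - 30 + 1) / (L_T - read_len + 1); reads are multinomial with
# weights proportional to abundance x length.
expected_probe_counts <- function(locus, abundance, n_reads, read_len,
                                  probes = default_probe_set(locus),
                                  cache = NULL) {
  if (is.null(cache)) cache <- sim_count_cache(locus, probes)
  tx_types <- cache$tx_types
  types <- names(abundance)
  mol <- vapply(seq_along(cache$seqs), function(i) {
    a <- abundance[match(tx_types[i], types)]
    if (is.na(a)) 0 else a / sum(tx_types == tx_types[i])
  }, numeric(1))
  lens <- cache$lens
  w <- mol * lens
  lam <- stats::setNames(numeric(length(cache$probe_names)),
                         cache$probe_names)
  if (sum(w) == 0) return(lam)
  w <- w / sum(w)
  pw <- cache$pw
  for (k in seq_len(nrow(pw))) {
    i <- pw$tx[k]
    wlen <- pw$end[k] - pw$start[k] + 1L
    cov <- max(read_len - wlen + 1L, 0L) / (lens[i] - read_len + 1L)
    lam[pw$probe[k]] <- lam[pw$probe[k]] + n_reads * w[i] * cov
  }
  lam
}

#' Write a cohort truth manifest as JSON
#' @param cohort A `sim_cohort`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(cohort, path) {
  entries <- lapply(cohort$samples, function(s) {
    list(sample_id = s$sample_id, group = s$group, pair_id = s$pair_id,
         abundance = as.list(s$abundance),
         n_reads = s$n_reads,
         expected_counts = as.list(s$expected_counts))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
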