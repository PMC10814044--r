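# Anchored discovery of novel 3' splice junctions.
#
# Desk-scale re-implementation of the targeted CaptureSeq workflow: merge
# overlapping read pairs into fragments, locate exon-boundary anchors (the
# last 40 nt of exon 4, first 38 nt of exon 5a, first 40 nt of exon 5b),
# extract the 15 nt immediately beyond each anchor, aggregate unique flanks,
# and classify each flank into a junction call with a cryptic-site offset.

#' Merge one read pair into a fragment
#'
#' Finds the maximal overlap between the 3' end of read 1 and the 5' end of
#' the reverse-complemented read 2 with a mismatch rate at or below
#' `max_mismatch_rate`; at mismatching positions the consensus takes the
#' higher-quality base.  Returns an unmerged marker (not an error) when no
#' qualifying overlap exists.
#'
#' @param r1,r2 Read sequences (read 2 in sequencing orientation).
#' @param q1,q2 Optional Phred+33 quality strings.
#' @param min_overlap Minimum acceptable overlap (>= 5 nt).
#' @param max_mismatch_rate Maximum fraction of mismatching bases in the
#'   overlap.
#' @return List with `merged` (logical); when merged also `sequence`,
#'   `overlap_len`, `mismatches_in_overlap`.
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 10L,
                       max_mismatch_rate = 0) {
  if (min_overlap < 5L) stopf("min_overlap must be >= 5")
  if (!nzchar(r1) || !nzchar(r2)) stopf("reads must be non-empty")
  rc2 <- revcomp(r2)
  qc2 <- if (!is.null(q2)) paste(rev(strsplit(q2, "")[[1L]]), collapse = "") else NULL
  n1 <- nchar(r1); n2 <- nchar(rc2)
  a <- strsplit(r1, "")[[1L]]
  b <- strsplit(rc2, "")[[1L]]
  qa <- if (!is.null(q1)) utf8ToInt(q1) else rep(30L, n1)
  qb <- if (!is.null(qc2)) utf8ToInt(qc2) else rep(30L, n2)
  for (ov in seq(min(n1, n2), min_overlap)) {
    ia <- (n1 - ov + 1L):n1
    ib <- 1L:ov
    mism <- which(a[ia] != b[ib])
    if (length(mism) <= max_mismatch_rate * ov) {
      cons <- a
      take_b <- mism[qb[ib[mism]] > qa[ia[mism]]]
      if (length(take_b) > 0L) cons[ia[take_b]] <- b[ib[take_b]]
      merged <- paste0(paste(cons, collapse = ""),
                       substr(rc2, ov + 1L, n2))
      return(list(merged = TRUE, sequence = merged, overlap_len = ov,
                  mismatches_in_overlap = length(mism)))
    }
  }
  list(merged = FALSE)
}

# Vectorised merge over read-pair vectors: an exact-overlap pass (maximal
# overlap, scanning from the longest possible overlap down), then an optional
# per-pair mismatch-tolerant pass for the leftovers.
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 10L,
                        max_mismatch_rate = 0) {
  n <- length(r1)
  merged <- character(n)
  ok <- logical(n)
  if (n == 0L) return(list(sequence = merged, merged = ok))
  rc2 <- revcomp(r2)
  n1 <- nchar(r1); n2 <- nchar(rc2)
  remaining <- seq_len(n)
  ov_max <- max(pmin(n1, n2))
  if (ov_max >= min_overlap) for (ov in seq(ov_max, min_overlap)) {
    if (length(remaining) == 0L) break
    cand <- remaining[n1[remaining] >= ov & n2[remaining] >= ov]
    if (length(cand) == 0L) next
    suf <- substr(r1[cand], n1[cand] - ov + 1L, n1[cand])
    pre <- substr(rc2[cand], 1L, ov)
    hit <- suf == pre
    if (any(hit)) {
      i <- cand[hit]
      merged[i] <- paste0(r1[i], substr(rc2[i], ov + 1L, n2[i]))
      ok[i] <- TRUE
      remaining <- setdiff(remaining, i)
    }
  }
  if (max_mismatch_rate > 0 && length(remaining) > 0L) {
    for (i in remaining) {
      m <- merge_pair(r1[i], r2[i],
                      if (is.null(q1)) NULL else q1[i],
                      if (is.null(q2)) NULL else q2[i],
                      min_overlap, max_mismatch_rate)
      if (m$merged) {
        merged[i] <- m$sequence
        ok[i] <- TRUE
      }
    }
  }
  list(sequence = merged, merged = ok)
}

#' Extract anchored flank observations from reads
#'
#' For each occurrence of the exon-4 3' anchor, the 15 nt immediately
#' following it are extracted (`side = "downstream_of_E4"`); for the exon-5a
#' and exon-5b 5' anchors, the 15 nt immediately preceding
#' (`side = "upstream_of_E5a"` / `"upstream_of_E5b"`).  Hits too close to a
#' read end to yield a full flank are dropped.  In `"both"` strand mode each
#' read is also scanned in reverse complement.
#'
#' @param reads Character vector of read/fragment sequences.
#' @param anchors Named list with `E4_end`, `E5a_start`, `E5b_start`
#'   (see [locus_anchors()]).
#' @param flank_len Flank length (default 15 nt).
#' @param strand_mode `"forward"` or `"both"`.
#' @return Data frame: `read_id` (index), `anchor_name`, `side`, `flank_seq`.
#' @export
find_anchored_flanks <- function(reads, anchors, flank_len = 15L,
                                 strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  sides <- c(E4_end = "downstream_of_E4", E5a_start = "upstream_of_E5a",
             E5b_start = "upstream_of_E5b")
  scan_orientation <- function(seqs, read_ids) {
    out <- list()
    len <- nchar(seqs)
    for (an in names(sides)) {
      pos <- regexpr(anchors[[an]], seqs, fixed = TRUE)
      hit <- which(pos > 0L)
      if (length(hit) == 0L) next
      if (an == "E4_end") {
        fs <- pos[hit] + nchar(anchors[[an]])
        fe <- fs + flank_len - 1L
        keep <- fe <= len[hit]
      } else {
        fe <- pos[hit] - 1L
        fs <- fe - flank_len + 1L
        keep <- fs >= 1L
      }
      if (!any(keep)) next
      out[[an]] <- data.frame(
        read_id = read_ids[hit[keep]],
        anchor_name = an, side = unname(sides[an]),
        flank_seq = substr(seqs[hit[keep]], fs[keep], fe[keep]),
        stringsAsFactors = FALSE
      )
    }
    out
  }
  obs <- scan_orientation(reads, seq_along(reads))
  if (strand_mode == "both") {
    obs <- c(obs, scan_orientation(revcomp(reads), seq_along(reads)))
  }
  if (length(obs) == 0L) {
    return(data.frame(read_id = integer(0), anchor_name = character(0),
                      side = character(0), flank_seq = character(0)))
  }
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  out
}

#' Aggregate flank observations into unique flanks with support
#'
#' Exact-sequence grouping per anchor; rows are sorted by support descending,
#' ties broken by flank sequence.
#'
#' @param observations Output of [find_anchored_flanks()].
#' @return Data frame: `anchor_name`, `side`, `flank_seq`, `support`.
#' @export
aggregate_flanks <- function(observations) {
  if (nrow(observations) == 0L) {
    return(data.frame(anchor_name = character(0), side = character(0),
                      flank_seq = character(0), support = integer(0)))
  }
  agg <- stats::aggregate(
    list(support = observations$read_id),
    by = list(anchor_name = observations$anchor_name,
              side = observations$side,
              flank_seq = observations$flank_seq),
    FUN = length
  )
  agg <- agg[order(-agg$support, agg$flank_seq), ]
  rownames(agg) <- NULL
  agg
}

# Candidate table: every flank sequence the classifier recognises, derived
# from the locus.  For each junction spec this is the expected 15-nt flank on
# each anchor side of the junction in the carrying transcript, plus the
# canonical unspliced (intronic) continuations.
discovery_candidates <- function(locus, flank_len = 15L) {
  g <- function(s, e) genome_sub(locus, s, e)
  e4 <- exon_row(locus, "E4"); e2 <- exon_row(locus, "E2")
  e5a <- exon_row(locus, "E5a"); e5b <- exon_row(locus, "E5b")
  e5bv <- exon_row(locus, "E5bv")
  rows <- list()
  add <- function(anchor, flank, class_label, category, donor, acceptor, offset,
                  genomic = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      anchor_name = anchor, expected_flank = flank, class_label = class_label,
      category = category, donor_exon = donor, acceptor_exon = acceptor,
      offset = as.integer(offset), genomic = genomic, stringsAsFactors = FALSE)
  }
  fl <- flank_len
  # downstream of the exon-4 anchor: acceptor-side flanks
  acceptor_flank <- function(exon, off) g(exon$start + off, exon$start + off + fl - 1L)
  add("E4_end", acceptor_flank(e5a, 0L), "v1", "known", "E4", "E5a", 0L)
  add("E4_end", acceptor_flank(e5b, 0L), "v2v3", "known", "E4", "E5b", 0L)
  add("E4_end", acceptor_flank(e5a, 8L), "vE5a1", "novel", "E4", "E5a", 8L)
  add("E4_end", acceptor_flank(e5a, 18L), "vE5a2", "novel", "E4", "E5a", 18L)
  add("E4_end", acceptor_flank(e5a, 31L), "vE5a3", "novel", "E4", "E5a", 31L)
  add("E4_end", acceptor_flank(e5b, -14L), "v2v3up", "novel", "E4", "E5b", -14L)
  add("E4_end", acceptor_flank(e5b, 4L), "v2v3down", "novel", "E4", "E5b", 4L)
  for (nv in c("vE5c", "vE5d")) {
    ex <- exon_row(locus, nv)
    add("E4_end", acceptor_flank(ex, 0L), nv, "novel", "E4", nv,
        ex$start - e5a$end)   # reported as distance downstream of exon 5a
  }
  add("E4_end", g(e4$end + 1L, e4$end + fl), "E4_unspliced", "canonical",
      "E4", "intron", 0L)
  # upstream of the exon-5a anchor: donor-side flanks
  donor_flank <- function(exon, off) g(exon$end + off - fl + 1L, exon$end + off)
  add("E5a_start", donor_flank(e4, 0L), "v1", "known", "E4", "E5a", 0L)
  add("E5a_start", donor_flank(e5bv, 0L), "v3", "known", "E5bv", "E5a", 0L)
  add("E5a_start", donor_flank(e5bv, 8L), "v3down1", "novel", "E5bv", "E5a", 8L)
  add("E5a_start", donor_flank(e5bv, 10L), "v3down2", "novel", "E5bv", "E5a", 10L)
  add("E5a_start", donor_flank(e2, 0L), "vE2E5a", "novel", "E2", "E5a", 0L)
  add("E5a_start", g(e5a$start - fl, e5a$start - 1L), "E5a_unspliced",
      "canonical", "intron", "E5a", 0L)
  # upstream of the exon-5b anchor
  add("E5b_start", donor_flank(e4, 0L), "v2v3", "known", "E4", "E5b", 0L)
  # the v2/v3up transcript retains 14 intronic nt upstream of exon 5b, so its
  # flank on this side is 1 nt of exon 4 followed by that extension
  add("E5b_start", paste0(substr(donor_flank(e4, 0L), fl, fl),
                          g(e5b$start - 14L, e5b$start - 1L)),
      "v2v3up", "novel", "E4", "E5b", -14L, genomic = FALSE)
  # exon 4 ends ...GACAAAAG and exon 5b starts AAAG, so in the v2/v3down
  # transcript (exon 5b minus its first 4 nt) the exon-5b anchor is
  # reconstituted across the junction, shifted 4 nt into exon 4; the flank
  # preceding that occurrence ends 4 nt short of the exon-4 3' end
  add("E5b_start", donor_flank(e4, -4L), "v2v3down", "novel", "E4", "E5b", 4L)
  add("E5b_start", g(e5b$start - fl, e5b$start - 1L), "E5b_unspliced",
      "canonical", "intron", "E5b", 0L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a single anchored flank
#'
#' Matches the flank against the expected continuations of the known and
#' novel junction specs and the canonical unspliced (intronic) continuation.
#' A flank matching no candidate falls back to a genomic search: a unique hit
#' yields an `unclassified` call with its computed offset relative to the
#' nearest relevant exon boundary; an ambiguous (multi-locus) or absent hit is
#' `unclassified` with an NA offset.
#'
#' @param anchor_name One of `"E4_end"`, `"E5a_start"`, `"E5b_start"`.
#' @param flank_seq The observed flank sequence.
#' @param locus A `ugt_locus`.
#' @param candidates Precomputed [discovery_candidates()] table (optional).
#' @return One-row data frame: `class_label`, `category`, `donor_exon`,
#'   `acceptor_exon`, `offset`, `note`.
#' @export
classify_junction <- function(anchor_name, flank_seq, locus,
                              candidates = discovery_candidates(locus)) {
  cand <- candidates[candidates$anchor_name == anchor_name &
                       candidates$expected_flank == flank_seq, ]
  if (nrow(cand) == 1L) {
    return(data.frame(class_label = cand$class_label, category = cand$category,
                      donor_exon = cand$donor_exon,
                      acceptor_exon = cand$acceptor_exon,
                      offset = cand$offset, note = "", stringsAsFactors = FALSE))
  }
  if (nrow(cand) > 1L) {
    return(data.frame(class_label = "unclassified", category = "unclassified",
                      donor_exon = NA_character_, acceptor_exon = NA_character_,
                      offset = NA_integer_, note = "ambiguous candidate match",
                      stringsAsFactors = FALSE))
  }
  hits <- Biostrings::matchPattern(flank_seq, Biostrings::DNAString(locus$genome))
  if (length(hits) == 1L) {
    pos <- BiocGenerics::start(hits)[1L]
    ref <- if (anchor_name == "E4_end") {
      # offset of the observed acceptor relative to exon 5a's 5' end
      exon_row(locus, "E5a")$start
    } else if (anchor_name == "E5a_start") {
      exon_row(locus, "E5bv")$end - 15L + 1L
    } else {
      exon_row(locus, "E5b")$start
    }
    return(data.frame(class_label = "unclassified", category = "unclassified",
                      donor_exon = NA_character_, acceptor_exon = NA_character_,
                      offset = as.integer(pos - ref),
                      note = sprintf("unique genomic hit at %d", pos),
                      stringsAsFactors = FALSE))
  }
  data.frame(class_label = "unclassified", category = "unclassified",
             donor_exon = NA_character_, acceptor_exon = NA_character_,
             offset = NA_integer_,
             note = if (length(hits) == 0L) "no genomic match" else
               "ambiguous genomic match",
             stringsAsFactors = FALSE)
}

#' Run the full discovery pipeline
#'
#' Paired input is merged first ([merge_pairs()]); unmerged pairs are scanned
#' as single reads.  Anchored flanks are extracted, aggregated, classified,
#' and calls are aggregated by junction class (support summed over anchor
#' sides and flanks).  Calls with support below `min_support` are retained but
#' flagged.
#'
#' @param reads FASTQ path(s) or character vector of read sequences (single
#'   mode), or a list with `r1` and `r2` vectors / `fastq1`, `fastq2` paths
#'   (paired mode).
#' @param locus A `ugt_locus`.
#' @param paired Treat input as read pairs?
#' @param min_overlap,max_mismatch_rate Pair-merging parameters.
#' @param min_support Calls below this support are flagged `low_support`.
#' @param flank_len Flank length (nt).
#' @param strand_mode Anchor scanning orientation.
#' @return A data frame of class `junction_calls`: `class_label`, `category`,
#'   `donor_exon`, `acceptor_exon`, `offset`, `supporting_reads`, `flank`
#'   (representative, highest-support), `low_support`, `note`.
#' @export
discover <- function(reads, locus, paired = FALSE, min_overlap = 10L,
                     max_mismatch_rate = 0, min_support = 1L,
                     flank_len = 15L, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (paired) {
    if (is.list(reads)) {
      r1 <- reads$r1 %||% reads$fastq1
      r2 <- reads$r2 %||% reads$fastq2
    } else if (length(reads) == 2L && all(file.exists(reads))) {
      r1 <- reads[1L]; r2 <- reads[2L]
    } else {
      stopf("paired input must supply r1/r2 (or fastq1/fastq2)")
    }
    if (length(r1) == 1L && is.character(r1) && file.exists(r1[1L])) {
      r1 <- as.character(read_fastq(r1))
      r2 <- as.character(read_fastq(r2))
    }
    m <- merge_pairs(r1, r2, min_overlap = min_overlap,
                     max_mismatch_rate = max_mismatch_rate)
    frags <- c(m$sequence[m$merged], r1[!m$merged], revcomp(r2[!m$merged]))
  } else {
    if (is.character(reads) && length(reads) > 0L && all(file.exists(reads))) {
      frags <- unlist(lapply(reads, function(f) as.character(read_fastq(f))))
    } else {
      frags <- reads
    }
  }
  anchors <- locus_anchors(locus)
  obs <- find_anchored_flanks(frags, anchors, flank_len = flank_len,
                              strand_mode = strand_mode)
  agg <- aggregate_flanks(obs)
  cand <- discovery_candidates(locus, flank_len = flank_len)
  if (nrow(agg) == 0L) {
    out <- data.frame(class_label = character(0), category = character(0),
                      donor_exon = character(0), acceptor_exon = character(0),
                      offset = integer(0), supporting_reads = integer(0),
                      flank = character(0), low_support = logical(0),
                      note = character(0))
    class(out) <- c("junction_calls", "data.frame")
    return(out)
  }
  cls <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i) {
    classify_junction(agg$anchor_name[i], agg$flank_seq[i], locus, cand)
  }))
  cls$supporting_reads <- agg$support
  cls$flank <- agg$flank_seq
  # aggregate by call identity (unclassified flanks stay separate); keep the
  # highest-support flank as representative
  key <- paste(cls$class_label, cls$donor_exon, cls$acceptor_exon, cls$offset,
               sep = "|")
  key <- ifelse(cls$class_label == "unclassified",
                paste("unclassified", cls$flank, sep = "|"), key)
  ord <- order(-cls$supporting_reads)
  cls <- cls[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  support <- tapply(cls$supporting_reads, key, sum)
  out <- cls[first, c("class_label", "category", "donor_exon", "acceptor_exon",
                      "offset", "supporting_reads", "flank", "note")]
  out$supporting_reads <- as.integer(support[key[first]])
  out$low_support <- out$supporting_reads < min_support
  out <- out[order(match(out$category, c("known", "novel", "canonical",
                                         "unclassified")),
                   -out$supporting_reads), ]
  rownames(out) <- NULL
  class(out) <- c("junction_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.junction_calls <- function(x, ...) {
  cat(sprintf("junction calls: %d (novel %d, unclassified %d)\n", nrow(x),
              sum(x$category == "novel"), sum(x$category == "unclassified")))
  print.data.frame(x[, c("class_label", "category", "donor_exon",
                         "acceptor_exon", "offset", "supporting_reads")],
                   row.names = FALSE)
  invisible(x)
}

#' Write junction calls as TSV
#' @param calls A `junction_calls` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write called junction breakpoints as BED (0-based half-open)
#' @param calls A `junction_calls` data frame.
#' @param locus The `ugt_locus` the calls refer to.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls_bed <- function(calls, locus, path) {
  known <- calls[calls$category %in% c("known", "novel") &
                   calls$class_label %in% locus$junctions$name, ]
  rows <- lapply(seq_len(nrow(known)), function(i) {
    j <- locus$junctions[match(known$class_label[i], locus$junctions$name), ]
    jc <- junction_coords(locus, j)
    data.frame(chrom = "UGT1A_locus", start = jc$donor_end - 1L,
               end = jc$acceptor_start, name = known$class_label[i],
               score = known$supporting_reads[i], strand = "+",
               stringsAsFactors = FALSE)
  })
  bed <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
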