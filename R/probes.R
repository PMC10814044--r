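# Junction-spanning probe construction and uniqueness verification.

#' Construct a junction-spanning probe
#'
#' The probe sequence is the last `left_len` nt of the (possibly
#' offset-trimmed) donor side followed by the first `right_len` nt of the
#' (possibly offset-trimmed) acceptor side of the named junction.  With the
#' default 15/15 arms the three known junctions yield exactly the published
#' 30-nt probes.
#'
#' @param locus A `ugt_locus`.
#' @param junction Junction name (row of `locus$junctions`).
#' @param left_len,right_len Arm lengths in nt (each >= 8).
#' @return A list of class `ugt_probe`: `name`, `sequence`, `left_len`,
#'   `right_len`, `target_junction`.
#' @examples
#' locus <- build_locus(seed = 1)
#' make_probe(locus, "v1")$sequence
#' @export
make_probe <- function(locus, junction, left_len = 15L, right_len = 15L) {
  left_len <- as.integer(left_len); right_len <- as.integer(right_len)
  if (left_len < 8L || right_len < 8L)
    stopf("probe arms must each be at least 8 nt")
  i <- match(junction, locus$junctions$name)
  if (is.na(i)) stopf("unknown junction: %s", junction)
  j <- locus$junctions[i, ]
  d <- exon_row(locus, j$donor_exon)
  a <- exon_row(locus, j$acceptor_exon)
  donor_end <- d$end + j$donor_offset
  acceptor_start <- a$start + j$acceptor_offset
  donor_avail <- donor_end - d$start + 1L
  acceptor_avail <- a$end - acceptor_start + 1L
  if (left_len > donor_avail)
    stopf("probe arm (%d nt) longer than available donor sequence for junction %s (%d nt)",
          left_len, junction, donor_avail)
  if (right_len > acceptor_avail)
    stopf("probe arm (%d nt) longer than available acceptor sequence for junction %s (%d nt)",
          right_len, junction, acceptor_avail)
  seq <- paste0(genome_sub(locus, donor_end - left_len + 1L, donor_end),
                genome_sub(locus, acceptor_start, acceptor_start + right_len - 1L))
  structure(list(name = junction, sequence = seq, left_len = left_len,
                 right_len = right_len, target_junction = junction),
            class = "ugt_probe")
}

#' @export
print.ugt_probe <- function(x, ...) {
  cat(sprintf("probe %s: %s/%s\n", x$name,
              substr(x$sequence, 1, x$left_len),
              substr(x$sequence, x$left_len + 1L, nchar(x$sequence))))
  invisible(x)
}

#' Default probe set with uniqueness verification
#'
#' One probe per junction in the locus (13 for the default locus: the three
#' published probes plus one 15/15 probe per novel junction).  Every probe is
#' checked by exhaustive substring scan against all enumerated transcript
#' sequences: it must occur in exactly the transcripts that realise its target
#' junction (the v2/v3 probe, for instance, legitimately matches every
#' transcript carrying the shared E4/E5b(v) boundary).  Mismatches are flagged,
#' never silently accepted.
#'
#' @param locus A `ugt_locus`.
#' @param left_len,right_len Arm lengths for all probes.
#' @param transcripts Transcript list to verify against (default
#'   [enumerate_all_transcripts()]).
#' @return A data frame of class `ugt_probe_set` with columns `name`,
#'   `sequence`, `left_len`, `right_len`, `target_junction`, `n_expected`,
#'   `n_observed`, `ok`, `collisions` (comma-separated ids of transcripts that
#'   match but should not, or should match but do not).
#' @export
default_probe_set <- function(locus, left_len = 15L, right_len = 15L,
                              transcripts = enumerate_all_transcripts(locus)) {
  seqs <- vapply(transcripts, function(t) transcript_sequence(locus, t),
                 character(1))
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  rows <- lapply(seq_len(nrow(locus$junctions)), function(i) {
    j <- locus$junctions[i, ]
    p <- make_probe(locus, j$name, left_len, right_len)
    expected <- vapply(transcripts, function(t) {
      transcript_has_junction(locus, t, j)
    }, logical(1))
    observed <- grepl(p$sequence, seqs, fixed = TRUE)
    bad <- xor(expected, observed)
    data.frame(name = p$name, sequence = p$sequence,
               left_len = p$left_len, right_len = p$right_len,
               target_junction = p$target_junction,
               n_expected = sum(expected), n_observed = sum(observed),
               ok = !any(bad),
               collisions = paste(ids[bad], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ugt_probe_set", "data.frame")
  out
}

#' @export
print.ugt_probe_set <- function(x, ...) {
  cat(sprintf("Probe set: %d probes (%d verified unique to their targets)\n",
              nrow(x), sum(x$ok)))
  print.data.frame(x[, c("name", "sequence", "n_expected", "n_observed", "ok")],
                   row.names = FALSE)
  if (any(!x$ok)) {
    cat("flagged collisions:\n")
    print.data.frame(x[!x$ok, c("name", "collisions")], row.names = FALSE)
  }
  invisible(x)
}

#' Export a probe set as TSV
#' @param probes A `ugt_probe_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_probes_tsv <- function(probes, path) {
  utils::write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe TSV back into a named probe vector
#' @param path TSV with at least `name` and `sequence` columns.
#' @return Named character vector of probe sequences.
#' @export
read_probes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$sequence, df$name)
}

# Named probe sequence vector from a probe set (the form the quantifier uses).
probe_sequences <- function(probes) {
  if (is.character(probes)) {
    if (is.null(names(probes)) || any(!nzchar(names(probes))))
      stopf("probe vectors must be named")
    return(probes)
  }
  stats::setNames(probes$sequence, probes$name)
}
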