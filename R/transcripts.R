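# Transcript enumeration and sequence assembly.
#
# A transcript model is a chain of exons with optional signed trims/extensions:
# `off5` shifts the exon's 5' start (positive = bases skipped, negative =
# extension into upstream genomic sequence) and `off3` shifts its 3' end
# (positive = extension into downstream genomic sequence).

new_transcript <- function(transcript_id, type_label, exon_ids,
                           off5 = integer(length(exon_ids)),
                           off3 = integer(length(exon_ids))) {
  structure(list(
    transcript_id = transcript_id,
    type_label = type_label,
    chain = data.frame(exon_id = exon_ids, off5 = as.integer(off5),
                       off3 = as.integer(off3), stringsAsFactors = FALSE)
  ), class = "ugt_transcript")
}

#' @export
print.ugt_transcript <- function(x, ...) {
  cat(sprintf("<%s> [%s] %s\n", x$transcript_id, x$type_label,
              paste(x$chain$exon_id, collapse = "-")))
  invisible(x)
}

#' Enumerate the known transcript set
#'
#' For each functional first exon: a canonical v1 transcript
#' (first-E2-E3-E4-E5a), a v2 variant ending in exon 5b, and a v3 variant with
#' exon 5bv inserted between exons 4 and 5a.  Canonical splicing joins the
#' transcript's own first exon directly to exon 2, excising any intervening
#' first exons.
#'
#' @param locus A `ugt_locus`.
#' @return List of `ugt_transcript` objects (9 v1 + 9 v2 + 9 v3 for the
#'   default locus).
#' @export
enumerate_known_transcripts <- function(locus) {
  stopifnot(length(locus$first_exons) >= 1L)
  out <- list()
  for (f in locus$first_exons) {
    out[[paste0("v1.", f)]] <- new_transcript(paste0("v1.", f), "v1",
                                              c(f, "E2", "E3", "E4", "E5a"))
    out[[paste0("v2.", f)]] <- new_transcript(paste0("v2.", f), "v2",
                                              c(f, "E2", "E3", "E4", "E5b"))
    out[[paste0("v3.", f)]] <- new_transcript(paste0("v3.", f), "v3",
                                              c(f, "E2", "E3", "E4", "E5bv", "E5a"))
  }
  out
}

#' Enumerate the ten novel 3'-variant transcript classes
#'
#' One transcript per novel junction: extended-5bv cassettes (v3down1/2),
#' extended or truncated exon 5b (v2/v3up, v2/v3down), 5'-truncated exon 5a
#' (vE5a1/2/3), direct exon2-exon5a splicing (vE2E5a), and the distal novel
#' terminal exons vE5c/vE5d.
#'
#' @param locus A `ugt_locus`.
#' @param first_exon First exon used for the novel models (default the most
#'   distal, `E1_1`).
#' @return List of 10 `ugt_transcript` objects.
#' @export
enumerate_novel_transcripts <- function(locus, first_exon = locus$first_exons[1L]) {
  f <- first_exon
  common <- c(f, "E2", "E3", "E4")
  tx <- list(
    v3down1 = new_transcript("v3down1", "novel:v3down1",
                             c(common, "E5bv", "E5a"),
                             off3 = c(0L, 0L, 0L, 0L, 8L, 0L)),
    v3down2 = new_transcript("v3down2", "novel:v3down2",
                             c(common, "E5bv", "E5a"),
                             off3 = c(0L, 0L, 0L, 0L, 10L, 0L)),
    v2v3up = new_transcript("v2v3up", "novel:v2v3up",
                            c(common, "E5b"),
                            off5 = c(0L, 0L, 0L, 0L, -14L)),
    v2v3down = new_transcript("v2v3down", "novel:v2v3down",
                              c(common, "E5b"),
                              off5 = c(0L, 0L, 0L, 0L, 4L)),
    vE5a1 = new_transcript("vE5a1", "novel:vE5a1", c(common, "E5a"),
                           off5 = c(0L, 0L, 0L, 0L, 8L)),
    vE5a2 = new_transcript("vE5a2", "novel:vE5a2", c(common, "E5a"),
                           off5 = c(0L, 0L, 0L, 0L, 18L)),
    vE5a3 = new_transcript("vE5a3", "novel:vE5a3", c(common, "E5a"),
                           off5 = c(0L, 0L, 0L, 0L, 31L)),
    vE2E5a = new_transcript("vE2E5a", "novel:vE2E5a", c(f, "E2", "E5a")),
    vE5c = new_transcript("vE5c", "novel:vE5c", c(common, "vE5c")),
    vE5d = new_transcript("vE5d", "novel:vE5d", c(common, "vE5d"))
  )
  tx
}

#' All transcripts of the locus
#'
#' The known set plus the ten novel classes (37 transcripts for the default
#' nine-first-exon locus).
#'
#' @inheritParams enumerate_known_transcripts
#' @return Named list of `ugt_transcript` objects.
#' @export
enumerate_all_transcripts <- function(locus) {
  c(enumerate_known_transcripts(locus), enumerate_novel_transcripts(locus))
}

#' Assemble a transcript's nucleotide sequence
#'
#' Concatenates the chained exon sequences with 5'/3' trims and extensions
#' applied.
#'
#' @param locus A `ugt_locus`.
#' @param transcript A `ugt_transcript`.
#' @return Character string.
#' @export
transcript_sequence <- function(locus, transcript) {
  ch <- transcript$chain
  if (nrow(ch) == 0L) stopf("transcript %s has an empty exon chain",
                            transcript$transcript_id)
  segs <- vapply(seq_len(nrow(ch)), function(i) {
    r <- exon_row(locus, ch$exon_id[i])
    genome_sub(locus, r$start + ch$off5[i], r$end + ch$off3[i])
  }, character(1))
  paste(segs, collapse = "")
}

# Genomic breakpoints realised by a transcript chain: for each consecutive
# exon pair, the donor 3' coordinate and acceptor 5' coordinate.
transcript_breakpoints <- function(locus, transcript) {
  ch <- transcript$chain
  if (nrow(ch) < 2L) {
    return(data.frame(donor_coord = integer(0), acceptor_coord = integer(0)))
  }
  i <- seq_len(nrow(ch) - 1L)
  donor <- vapply(i, function(k) {
    exon_row(locus, ch$exon_id[k])$end + ch$off3[k]
  }, numeric(1))
  acceptor <- vapply(i + 1L, function(k) {
    exon_row(locus, ch$exon_id[k])$start + ch$off5[k]
  }, numeric(1))
  data.frame(donor_coord = as.integer(donor), acceptor_coord = as.integer(acceptor))
}

# Does the transcript realise junction `jrow` (matched on genomic
# coordinates, so e.g. the shared E4/E5bv == E4/E5b 5' boundary is honoured)?
transcript_has_junction <- function(locus, transcript, jrow) {
  jc <- junction_coords(locus, jrow)
  bp <- transcript_breakpoints(locus, transcript)
  any(bp$donor_coord == jc$donor_end & bp$acceptor_coord == jc$acceptor_start)
}

#' Export transcript (or locus) sequences as FASTA
#'
#' @param locus A `ugt_locus`.
#' @param path Output file path.
#' @param transcripts Optional list of `ugt_transcript`; when `NULL` the
#'   genomic locus sequence is written as a single record.
#' @return The path, invisibly.
#' @export
write_locus_fasta <- function(locus, path, transcripts = NULL) {
  if (is.null(transcripts)) {
    x <- Biostrings::DNAStringSet(c(UGT1A_locus = locus$genome))
  } else {
    seqs <- vapply(transcripts, function(t) transcript_sequence(locus, t),
                   character(1))
    names(seqs) <- vapply(transcripts, `[[`, character(1), "transcript_id")
    x <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Export the junction table as TSV
#' @param locus A `ugt_locus`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_junctions_tsv <- function(locus, path) {
  utils::write.table(locus$junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export junction breakpoints as BED
#'
#' Coordinates are converted from the internal 1-based inclusive convention to
#' BED's 0-based half-open intervals; each record covers the two bases flanking
#' the splice (donor 3' base and acceptor 5' base).
#'
#' @param locus A `ugt_locus`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_junctions_bed <- function(locus, path) {
  rows <- lapply(seq_len(nrow(locus$junctions)), function(i) {
    j <- locus$junctions[i, ]
    jc <- junction_coords(locus, j)
    data.frame(chrom = "UGT1A_locus",
               start = jc$donor_end - 1L,   # 0-based start of donor 3' base
               end = jc$acceptor_start,     # half-open end covering acceptor base
               name = j$name, score = 0L, strand = "+",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
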