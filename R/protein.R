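# Protein prediction for locus transcripts.
#
# The annotated ORF starts at the first exon's start codon.  Exon 4 contributes
# its final two bases to the codon spanning the 3' junction, so v2/v3
# transcripts read AG + exon-5b sequence at the junction and terminate at the
# i2 stop codon inside exon 5bv — which is why v2 and v3 encode identical
# truncated proteins ending in the novel 10-residue C-terminal peptide.

#' Predict the protein encoded by a transcript
#'
#' Translates from the annotated start codon in the transcript's first exon to
#' the first in-frame stop.  The prediction is compared against the full-length
#' i1 reference (the v1 transcript sharing the same first exon) to derive the
#' shared N-terminal length and the novel C-terminal peptide.
#'
#' @param locus A `ugt_locus`.
#' @param transcript A `ugt_transcript` whose chain starts with a first exon.
#' @param reference Optional i1 reference prediction; computed from the
#'   matching v1 transcript when `NULL` (a v1 transcript is its own reference).
#' @return A list of class `ugt_protein`: `peptide`, `stop_found`,
#'   `shared_n_terminal_len`, `novel_c_terminal`, `e4_boundary_aa` (number of
#'   complete codons upstream of the exon-4 junction codon) and
#'   `i1_tail_len` (residues of the reference from the junction codon on).
#' @examples
#' locus <- build_locus(seed = 1)
#' tx <- enumerate_known_transcripts(locus)
#' predict_protein(locus, tx[["v2.E1_1"]])$novel_c_terminal
#' @export
predict_protein <- function(locus, transcript, reference = NULL) {
  first <- transcript$chain$exon_id[1L]
  if (!(first %in% locus$first_exons))
    stopf("transcript %s does not start at a first exon", transcript$transcript_id)
  seq <- transcript_sequence(locus, transcript)
  atg <- locus$atg_offset
  if (substr(seq, atg, atg + 2L) != "ATG")
    stopf("no start codon at the annotated position of %s", transcript$transcript_id)
  orf <- translate_orf(substr(seq, atg, nchar(seq)))

  e4_boundary_aa <- (cds_len_through_e4(locus$config) - locus$e4_codon_overhang) %/% 3L

  is_v1 <- transcript$type_label == "v1"
  if (is.null(reference) && !is_v1) {
    ref_tx <- new_transcript(paste0("v1.", first), "v1",
                             c(first, "E2", "E3", "E4", "E5a"))
    reference <- predict_protein(locus, ref_tx)
  }
  if (is_v1 && is.null(reference)) {
    shared <- nchar(orf$peptide)
    novel <- ""
    i1_tail <- nchar(orf$peptide) - e4_boundary_aa
  } else {
    shared <- common_prefix_len(orf$peptide, reference$peptide)
    novel <- substr(orf$peptide, shared + 1L, nchar(orf$peptide))
    i1_tail <- nchar(reference$peptide) - e4_boundary_aa
  }
  structure(list(
    peptide = orf$peptide,
    stop_found = orf$stop_found,
    shared_n_terminal_len = shared,
    novel_c_terminal = novel,
    e4_boundary_aa = e4_boundary_aa,
    i1_tail_len = i1_tail
  ), class = "ugt_protein")
}

#' @export
print.ugt_protein <- function(x, ...) {
  cat(sprintf("%d aa%s; shared N-terminal %d aa; novel C-terminal '%s'\n",
              nchar(x$peptide), if (x$stop_found) "" else " (no stop found)",
              x$shared_n_terminal_len, x$novel_c_terminal))
  invisible(x)
}

#' Classify a predicted protein against the i1 reference
#'
#' `i1-like` when identical to the reference; `i2-like` when the shared
#' N-terminal region extends through all exon-4-encoded residues and the novel
#' C-terminal peptide is non-empty and shorter than the exon-5a-encoded tail of
#' the full-length protein; `other` otherwise (e.g. transcripts that skip
#' exons 3/4).
#'
#' @param p A `ugt_protein` prediction.
#' @param reference_i1 The i1 reference `ugt_protein`.
#' @return One of `"i1-like"`, `"i2-like"`, `"other"`.
#' @export
classify_protein <- function(p, reference_i1) {
  if (identical(p$peptide, reference_i1$peptide)) return("i1-like")
  tail_len <- nchar(p$novel_c_terminal)
  if (p$shared_n_terminal_len >= p$e4_boundary_aa &&
      tail_len > 0L && tail_len < p$i1_tail_len) {
    return("i2-like")
  }
  "other"
}
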