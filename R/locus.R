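# Splice-graph model of the UGT1A locus.
#
# The locus produces nine canonical transcripts (v1, one per functional first
# exon) ending in exon 5a, nine v2 variants ending in the alternative exon 5b,
# and nine v3 variants carrying exon 5bv (the 5' 134-nt portion of 5b) as an
# internal cassette between exons 4 and 5a.  Ten further transcript classes
# arise from cryptic 3' splice sites around exons 5a/5b/5bv.  The model is
# synthetic: sequence content is seeded-random except where published junction
# probes and exon-boundary anchors pin it down.

# Published 30-nt junction probes (slash removed) and exon-boundary anchors.
PROBE_V1   <- "CATCAATGACAAAAGTTACAAGGAGAACAT"
PROBE_V2V3 <- "CATCAATGACAAAAGAAAGAAGCAGCAGTC"
PROBE_V3   <- "CTTCCCACCTTTGAGTTACAAGGAGAACAT"
ANCHOR_E4_END    <- "ATTTAGAAAATGCTCTAAAAGCAGTCATCAATGACAAAAG"
ANCHOR_E5A_START <- "TTACAAGGAGAACATCATGCGCCTCTCCAGCCTTCACA"
ANCHOR_E5B_START <- "AAAGAAGCAGCAGTCAGGAAGACAGATGTGAAGAGCTGGA"
E5BV_END <- "CTTCCCACCTTTGAG"  # last 15 nt of exon 5bv

NOVEL_CLASSES <- c("v3down1", "v3down2", "v2v3up", "v2v3down",
                   "vE5a1", "vE5a2", "vE5a3", "vE2E5a", "vE5c", "vE5d")

#' Default locus configuration
#'
#' Lengths are in nucleotides.  Exon 5b defaults to 2086 nt and exon 5bv to its
#' 5' 134-nt prefix.  The reading frame is arranged so that exon 4 contributes
#' its final two bases to the codon spanning the exon 4 junction
#' (`e4_codon_overhang = 2`), the only frame in which the published junction
#' anchors translate to the i2 C-terminal peptide.  `i1_tail_aa` is the number
#' of residues of the full-length protein encoded from the junction codon
#' onwards by exon 5a (the C-terminal tail that the truncated i2 isoforms
#' lack).
#'
#' @param n_first Number of functional first exons.
#' @param first_exon_len,utr5_len First-exon length and its 5' UTR length
#'   (the start codon sits at `utr5_len + 1`).
#' @param e2_len,e3_len,e4_len,e5a_len,e5b_len,e5bv_len Exon lengths.
#' @param intron_first,intron23,intron34,intron4a,intron5 Intron lengths
#'   (between first exons; E2-E3; E3-E4; E4-E5b; E5b-E5a).
#' @param flank_len Length of the genomic region downstream of exon 5a that
#'   hosts the novel terminal exons vE5c and vE5d.
#' @param ve5c_offset,ve5d_offset Distances (nt) from the 3' end of exon 5a to
#'   the first base of vE5c and vE5d.
#' @param novel_exon_len Length given to the novel terminal exons vE5c/vE5d.
#' @param i1_tail_aa Residues of the i1 protein encoded by exon 5a.
#' @param sequences Optional named list of explicit exon/segment sequences
#'   overriding synthesis (names as in the exon table, plus `flank` and
#'   `decoy`); overridden sequences are still validated against every locus
#'   invariant.
#' @return A list of class `ugt_locus_config`.
#' @export
locus_config <- function(n_first = 9L,
                         first_exon_len = 600L, utr5_len = 120L,
                         e2_len = 150L, e3_len = 133L, e4_len = 220L,
                         e5a_len = 400L, e5b_len = 2086L, e5bv_len = 134L,
                         intron_first = 200L, intron23 = 150L,
                         intron34 = 150L, intron4a = 400L, intron5 = 300L,
                         flank_len = 8000L,
                         ve5c_offset = 7054L, ve5d_offset = 7405L,
                         novel_exon_len = 200L,
                         i1_tail_aa = 99L,
                         sequences = NULL) {
  cfg <- list(
    n_first = as.integer(n_first),
    first_exon_len = as.integer(first_exon_len),
    utr5_len = as.integer(utr5_len),
    e2_len = as.integer(e2_len), e3_len = as.integer(e3_len),
    e4_len = as.integer(e4_len), e5a_len = as.integer(e5a_len),
    e5b_len = as.integer(e5b_len), e5bv_len = as.integer(e5bv_len),
    intron_first = as.integer(intron_first), intron23 = as.integer(intron23),
    intron34 = as.integer(intron34), intron4a = as.integer(intron4a),
    intron5 = as.integer(intron5),
    flank_len = as.integer(flank_len),
    ve5c_offset = as.integer(ve5c_offset),
    ve5d_offset = as.integer(ve5d_offset),
    novel_exon_len = as.integer(novel_exon_len),
    i1_tail_aa = as.integer(i1_tail_aa),
    sequences = sequences
  )
  class(cfg) <- "ugt_locus_config"
  cfg
}

# Coding length from the start codon through the end of exon 4 for a given
# configuration.
cds_len_through_e4 <- function(cfg) {
  (cfg$first_exon_len - cfg$utr5_len) + cfg$e2_len + cfg$e3_len + cfg$e4_len
}

#' Build the synthetic UGT1A locus model
#'
#' Synthesises a locus sequence consistent with all published probe and anchor
#' sequences: exon 4 ends with the 40-nt exon-4 anchor, exon 5a starts with the
#' 38-nt exon-5a anchor, exon 5b starts with the 40-nt exon-5b anchor (which
#' carries the i2 stop codon), and exon 5bv is the 5' `e5bv_len` prefix of exon
#' 5b ending `...CTTCCCACCTTTGAG`.  All remaining sequence is drawn from a
#' seeded generator; coding segments are kept free of in-frame stop codons so
#' the annotated open reading frames behave as designed.  The same seed always
#' yields the same locus.
#'
#' After synthesis the model is validated: anchored boundaries must reproduce
#' the three published 30-nt junction probes, the reading-frame phase at the
#' end of exon 4 must leave a 2-nt codon overhang, and every 15-nt junction
#' flank used by the discovery classifier must be unique in the locus (if a
#' random draw collides, the generator deterministically redraws).
#'
#' @param seed Integer seed for sequence synthesis.
#' @param config A [locus_config()] object.
#' @return An object of class `ugt_locus` with components `genome` (single
#'   character string), `exons` (data frame: `exon_id`, `start`, `end`, `role`),
#'   `junctions` (data frame of the 3 known + 10 novel junction specs),
#'   `first_exons`, `atg_offset`, `e4_codon_overhang`, `decoy` (a screened
#'   background sequence for simulations), `config`, `seed`.
#' @examples
#' locus <- build_locus(seed = 1)
#' locus$junctions
#' @export
build_locus <- function(seed = 1L, config = locus_config()) {
  stopifnot(inherits(config, "ugt_locus_config"))
  for (attempt in 0:19) {
    locus <- with_seed(as.integer(seed) + attempt * 7919L,
                       synthesize_locus(config))
    validate_locus(locus)
    if (length(screen_kmer_uniqueness(locus)) == 0L) {
      locus$seed <- as.integer(seed)
      return(locus)
    }
  }
  stopf("could not synthesise a locus with unique junction flanks from seed %d", seed)
}

# One synthesis pass (assumes RNG already seeded).
synthesize_locus <- function(cfg) {
  sq <- cfg$sequences
  # the generator is always consumed so that overriding one segment leaves
  # the RNG stream (and hence every other segment) unchanged
  pick <- function(id, gen) {
    drawn <- gen()
    if (!is.null(sq) && !is.null(sq[[id]])) toupper(sq[[id]]) else drawn
  }

  if (cfg$utr5_len < 0L || cfg$first_exon_len - cfg$utr5_len - 3L <= 0L)
    stopf("locus invariant violated: first exon too short for UTR plus ORF")
  n_first_codons <- (cfg$first_exon_len - cfg$utr5_len - 3L) %/% 3L
  if ((cfg$first_exon_len - cfg$utr5_len - 3L) %% 3L != 0L)
    stopf("locus invariant violated: first-exon coding length must be a whole number of codons")
  if (cds_len_through_e4(cfg) %% 3L != 2L)
    stopf("locus invariant violated: e4_codon_overhang = 2 requires CDS length through exon 4 == 2 (mod 3)")

  first_ids <- paste0("E1_", seq_len(cfg$n_first))
  first_seqs <- lapply(first_ids, function(id) {
    pick(id, function() {
      paste0(random_dna(cfg$utr5_len), "ATG", random_codons(n_first_codons))
    })
  })
  names(first_seqs) <- first_ids

  if (cfg$e2_len %% 3L != 0L)
    stopf("locus invariant violated: default phase layout requires exon-2 length divisible by 3")
  e2 <- pick("E2", function() random_codons(cfg$e2_len %/% 3L))
  # Exon 3 ends mid-codon: 44 whole codons + 1 nt; the straddling codon is
  # completed by the fixed "GG" opening of exon 4 (x-G-G is never a stop).
  e3_codons <- (cfg$e3_len - 1L) %/% 3L
  if (cfg$e3_len - 1L - 3L * e3_codons != 0L)
    stopf("locus invariant violated: default phase layout requires exon-3 length == 1 (mod 3)")
  e3 <- pick("E3", function() paste0(random_codons(e3_codons), "C"))

  # Exon 4: "GG" completes the straddling codon; then whole codons; one free
  # base whose codon straddles into the anchor ("xAT", never a stop); then the
  # published 40-nt 3' anchor whose final two bases overhang the junction.
  mid_len <- cfg$e4_len - 2L - 1L - nchar(ANCHOR_E4_END)
  if (mid_len < 0L || mid_len %% 3L != 0L)
    stopf("locus invariant violated: exon-4 length incompatible with anchored frame layout")
  e4 <- pick("E4", function() {
    paste0("GG", random_codons(mid_len %/% 3L), random_dna(1L), ANCHOR_E4_END)
  })

  # Exon 5a: published 38-nt anchor, then stop-free coding through residue
  # i1_tail_aa of the exon-5a-encoded tail, a TAA stop, then 3' UTR.  The
  # junction codon is AG + E5a[1]; codons restart at E5a position 2.
  stop_start <- 2L + 3L * (cfg$i1_tail_aa - 1L)
  if (cfg$e5a_len < stop_start + 2L)
    stopf("locus invariant violated: exon 5a too short for a %d-aa tail", cfg$i1_tail_aa)
  e5a <- pick("E5a", function() {
    n_mid <- stop_start - 1L - nchar(ANCHOR_E5A_START)  # nt between anchor and stop
    # anchor ends one base into a codon; fill 2 nt to complete it, then codons
    paste0(ANCHOR_E5A_START,
           random_dna(2L),
           random_codons((n_mid - 2L) %/% 3L),
           "TAA",
           random_dna(cfg$e5a_len - stop_start - 2L))
  })

  # Exon 5b: published 40-nt anchor (contains the i2 stop TGA in frame), then
  # unconstrained sequence except that positions 120..134 spell the published
  # 3' end of exon 5bv.
  if (cfg$e5bv_len < nchar(ANCHOR_E5B_START) + nchar(E5BV_END))
    stopf("locus invariant violated: exon 5bv too short to host its anchored ends")
  e5b <- pick("E5b", function() {
    paste0(ANCHOR_E5B_START,
           random_dna(cfg$e5bv_len - nchar(ANCHOR_E5B_START) - nchar(E5BV_END)),
           E5BV_END,
           random_dna(cfg$e5b_len - cfg$e5bv_len))
  })
  if (nchar(e5b) != cfg$e5b_len)
    stopf("locus invariant violated: exon 5b sequence length %d != configured %d",
          nchar(e5b), cfg$e5b_len)

  flank <- pick("flank", function() random_dna(cfg$flank_len))
  if (cfg$ve5d_offset + cfg$novel_exon_len - 1L > cfg$flank_len)
    stopf("locus invariant violated: downstream flank too short to host vE5d")

  introns <- list(
    first = lapply(seq_len(cfg$n_first), function(i) {
      pick(paste0("I1_", i), function() random_dna(cfg$intron_first))
    }),
    i23 = pick("I23", function() random_dna(cfg$intron23)),
    i34 = pick("I34", function() random_dna(cfg$intron34)),
    i4a = pick("I4a", function() random_dna(cfg$intron4a)),
    i5 = pick("I5", function() random_dna(cfg$intron5))
  )

  # Assemble the genome and record coordinates (1-based, inclusive).
  parts <- character(0)
  exons <- list()
  pos <- 1L
  add <- function(seq) {
    parts[[length(parts) + 1L]] <<- seq
    start <- pos
    pos <<- pos + nchar(seq)
    c(start, pos - 1L)
  }
  for (i in seq_len(cfg$n_first)) {
    sp <- add(first_seqs[[i]])
    exons[[first_ids[i]]] <- c(sp, "first")
    add(introns$first[[i]])
  }
  sp <- add(e2); exons[["E2"]] <- c(sp, "common")
  add(introns$i23)
  sp <- add(e3); exons[["E3"]] <- c(sp, "common")
  add(introns$i34)
  sp <- add(e4); exons[["E4"]] <- c(sp, "common")
  add(introns$i4a)
  sp <- add(e5b); exons[["E5b"]] <- c(sp, "variant_terminal")
  exons[["E5bv"]] <- c(sp[1], as.integer(sp[1]) + cfg$e5bv_len - 1L, "variant_terminal")
  add(introns$i5)
  sp <- add(e5a); exons[["E5a"]] <- c(sp, "common")
  e5a_end <- as.integer(sp[2])
  flank_sp <- add(flank)
  exons[["vE5c"]] <- c(e5a_end + cfg$ve5c_offset,
                       e5a_end + cfg$ve5c_offset + cfg$novel_exon_len - 1L, "novel")
  exons[["vE5d"]] <- c(e5a_end + cfg$ve5d_offset,
                       e5a_end + cfg$ve5d_offset + cfg$novel_exon_len - 1L, "novel")

  exon_df <- data.frame(
    exon_id = names(exons),
    start = vapply(exons, function(x) as.integer(x[1]), integer(1)),
    end = vapply(exons, function(x) as.integer(x[2]), integer(1)),
    role = vapply(exons, function(x) x[3], character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  junctions <- data.frame(
    name = c("v1", "v2v3", "v3", NOVEL_CLASSES),
    donor_exon = c("E4", "E4", "E5bv",
                   "E5bv", "E5bv", "E4", "E4", "E4", "E4", "E4", "E2", "E4", "E4"),
    donor_offset = c(0L, 0L, 0L, 8L, 10L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    acceptor_exon = c("E5a", "E5b", "E5a",
                      "E5a", "E5a", "E5b", "E5b", "E5a", "E5a", "E5a", "E5a",
                      "vE5c", "vE5d"),
    acceptor_offset = c(0L, 0L, 0L, 0L, 0L, -14L, 4L, 8L, 18L, 31L, 0L, 0L, 0L),
    class = c(rep("known", 3L), rep("novel", 10L)),
    stringsAsFactors = FALSE
  )

  locus <- structure(list(
    genome = paste(parts, collapse = ""),
    exons = exon_df,
    junctions = junctions,
    first_exons = first_ids,
    atg_offset = cfg$utr5_len + 1L,
    e4_codon_overhang = 2L,
    decoy = NULL,
    config = cfg,
    seed = NA_integer_
  ), class = "ugt_locus")
  locus$decoy <- make_decoy(locus, 2000L)
  locus
}

# A background (non-target) sequence screened to contain none of the probes,
# anchors, or their reverse complements.
make_decoy <- function(locus, len) {
  forbidden <- c(PROBE_V1, PROBE_V2V3, PROBE_V3, unlist(locus_anchors(locus)))
  forbidden <- c(forbidden, revcomp(forbidden))
  for (i in 1:50) {
    d <- random_dna(len)
    if (!any(vapply(forbidden, function(p) grepl(p, d, fixed = TRUE), logical(1))))
      return(d)
  }
  stopf("could not generate a probe-free decoy sequence")
}

#' @export
print.ugt_locus <- function(x, ...) {
  cat(sprintf("UGT1A synthetic locus model (%d nt genome, seed %s)\n",
              nchar(x$genome), x$seed))
  cat(sprintf("  %d first exons; exons: %s\n", length(x$first_exons),
              paste(setdiff(x$exons$exon_id, x$first_exons), collapse = ", ")))
  cat(sprintf("  junctions: %d known, %d novel\n",
              sum(x$junctions$class == "known"), sum(x$junctions$class == "novel")))
  invisible(x)
}

exon_row <- function(locus, exon_id) {
  i <- match(exon_id, locus$exons$exon_id)
  if (is.na(i)) stopf("unknown exon id: %s", exon_id)
  locus$exons[i, ]
}

genome_sub <- function(locus, start, end) {
  if (start < 1L || end > nchar(locus$genome) || end < start)
    stopf("genome coordinates out of range: [%d, %d]", start, end)
  substr(locus$genome, start, end)
}

#' Exon sequence
#' @param locus A `ugt_locus`.
#' @param exon_id Exon identifier (e.g. `"E4"`, `"E5bv"`).
#' @return Character string.
#' @export
exon_seq <- function(locus, exon_id) {
  r <- exon_row(locus, exon_id)
  genome_sub(locus, r$start, r$end)
}

#' Exon-boundary anchor sequences
#'
#' The three boundary anchors used by the discovery workflow, taken from the
#' built locus: the last 40 nt of exon 4, the first 38 nt of exon 5a and the
#' first 40 nt of exon 5b.
#'
#' @param locus A `ugt_locus`.
#' @return Named list with elements `E4_end`, `E5a_start`, `E5b_start`.
#' @export
locus_anchors <- function(locus) {
  e4 <- exon_seq(locus, "E4")
  list(
    E4_end = substr(e4, nchar(e4) - 39L, nchar(e4)),
    E5a_start = substr(exon_seq(locus, "E5a"), 1L, 38L),
    E5b_start = substr(exon_seq(locus, "E5b"), 1L, 40L)
  )
}

# Genomic coordinate of a junction's donor 3' end / acceptor 5' start.
junction_coords <- function(locus, jrow) {
  d <- exon_row(locus, jrow$donor_exon)
  a <- exon_row(locus, jrow$acceptor_exon)
  list(donor_end = d$end + jrow$donor_offset,
       acceptor_start = a$start + jrow$acceptor_offset)
}

# Validate every structural invariant; errors name the violated invariant.
validate_locus <- function(locus) {
  cfg <- locus$config
  ex <- locus$exons
  if (any(ex$end < ex$start))
    stopf("locus invariant violated: exon end < start")
  e5b <- exon_seq(locus, "E5b")
  e5bv <- exon_seq(locus, "E5bv")
  if (e5bv != substr(e5b, 1L, nchar(e5bv)))
    stopf("locus invariant violated: exon 5bv must equal the 5' prefix of exon 5b")
  if (!endsWith(e5bv, E5BV_END))
    stopf("constraint conflict: exon 5bv 3' end does not match probe v3 left arm (expected ...%s)",
          E5BV_END)
  anc <- locus_anchors(locus)
  if (anc$E4_end != ANCHOR_E4_END)
    stopf("constraint conflict: exon-4 3' anchor vs configured exon-4 sequence")
  if (anc$E5a_start != ANCHOR_E5A_START)
    stopf("constraint conflict: exon-5a 5' anchor vs configured exon-5a sequence")
  if (anc$E5b_start != ANCHOR_E5B_START)
    stopf("constraint conflict: exon-5b 5' anchor vs configured exon-5b sequence")
  # The anchored boundaries must reproduce all three published probes.
  probes <- c(v1 = as.character(make_probe(locus, "v1")$sequence),
              v2v3 = as.character(make_probe(locus, "v2v3")$sequence),
              v3 = as.character(make_probe(locus, "v3")$sequence))
  expected <- c(v1 = PROBE_V1, v2v3 = PROBE_V2V3, v3 = PROBE_V3)
  for (nm in names(expected)) {
    if (probes[[nm]] != expected[[nm]])
      stopf("constraint conflict: probe %s derived from exon boundaries (%s) does not match the published probe (%s)",
            nm, probes[[nm]], expected[[nm]])
  }
  if (cds_len_through_e4(cfg) %% 3L != 2L)
    stopf("locus invariant violated: e4_codon_overhang must be 2")
  # i2 stop codon must sit inside exon 5bv (forces v2/v3 ORF identity).
  i2 <- translate_orf(paste0("AG", e5b))
  if (!i2$stop_found || (i2$stop_codon_start - 2L) > nchar(e5bv))
    stopf("locus invariant violated: i2 stop codon must lie within exon 5bv")
  if (nrow(locus$junctions) != 13L)
    stopf("locus invariant violated: junction table must contain 3 known + 10 novel specs")
  invisible(locus)
}

# Every genomic 15-nt flank the discovery classifier keys on must occur
# exactly once in the genome, the anchors themselves must be unique, and no
# two candidate flanks under the same anchor may collide (composite
# junction-spanning flanks are only checked for collisions).  Returns the
# offending sequences (empty when clean).
screen_kmer_uniqueness <- function(locus) {
  cand <- discovery_candidates(locus)
  kmers <- unique(c(cand$expected_flank[cand$genomic],
                    unlist(locus_anchors(locus))))
  n <- vapply(kmers, count_occurrences, integer(1), subject = locus$genome)
  bad <- names(n)[n != 1L]
  dup <- cand$expected_flank[duplicated(paste(cand$anchor_name,
                                              cand$expected_flank))]
  unique(c(bad, dup))
}
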