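# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random DNA of length n (uses the current RNG stream).
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# `n_codons` random codons avoiding stop codons (keeps a designated reading
# frame open).
random_codons <- function(n_codons) {
  if (n_codons <= 0L) return("")
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Count non-overlapping exact occurrences of `pattern` in a single string.
count_occurrences <- function(pattern, subject) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(subject))
}

# Translate an in-frame DNA string up to (not including) the first stop codon.
# Returns list(peptide, stop_found, stop_codon_start) where stop_codon_start is
# the 1-based nt position of the stop codon within `dna` (NA when none).
translate_orf <- function(dna) {
  n_codons <- nchar(dna) %/% 3L
  if (n_codons == 0L) {
    return(list(peptide = "", stop_found = FALSE, stop_codon_start = NA_integer_))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, 3L * n_codons)),
    no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(
      peptide = substr(aa, 1L, stop_at - 1L),
      stop_found = TRUE,
      stop_codon_start = 3L * (as.integer(stop_at) - 1L) + 1L
    )
  } else {
    list(peptide = aa, stop_found = FALSE, stop_codon_start = NA_integer_)
  }
}

# Length of the common prefix of two amino-acid (or any) strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1L]]
  bv <- strsplit(substr(b, 1L, n), "")[[1L]]
  mism <- which(av != bv)
  if (length(mism) == 0L) n else mism[1L] - 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Read a FASTQ (optionally gzipped) file into a DNAStringSet; an empty file
# yields an empty set rather than an error.
read_fastq <- function(path, with_qualities = FALSE) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = with_qualities),
    error = function(e) {
      con <- gzfile(path, "rt")
      on.exit(close(con))
      first <- readLines(con, n = 1L)
      if (length(first) == 0L || !nzchar(trimws(first))) {
        return(Biostrings::DNAStringSet())
      }
      stopf("malformed FASTQ in %s (near record 1): %s", path, conditionMessage(e))
    }
  )
  res
}

# Write reads as FASTQ with constant per-base quality `qual_char`.
write_fastq <- function(sequences, ids, path, qual_char = "?", qualities = NULL) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  if (is.null(qualities)) {
    qualities <- vapply(nchar(sequences), function(n) {
      paste(rep(qual_char, n), collapse = "")
    }, character(1))
  }
  qualities <- stats::setNames(qualities, names(x))
  compress <- grepl("\\.gz$", path)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              compress = compress,
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}
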