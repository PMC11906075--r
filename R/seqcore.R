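#' Sanitize raw sequence text into a canonical DNA string
#'
#' Strips whitespace (spaces, tabs, line breaks), digits and gap characters
#' (`-`), uppercases the remainder and validates it against the unambiguous
#' DNA alphabet `A/C/G/T`. This is the single entry point through which every
#' sequence enters the package; downstream code assumes its output.
#'
#' IUPAC ambiguity codes (including `N`) are rejected: both the
#' nearest-neighbor melting-temperature model and the exact-identity junction
#' overlaps require fully specified bases.
#'
#' @param raw Character scalar of arbitrary sequence text (may contain codon
#'   spacing, line breaks, position numbers from a sequence editor, or `-`
#'   alignment gaps).
#' @param allow_empty Logical; if `FALSE` (default) an empty result is an
#'   error. Deletion and insert segments of a class-2 job may legitimately be
#'   empty and are parsed with `allow_empty = TRUE`.
#' @return Character scalar: uppercase DNA over `{A,C,G,T}`.
#' @examples
#' sanitize_seq("ggt tct cca ggt tct")
#' sanitize_seq("AC\nGT-")
#' @export
sanitize_seq <- function(raw, allow_empty = FALSE) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  s <- toupper(gsub("[[:space:][:digit:]-]", "", raw))
  if (!nzchar(s)) {
    if (allow_empty) return("")
    stop("sequence is empty after removing whitespace, digits and gaps",
         call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    stop(sprintf(
      "invalid character '%s' at position %d: only A/C/G/T are accepted (ambiguity codes are not supported)",
      substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param s Character vector of sanitized DNA strings (empty strings allowed).
#' @return Character vector of the same length, each element the reverse
#'   complement of the input, 5'->3'.
#' @examples
#' revcomp("GGTTCTCCAGGTTCTA")
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s))
  if (length(s) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Translate a DNA string in the three forward frames
#'
#' Frames start at offsets 0, 1 and 2 (labelled `+1`, `+2`, `+3`); any
#' trailing partial codon is dropped and stop codons are rendered `*`.
#' Only forward-strand frames are produced. Uses the standard genetic code.
#'
#' @param s Character scalar, sanitized DNA.
#' @return Named character vector of length 3 (`+1`, `+2`, `+3`); frames
#'   shorter than one codon are empty strings.
#' @examples
#' translate_frames("ATGAAATAA")
#' @export
translate_frames <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  out <- vapply(0:2, function(off) {
    sub <- substr(s, off + 1L, nchar(s))
    w <- (nchar(sub) %/% 3L) * 3L
    if (w == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sub, 1L, w)),
      no.init.codon = TRUE))
  }, character(1))
  names(out) <- c("+1", "+2", "+3")
  out
}
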