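# Input grammars. Class 1 ("vector part-1 + insert + vector part-2") describes
# a chimera: the insert is PCR-amplified with 16-bp vector-derived tails and
# recombined into the PCR-linearized vector. Class 2
# ("upstream * deleted-region * downstream * insert") describes a deletion,
# a small insertion (< 120 bp), or both, on a single circular template.

strip_fasta <- function(raw) {
  stopifnot(is.character(raw))
  raw <- paste(raw, collapse = "\n")
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  header <- NULL
  is_hdr <- grepl("^>", trimws(lines))
  if (any(is_hdr)) {
    if (sum(is_hdr) > 1L)
      stop("multi-record FASTA input is not supported: one construct per job",
           call. = FALSE)
    if (which(is_hdr) != 1L)
      stop("FASTA header must be the first line", call. = FALSE)
    header <- sub("^>", "", trimws(lines[1]))
    lines <- lines[-1]
  }
  body <- paste(lines, collapse = "\n")
  # the printed input convention ends the sequence with a sentence period
  body <- gsub("[.[:space:]]+$", "", body)
  list(header = header, body = body)
}

#' Parse a class-1 (vector + insert chimera) input
#'
#' Expects `vector part-1 + insert + vector part-2`: exactly two `+` markers
#' placing the insert at its destination inside the vector sequence. Input
#' may be plain text or a single-record FASTA (markers inside the body); a
#' trailing `.` and whitespace are ignored. Segments are sanitized with
#' [sanitize_seq()].
#'
#' Size thresholds (inclusive as stated): each vector part >= 40 bp, insert
#' >= 100 bp.
#'
#' @param raw Character scalar (or vector of lines) with the annotated input.
#' @return An object of class `fc_class1`: list with `vector_part1`,
#'   `insert`, `vector_part2`, and a `header` attribute if FASTA.
#' @export
parse_class1 <- function(raw) {
  x <- strip_fasta(raw)
  parts <- strsplit(x$body, "+", fixed = TRUE)[[1]]
  n_marks <- lengths(regmatches(x$body, gregexpr("+", x$body, fixed = TRUE)))
  if (n_marks != 2L)
    stop("class-1 input must contain exactly two '+' markers ",
         "(vector part-1 + insert + vector part-2); found ", n_marks,
         call. = FALSE)
  seqs <- lapply(parts, sanitize_seq)
  out <- list(vector_part1 = seqs[[1]], insert = seqs[[2]],
              vector_part2 = seqs[[3]])
  if (nchar(out$vector_part1) < 40L || nchar(out$vector_part2) < 40L)
    stop("vector part-1 and part-2 must each be >= 40 bp (got ",
         nchar(out$vector_part1), " and ", nchar(out$vector_part2), ")",
         call. = FALSE)
  if (nchar(out$insert) < 100L)
    stop("class-1 insert >= 100 bp required (got ", nchar(out$insert),
         " bp); use class 2 for short insertions", call. = FALSE)
  structure(out, header = x$header, class = "fc_class1")
}

#' Parse a class-2 (deletion / small insertion) input
#'
#' Expects `upstream * deleted-region * downstream * insert`: exactly three
#' `*` markers. An empty deleted region (`**`) makes it a pure insertion; an
#' empty insert (nothing after the third `*`) a pure deletion; both empty is
#' a no-op job and is rejected. The insert must be shorter than 120 bp.
#' The upstream and downstream segments must be long enough to host a
#' cross-junction tail plus the minimum annealing region
#' (`min_anneal_len + 8`).
#'
#' @param raw Character scalar (or vector of lines), plain text or
#'   single-record FASTA.
#' @param min_anneal_len Minimum annealing length the designer will request
#'   from each host segment (default 18).
#' @return An object of class `fc_class2`: list with `upstream`, `deletion`,
#'   `downstream`, `insert`, and a `header` attribute if FASTA.
#' @export
parse_class2 <- function(raw, min_anneal_len = 18L) {
  x <- strip_fasta(raw)
  n_marks <- lengths(regmatches(x$body, gregexpr("*", x$body, fixed = TRUE)))
  if (n_marks != 3L)
    stop("class-2 input must contain exactly three '*' markers ",
         "(upstream * deletion * downstream * insert, segments may be ",
         "empty); found ", n_marks, call. = FALSE)
  parts <- strsplit(paste0(x$body, " "), "*", fixed = TRUE)[[1]]
  out <- list(upstream  = sanitize_seq(parts[1]),
              deletion  = sanitize_seq(parts[2], allow_empty = TRUE),
              downstream = sanitize_seq(parts[3]),
              insert    = sanitize_seq(parts[4], allow_empty = TRUE))
  if (nchar(out$insert) >= 120L)
    stop("class-2 insert must be < 120 bp (got ", nchar(out$insert),
         " bp); use class 1 for large inserts", call. = FALSE)
  if (!nzchar(out$deletion) && !nzchar(out$insert))
    stop("nothing to do: both the deletion and the insert are empty",
         call. = FALSE)
  host_min <- min_anneal_len + 8L
  if (nchar(out$upstream) < host_min || nchar(out$downstream) < host_min)
    stop("upstream and downstream segments must each be >= ", host_min,
         " bp to host a junction tail plus the minimum annealing region",
         call. = FALSE)
  structure(out, header = x$header, class = "fc_class2")
}

#' Render a parsed input back to marker syntax
#'
#' Inverse of the parsers (up to whitespace/case normalization): re-parsing
#' the rendered text yields an identical structure.
#'
#' @param input An `fc_class1` or `fc_class2` object.
#' @return Character scalar in `+`/`*` marker syntax.
#' @export
render_input <- function(input) {
  if (inherits(input, "fc_class1")) {
    paste0(input$vector_part1, "+", input$insert, "+", input$vector_part2)
  } else if (inherits(input, "fc_class2")) {
    paste0(input$upstream, "*", input$deletion, "*", input$downstream, "*",
           input$insert)
  } else {
    stop("input must be an fc_class1 or fc_class2 object", call. = FALSE)
  }
}
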