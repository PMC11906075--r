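# In-silico PCR and assembly verification. The simulator is deliberately
# strict (perfect-match annealing, exact 16-bp junction identity): the
# designer guarantees template identity, so any deviation signals a design
# bug, not a tolerable wobble.

circular_substr <- function(s, start, len) {
  L <- nchar(s)
  substr(paste0(s, s), start, start + len - 1L)
}

find_anneal <- function(anneal, top, circular) {
  hay <- if (circular) paste0(top, substr(top, 1L, nchar(anneal) - 1L))
         else top
  pos <- as.integer(regexpr(anneal, hay, fixed = TRUE))
  if (pos < 1L)
    stop("annealing region '", substr(anneal, 1L, 12L),
         "...' has no exact match on template; the design is inconsistent ",
         "with its template", call. = FALSE)
  pos
}

amplify <- function(template, fwd_tail, fwd_anneal, rev_tail, rev_anneal,
                    circular) {
  L <- nchar(template)
  fs <- find_anneal(fwd_anneal, template, circular)
  rc_r <- revcomp(rev_anneal)
  rs <- find_anneal(rc_r, template, circular)
  re <- rs + nchar(rc_r) - 1L
  if (!circular && re < fs + nchar(fwd_anneal) - 1L)
    stop("primer annealing sites do not define a forward amplicon",
         call. = FALSE)
  span_len <- if (circular) ((re - fs) %% L) + 1L else re - fs + 1L
  paste0(fwd_tail, circular_substr(template, fs, span_len), revcomp(rev_tail))
}

#' Simulate the PCR products of a design
#'
#' Primer-extension arithmetic on the ORIGINAL (unmodified) templates: each
#' amplicon is the forward primer's 5' tail, the top-strand template span
#' from the forward annealing site to the reverse primer's footprint, and
#' the reverse complement of the reverse primer's 5' tail. Annealing is
#' all-or-nothing: an annealing region without an exact template match is a
#' simulation error. Class-1 vector amplification treats the vector as the
#' circle `part2 ++ part1` (the input format carries no backbone between
#' them); the class-2 template `upstream ++ deletion ++ downstream` is
#' likewise circular, so one primer pair amplifies the whole plasmid.
#'
#' @param design An `fc_design` object.
#' @return A tibble with one row per amplicon: `template`, `fwd_primer`,
#'   `rev_primer`, `sequence`.
#' @export
simulate_products <- function(design) {
  stopifnot(inherits(design, "fc_design"))
  pr <- design$primers
  g <- function(name, col) pr[[col]][pr$name == name]
  if (design$mode == "class2") {
    template <- paste0(design$input$upstream, design$input$deletion,
                       design$input$downstream)
    seqs <- amplify(template,
                    g("F", "tail"), g("F", "anneal"),
                    g("R", "tail"), g("R", "anneal"),
                    circular = TRUE)
    tibble::tibble(template = "plasmid", fwd_primer = "F", rev_primer = "R",
                   sequence = seqs)
  } else {
    vec <- amplify(paste0(design$input$vector_part2,
                          design$input$vector_part1),
                   g("VF", "tail"), g("VF", "anneal"),
                   g("VR", "tail"), g("VR", "anneal"),
                   circular = TRUE)
    ins <- amplify(design$input$insert,
                   g("IF", "tail"), g("IF", "anneal"),
                   g("IR", "tail"), g("IR", "anneal"),
                   circular = FALSE)
    tibble::tibble(template = c("vector", "insert"),
                   fwd_primer = c("VF", "IF"), rev_primer = c("VR", "IR"),
                   sequence = c(vec, ins))
  }
}

#' Verify that amplicons assemble into the intended construct
#'
#' Finds the 16-bp terminal identities between amplicon ends, merges the
#' amplicons into a circle (dropping one copy of each shared overlap), and
#' compares the circle — rotation-invariantly — with the intended construct.
#'
#' @param amplicons Tibble from [simulate_products()] or a character vector
#'   of amplicon sequences.
#' @param intended Character scalar: the intended construct (treated as a
#'   circle).
#' @param overlap Junction overlap length in bp (16).
#' @return List of class `fc_verify`: `pass` (logical), `circle` (merged
#'   circular sequence or `NA`), `diagnostics` (character vector; empty on
#'   pass).
#' @export
verify_assembly <- function(amplicons, intended, overlap = 16L) {
  seqs <- if (is.data.frame(amplicons)) amplicons$sequence else amplicons
  stopifnot(length(seqs) >= 1L, is.character(intended))
  fail <- function(...) structure(list(pass = FALSE, circle = NA_character_,
                                       diagnostics = paste0(...)),
                                  class = "fc_verify")
  hd <- function(s) substr(s, 1L, overlap)
  tl <- function(s) substr(s, nchar(s) - overlap + 1L, nchar(s))
  # greedy linear merge on shared 16-bp ends
  pool <- seqs
  while (length(pool) > 1L) {
    merged <- FALSE
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i == j) next
        if (tl(pool[i]) == hd(pool[j])) {
          pool[i] <- paste0(pool[i],
                            substr(pool[j], overlap + 1L, nchar(pool[j])))
          pool <- pool[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged)
      return(fail("no junction: no ", overlap,
                  "-bp identity links the amplicon ends"))
  }
  m <- pool[1]
  if (hd(m) != tl(m))
    return(fail("no junction: merged product ends do not share a ", overlap,
                "-bp identity to circularize"))
  circle <- substr(m, 1L, nchar(m) - overlap)
  if (nchar(circle) != nchar(intended))
    return(fail("length mismatch: assembled circle is ", nchar(circle),
                " bp, intended construct is ", nchar(intended), " bp"))
  if (grepl(intended, paste0(circle, circle), fixed = TRUE))
    return(structure(list(pass = TRUE, circle = circle,
                          diagnostics = character(0)), class = "fc_verify"))
  # align on the intended start, if findable, to report a mismatch position
  anchor <- as.integer(regexpr(hd(intended), paste0(circle, circle),
                               fixed = TRUE))
  if (anchor >= 1L) {
    rot <- circular_substr(circle, anchor, nchar(circle))
    a <- strsplit(rot, "")[[1]]
    b <- strsplit(intended, "")[[1]]
    pos <- which(a != b)[1]
    fail("sequence mismatch at construct position ", pos, ": expected ",
         b[pos], ", assembled ", a[pos])
  } else {
    fail("assembled circle shares no anchor with the intended construct")
  }
}

#' @export
print.fc_verify <- function(x, ...) {
  cat(if (x$pass) "assembly verified: amplicons reproduce the intended construct\n"
      else paste0("assembly FAILED: ", x$diagnostics, "\n"))
  invisible(x)
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a seeded synthetic design case
#'
#' Deterministic for a fixed seed. Bases are uniform with a GC fraction
#' drawn in [0.3, 0.7] so the default Tm window is reachable within the
#' annealing-length bounds. Segment sizes default to comfortably above the
#' grammar thresholds (class-1 parts 120 bp, class-1 insert 150 bp, class-2
#' hosts 120 bp) so that every generated case is designable.
#'
#' @param seed Integer seed.
#' @param mode `"class1"` or `"class2"`.
#' @param insert_len Insert length: class 1 >= 100 (default 150); class 2 in
#'   [0, 120) (default: drawn uniformly in 0..119).
#' @param part_len Class-1 vector part length (>= 40; default 120).
#' @param host_len Class-2 upstream/downstream length (default 120).
#' @param deletion_len Class-2 deleted-region length (default: drawn in
#'   0..30; forced >= 1 when `insert_len` is 0 so the job is not a no-op).
#' @return List of class `fc_case`: `seed`, `mode`, `raw_input`,
#'   `expected_construct`.
#' @export
gen_case <- function(seed, mode = c("class2", "class1"), insert_len = NULL,
                     part_len = 120L, host_len = 120L, deletion_len = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  gc <- stats::runif(1, 0.3, 0.7)
  if (mode == "class1") {
    if (is.null(insert_len)) insert_len <- 150L
    if (insert_len < 100L || part_len < 40L)
      stop("infeasible size parameters: class-1 needs parts >= 40 bp and ",
           "insert >= 100 bp", call. = FALSE)
    p1 <- random_dna(part_len, gc)
    ins <- random_dna(insert_len, gc)
    p2 <- random_dna(part_len, gc)
    raw <- paste0(p1, "+", ins, "+", p2)
    expected <- paste0(p1, ins, p2)
  } else {
    if (is.null(insert_len)) insert_len <- sample(0:119, 1L)
    if (is.null(deletion_len))
      deletion_len <- if (insert_len == 0L) sample(1:30, 1L)
                      else sample(0:30, 1L)
    if (insert_len < 0L || insert_len >= 120L ||
        (insert_len == 0L && deletion_len == 0L) || host_len < 26L)
      stop("infeasible size parameters: class-2 needs insert in [0, 120), ",
           "a non-no-op job and hosts >= 26 bp", call. = FALSE)
    up <- random_dna(host_len, gc)
    del <- random_dna(deletion_len, gc)
    down <- random_dna(host_len, gc)
    ins <- random_dna(insert_len, gc)
    raw <- paste0(up, "*", del, "*", down, "*", ins)
    expected <- paste0(up, ins, down)
  }
  structure(list(seed = seed, mode = mode, raw_input = raw,
                 expected_construct = expected),
            class = "fc_case")
}

#' Write a synthetic case as FASTA fixtures
#'
#' Emits the raw marker input (as a comment-free text record), the
#' unmodified template segments and the expected construct for external
#' inspection.
#'
#' @param case An [gen_case()] result.
#' @param path Output FASTA file path.
#' @return `path`, invisibly.
#' @export
write_case_fasta <- function(case, path) {
  stopifnot(inherits(case, "fc_case"))
  inp <- if (case$mode == "class1") parse_class1(case$raw_input)
         else parse_class2(case$raw_input)
  recs <- c(stats::setNames(unclass(inp)[vapply(unclass(inp), is.character,
                                                logical(1))], names(unclass(inp))),
            list(expected_construct = case$expected_construct))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(recs)) {
    if (!nzchar(recs[[nm]])) next
    writeLines(c(paste0(">", case$mode, "_seed", case$seed, "_", nm),
                 wrap_seq(recs[[nm]])), con)
  }
  invisible(path)
}
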