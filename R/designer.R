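# Core design algorithm. Junctions between PCR fragments are created by 5'
# primer tails so that, after amplification, the two fragment ends (class 1)
# or the two ends of the single whole-plasmid amplicon (class 2) share
# exactly 16 identical bases, which direct the in-vivo recombination.

#' Junction-window geometry for a class-2 design
#'
#' Computes how the fixed 16-bp complementary overlap between the forward
#' and reverse primer is laid out around an insert of length `Li` at the
#' deletion/insertion junction:
#' \itemize{
#'  \item `Li < 16`: the insert alone cannot provide 16 bases, so the window
#'    recruits `u = floor((16-Li)/2)` upstream and `d = ceil((16-Li)/2)`
#'    downstream flanking bases (the odd base goes downstream). Forward tail
#'    length `k_f = u + Li`, reverse tail length `k_r = Li + d`.
#'  \item `Li >= 16`: the window sits entirely inside the insert, offset
#'    `s = ceil((Li-16)/2)` from its 5' end (the odd base toward 5').
#'    `k_f = Li - s`, `k_r = s + 16`.
#'  \item `Li = 0` (pure deletion): degenerates to symmetric 8+8 cross-tails.
#' }
#' In every case `k_f + k_r - Li = 16`: the primers share exactly 16
#' complementary construct bases.
#'
#' @param Li Insert length in bp, `0 <= Li < 120`.
#' @param overlap Overlap length in bp (fixed at 16 by the method; exposed
#'   for power users).
#' @return Named list with `O`, `Li`, `u`, `d`, `s`, `k_f`, `k_r`.
#' @export
overlap_window <- function(Li, overlap = 16L) {
  Li <- as.integer(Li)
  stopifnot(length(Li) == 1L, !is.na(Li), overlap >= 2L)
  if (Li < 0L || Li >= 120L)
    stop("class-2 insert length must be in [0, 120) bp; got ", Li,
         call. = FALSE)
  if (Li < overlap) {
    u <- (overlap - Li) %/% 2L
    d <- overlap - Li - u
    s <- 0L
  } else {
    u <- d <- 0L
    s <- as.integer(ceiling((Li - overlap) / 2))
  }
  # closed forms covering both branches: Li<O gives (u+Li, Li+d) since
  # u+Li+d = O; Li>=O gives (Li-s, s+O) since u = 0
  list(O = as.integer(overlap), Li = Li, u = u, d = d, s = s,
       k_f = u + Li - s, k_r = s + as.integer(overlap) - u)
}

#' Grow an annealing region until its Tm enters the requested window
#'
#' Starting from `min_len`, extends one base at a time along the sense-strand
#' template and returns the first length whose nearest-neighbor Tm reaches
#' the lower bound. If that first-crossing Tm also exceeds the upper bound
#' (a single GC-rich base can jump the whole window) the region is returned
#' with an overshoot warning rather than failing: the method always emits a
#' primer. Reverse primers pass their template in sense orientation and
#' reverse-complement the result once, at primer construction.
#'
#' @param template Sense-strand template text. For `direction = "right"` the
#'   anneal is a prefix of `template` (extension 5'->3' into it); for
#'   `"left"` it is a suffix (extension leftward from the template's 3' end).
#' @param direction `"right"` or `"left"`.
#' @param range A [tm_range()].
#' @param params A [tm_params()].
#' @param min_len,max_len Annealing-length bounds (default 18-60 nt, which
#'   brackets any primer a practitioner would order). Extension clips at the
#'   template end if the template is shorter than `max_len`.
#' @return List with `anneal` (sense strand), `tm` (deg C) and `warning`
#'   (`NULL` or an overshoot message).
#' @export
extend_anneal <- function(template, direction = c("right", "left"),
                          range = tm_range(), params = tm_params(),
                          min_len = 18L, max_len = 60L) {
  direction <- match.arg(direction)
  stopifnot(inherits(range, "tm_range"), min_len >= 6L, max_len >= min_len)
  w <- nchar(template)
  if (w < min_len)
    stop("template (", w, " bp) is shorter than the minimum annealing ",
         "length (", min_len, " nt)", call. = FALSE)
  n_max <- min(max_len, w)
  for (n in min_len:n_max) {
    s <- if (direction == "right") substr(template, 1L, n)
         else substr(template, w - n + 1L, w)
    tm <- tm_nn(s, params)
    if (tm >= range$lo) {
      warn <- NULL
      if (tm > range$hi)
        warn <- sprintf(
          "annealing Tm %.2f degC overshoots the %.0f-%.0f degC window at the first length (%d nt) reaching the floor",
          tm, range$lo, range$hi, n)
      return(list(anneal = s, tm = tm, warning = warn))
    }
  }
  stop(sprintf(
    "cannot reach Tm >= %.1f degC within %d nt of template (Tm at full extension: %.2f degC)",
    range$lo, n_max, tm), call. = FALSE)
}

new_design <- function(mode, primers, input, construct, range, params,
                       min_anneal_len, max_anneal_len, warnings) {
  primers$sequence <- paste0(primers$tail, primers$anneal)
  primers$length <- nchar(primers$sequence)
  primers <- primers[, c("name", "tail", "anneal", "sequence", "length",
                         "tm_anneal")]
  structure(list(
    mode = mode,
    primers = primers,
    construct = construct,
    translations = translate_frames(construct),
    warnings = warnings,
    input_echo = render_input(input),
    input = input,
    tm_range = range,
    tm_params = params,
    config = list(min_anneal_len = min_anneal_len,
                  max_anneal_len = max_anneal_len, overlap_length = 16L)
  ), class = "fc_design")
}

#' Design the four class-1 primers (vector + insert chimera)
#'
#' The vector is linearized with plain primers `VF` (5' end of vector
#' part-2, rightward) and `VR` (reverse complement of an annealing region
#' ending at the 3' end of vector part-1). The insert primers carry the
#' junction overlaps: `IF` = last 16 bases of vector part-1 as 5' tail +
#' annealing region from the insert's 5' end; `IR` = reverse complement of
#' (insert 3'-terminal annealing region ++ first 16 bases of vector part-2),
#' i.e. its 5' tail is the reverse complement of vector part-2's first 16
#' bases. Each insert amplicon end is thereby identical to 16 bases of the
#' linearized vector's ends.
#'
#' @param input An [parse_class1()] result.
#' @param range A [tm_range()]; annealing regions are grown until their Tm
#'   reaches `range$lo` (see [extend_anneal()]).
#' @param params A [tm_params()].
#' @param min_anneal_len,max_anneal_len Annealing-length bounds.
#' @return An `fc_design` object; see [tidy.fc_design()] for the primer
#'   table.
#' @export
design_class1 <- function(input, range = tm_range(), params = tm_params(),
                          min_anneal_len = 18L, max_anneal_len = 60L) {
  stopifnot(inherits(input, "fc_class1"))
  p1 <- input$vector_part1; ins <- input$insert; p2 <- input$vector_part2
  ext <- function(template, direction)
    extend_anneal(template, direction, range, params, min_anneal_len,
                  max_anneal_len)
  vf <- ext(p2, "right")
  vr <- ext(p1, "left")
  if_ <- ext(ins, "right")
  ir <- ext(ins, "left")
  tail_if <- substr(p1, nchar(p1) - 15L, nchar(p1))
  tail_ir <- revcomp(substr(p2, 1L, 16L))
  primers <- tibble::tibble(
    name = c("VF", "VR", "IF", "IR"),
    tail = c("", "", tail_if, tail_ir),
    anneal = c(vf$anneal, revcomp(vr$anneal), if_$anneal,
               revcomp(ir$anneal)),
    tm_anneal = c(vf$tm, vr$tm, if_$tm, ir$tm))
  warnings <- collect_warnings(primers$name,
                               list(vf$warning, vr$warning, if_$warning,
                                    ir$warning))
  new_design("class1", primers, input, assemble_construct(input), range,
             params, min_anneal_len, max_anneal_len, warnings)
}

#' Design the class-2 primer pair (deletion and/or small insertion)
#'
#' On the intended construct `upstream ++ insert ++ downstream` (deletion
#' excised), with the insert at positions `p..q` and window `w =
#' overlap_window(Li)`: the forward primer is the `k_f`-base construct
#' stretch ending at `q` (its 5' tail, spanning the junction) followed by an
#' annealing region grown into the downstream segment; the reverse primer is
#' the reverse complement of (upstream annealing region ending at `p-1` ++
#' the `k_r`-base construct stretch starting at `p`). The two primers share
#' exactly 16 complementary construct bases; whole-plasmid PCR then yields a
#' linear product whose ends carry that 16-bp redundancy.
#'
#' @inheritParams design_class1
#' @param input An [parse_class2()] result.
#' @return An `fc_design` object with primers `F` and `R`.
#' @export
design_class2 <- function(input, range = tm_range(), params = tm_params(),
                          min_anneal_len = 18L, max_anneal_len = 60L) {
  stopifnot(inherits(input, "fc_class2"))
  up <- input$upstream; ins <- input$insert; down <- input$downstream
  Li <- nchar(ins)
  w <- overlap_window(Li)
  cseq <- paste0(up, ins, down)
  p <- nchar(up) + 1L
  q <- nchar(up) + Li
  tail_f_sense <- substr(cseq, p - w$u + w$s, q)          # k_f bases, ends at q
  tail_r_sense <- substr(cseq, p, p - 1L + w$k_r)         # k_r bases, starts at p
  fx <- extend_anneal(substr(cseq, q + 1L, nchar(cseq)), "right", range,
                      params, min_anneal_len, max_anneal_len)
  rx <- extend_anneal(substr(cseq, 1L, p - 1L), "left", range, params,
                      min_anneal_len, max_anneal_len)
  primers <- tibble::tibble(
    name = c("F", "R"),
    tail = c(tail_f_sense, revcomp(tail_r_sense)),
    anneal = c(fx$anneal, revcomp(rx$anneal)),
    tm_anneal = c(fx$tm, rx$tm))
  warnings <- collect_warnings(primers$name, list(fx$warning, rx$warning))
  new_design("class2", primers, input, cseq, range, params, min_anneal_len,
             max_anneal_len, warnings)
}

collect_warnings <- function(names, warns) {
  keep <- !vapply(warns, is.null, logical(1))
  if (!any(keep)) return(character(0))
  paste0(names[keep], ": ", unlist(warns[keep]))
}

#' Assemble the intended construct sequence
#'
#' Class 1: `vector_part1 ++ insert ++ vector_part2`. Class 2: `upstream ++
#' insert ++ downstream` with the deleted region excised (pure deletion:
#' `upstream ++ downstream`).
#'
#' @param input An `fc_class1` or `fc_class2` object.
#' @return Character scalar, the construct sequence.
#' @export
assemble_construct <- function(input) {
  if (inherits(input, "fc_class1"))
    paste0(input$vector_part1, input$insert, input$vector_part2)
  else if (inherits(input, "fc_class2"))
    paste0(input$upstream, input$insert, input$downstream)
  else stop("input must be an fc_class1 or fc_class2 object", call. = FALSE)
}

longest_affix_match <- function(suffix_of, prefix_of) {
  kmax <- min(nchar(suffix_of), nchar(prefix_of))
  for (k in rev(seq_len(kmax))) {
    if (substr(suffix_of, nchar(suffix_of) - k + 1L, nchar(suffix_of)) ==
        substr(prefix_of, 1L, k))
      return(k)
  }
  0L
}

#' Measure the realized junction overlaps of a design
#'
#' Recomputes, purely by string matching against the construct and vector
#' parts (independently of the designer's stored window geometry), how many
#' bases each junction actually shares.
#'
#' For a class-2 design: maps the forward primer and the reverse complement
#' of the reverse primer onto the construct and returns the length of the
#' contiguous stretch covered by both (named `FR`). For class 1: returns the
#' longest suffix of vector part-1 appearing as a prefix of `IF` (named
#' `IF`) and the longest prefix of vector part-2 whose reverse complement
#' ends... equivalently, the longest suffix of `revcomp(IR)` matching the
#' start of vector part-2 (named `IR`).
#'
#' @param design An `fc_design` object.
#' @return Named integer vector of overlap lengths in bp.
#' @export
junction_overlap <- function(design) {
  stopifnot(inherits(design, "fc_design"))
  pr <- design$primers
  if (design$mode == "class2") {
    cseq <- design$construct
    f <- pr$sequence[pr$name == "F"]
    r_fp <- revcomp(pr$sequence[pr$name == "R"])
    fs <- as.integer(regexpr(f, cseq, fixed = TRUE))
    rs <- as.integer(regexpr(r_fp, cseq, fixed = TRUE))
    if (fs < 1L || rs < 1L)
      stop("primer footprint not found on the construct", call. = FALSE)
    ov <- min(fs + nchar(f), rs + nchar(r_fp)) - max(fs, rs)
    c(FR = max(ov, 0L))
  } else {
    p1 <- design$input$vector_part1
    p2 <- design$input$vector_part2
    c(IF = longest_affix_match(p1, pr$sequence[pr$name == "IF"]),
      IR = longest_affix_match(revcomp(pr$sequence[pr$name == "IR"]), p2))
  }
}
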