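wrap_seq <- function(s, width = 70L) {
  if (!nzchar(s)) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

cased_sequence <- function(tail, anneal, lowercase_tails = TRUE) {
  if (lowercase_tails) paste0(tolower(tail), toupper(anneal))
  else paste0(tail, anneal)
}

#' Format a design as a plain-text report
#'
#' Deterministic layout: primers in stable order (VF, VR, IF, IR for class
#' 1; F, R for class 2) with Tm to two decimals and lengths in nt, the
#' construct as 70-column FASTA, the three forward-frame translations, the
#' input echo and the configuration. A WARNINGS section appears only when
#' there are warnings. Identical inputs and configuration give
#' byte-identical reports; an optional timestamp line is off by default for
#' that reason.
#'
#' @param design An `fc_design` object.
#' @param lowercase_tails Render 5' tails lowercase and annealing regions
#'   uppercase (the usual visual convention for tailed primers).
#' @param timestamp Include a generation timestamp (breaks byte-identical
#'   reproducibility; default `FALSE`).
#' @return Character vector of report lines.
#' @export
format_report <- function(design, lowercase_tails = TRUE, timestamp = FALSE) {
  stopifnot(inherits(design, "fc_design"))
  pr <- design$primers
  tp <- design$tm_params
  seq_col <- cased_sequence(pr$tail, pr$anneal, lowercase_tails)
  tab <- sprintf("%-4s %4d nt  Tm %6.2f C  5'-%s-3'",
                 pr$name, pr$length, pr$tm_anneal, seq_col)
  hdr <- attr(design$input, "header")
  lines <- c(
    "LIGATION-INDEPENDENT CLONING PRIMER DESIGN REPORT",
    "==================================================",
    "",
    paste0("Mode: ", design$mode,
           if (design$mode == "class1") " (vector + insert chimera)"
           else " (deletion / small insertion)"),
    if (timestamp) paste0("Generated: ", format(Sys.time(), tz = "UTC",
                                                usetz = TRUE)),
    sprintf("Tm window: %.1f-%.1f degC (annealing regions only)",
            design$tm_range$lo, design$tm_range$hi),
    sprintf(paste0("Config: min_anneal_len=%d, max_anneal_len=%d, ",
                   "overlap_length=%d"),
            design$config$min_anneal_len, design$config$max_anneal_len,
            design$config$overlap_length),
    sprintf(paste0("        monovalent_mM=%g, divalent_mM=%g, dNTP_mM=%g, ",
                   "primer_nM=%g, template_nM=%g"),
            tp$monovalent_mM, tp$divalent_mM, tp$dNTP_mM, tp$primer_nM,
            tp$template_nM),
    "",
    "PRIMERS (5' tail in lowercase, annealing region uppercase)",
    "----------------------------------------------------------",
    tab,
    "",
    sprintf("CONSTRUCT (%d bp)", nchar(design$construct)),
    "---------",
    paste0(">", if (!is.null(hdr)) hdr else "construct"),
    wrap_seq(design$construct),
    "",
    "TRANSLATIONS (forward frames, stop codons as *)",
    "------------",
    unlist(lapply(c("+1", "+2", "+3"), function(f)
      c(paste0("frame ", f, ":"),
        if (nzchar(design$translations[[f]]))
          wrap_seq(design$translations[[f]]) else "(empty)"))),
    "",
    "INPUT (as provided, after cleanup)",
    "-----",
    wrap_seq(design$input_echo, width = 70L)
  )
  if (length(design$warnings)) {
    lines <- c(lines, "", "WARNINGS", "--------",
               paste0("- ", design$warnings))
  }
  lines
}

#' Write the design report to a text file
#'
#' @inheritParams format_report
#' @param path Destination file (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_report <- function(design, path, lowercase_tails = TRUE,
                         timestamp = FALSE) {
  lines <- format_report(design, lowercase_tails, timestamp)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the assembled construct as FASTA
#'
#' @param design An `fc_design` object.
#' @param path Destination FASTA file.
#' @param header Record header; defaults to the input FASTA header if one
#'   was provided, else `construct`.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(design, path, header = NULL) {
  stopifnot(inherits(design, "fc_design"))
  if (is.null(header)) {
    header <- attr(design$input, "header")
    if (is.null(header)) header <- "construct"
  }
  writeLines(c(paste0(">", header), wrap_seq(design$construct)), path)
  invisible(path)
}

#' Serialize a design to JSON
#'
#' Schema-stable machine-readable mirror of the report: mode, primer table,
#' construct, translations, warnings, input echo and configuration.
#'
#' @param design An `fc_design` object.
#' @param path Optional destination; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "fc_design"))
  x <- list(
    mode = design$mode,
    primers = as.data.frame(design$primers),
    construct = design$construct,
    translations = as.list(design$translations),
    warnings = as.list(design$warnings),
    input_echo = design$input_echo,
    config = c(design$config,
               unclass(design$tm_params),
               list(tm_lo = design$tm_range$lo, tm_hi = design$tm_range$hi))
  )
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild a design object from its JSON serialization
#'
#' Reconstructs enough of an `fc_design` (primers, parsed input, construct,
#' configuration) to re-run [simulate_products()] and [verify_assembly()]
#' on a previously saved result.
#'
#' @param path JSON file written by [design_to_json()].
#' @return An `fc_design` object.
#' @export
design_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  input <- if (identical(x$mode, "class1")) parse_class1(x$input_echo)
           else parse_class2(x$input_echo)
  structure(list(
    mode = x$mode,
    primers = tibble::as_tibble(x$primers),
    construct = x$construct,
    translations = unlist(x$translations),
    warnings = as.character(unlist(x$warnings)),
    input_echo = x$input_echo,
    input = input,
    tm_range = tm_range(x$config$tm_lo, x$config$tm_hi),
    tm_params = tm_params(x$config$monovalent_mM, x$config$divalent_mM,
                          x$config$dNTP_mM, x$config$primer_nM,
                          x$config$template_nM),
    config = list(min_anneal_len = x$config$min_anneal_len,
                  max_anneal_len = x$config$max_anneal_len,
                  overlap_length = x$config$overlap_length)
  ), class = "fc_design")
}
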