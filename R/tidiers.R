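#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the primer set of a design
#'
#' @param x An `fc_design` object.
#' @param ... Unused.
#' @return A tibble with one row per primer: `name`, `tail`, `anneal`,
#'   `sequence`, `length`, `tm_anneal`.
#' @method tidy fc_design
#' @export
tidy.fc_design <- function(x, ...) {
  x$primers
}

#' One-row summary of a design
#'
#' @param x An `fc_design` object.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `n_primers`, `construct_length`,
#'   `tm_min`, `tm_max`, `overlap_length`, `n_warnings`.
#' @method glance fc_design
#' @export
glance.fc_design <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_primers = nrow(x$primers),
    construct_length = nchar(x$construct),
    tm_min = min(x$primers$tm_anneal),
    tm_max = max(x$primers$tm_anneal),
    overlap_length = x$config$overlap_length,
    n_warnings = length(x$warnings))
}

#' @export
print.fc_design <- function(x, ...) {
  cat(sprintf("<fc_design> %s | %d primers | construct %d bp | Tm window %.0f-%.0f degC\n",
              x$mode, nrow(x$primers), nchar(x$construct), x$tm_range$lo,
              x$tm_range$hi))
  pr <- x$primers
  cat(sprintf("  %-4s %3d nt  Tm %6.2f C  %s\n", pr$name, pr$length,
              pr$tm_anneal, cased_sequence(pr$tail, pr$anneal)), sep = "")
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

primer_footprints <- function(design) {
  pr <- design$primers
  cseq <- design$construct
  strand <- ifelse(pr$name %in% c("F", "VF", "IF"), "+", "-")
  start <- integer(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    probe <- if (strand[i] == "+") pr$sequence[i] else revcomp(pr$sequence[i])
    start[i] <- as.integer(regexpr(probe, cseq, fixed = TRUE))
  }
  tibble::tibble(name = pr$name, strand = strand, start = start,
                 end = start + pr$length - 1L, tm_anneal = pr$tm_anneal)
}

#' Primer map of a design
#'
#' Draws each primer as an arrow over its footprint on the assembled
#' construct (reverse primers on the bottom strand), colored by annealing
#' Tm. Class-1 vector primers point outward from the insert, as they
#' amplify the vector circle.
#'
#' @param object An `fc_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_design
#' @export
autoplot.fc_design <- function(object, ...) {
  fp <- primer_footprints(object)
  fp <- fp[fp$start > 0L, , drop = FALSE]
  fp$y <- ifelse(fp$strand == "+", 1, -1)
  fp$x <- ifelse(fp$strand == "+", fp$start, fp$end)
  fp$xend <- ifelse(fp$strand == "+", fp$end, fp$start)
  ggplot2::ggplot(fp) +
    ggplot2::annotate("segment", x = 1, xend = nchar(object$construct),
                      y = 0, yend = 0, linewidth = 1.2, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y, colour = .data$tm_anneal),
      linewidth = 2, arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                            type = "closed")) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = .data$y * 1.4, label = .data$name),
                       size = 3) +
    ggplot2::scale_colour_viridis_c(name = "annealing Tm (degC)") +
    ggplot2::scale_y_continuous(limits = c(-2, 2), breaks = NULL) +
    ggplot2::labs(x = "construct position (bp)", y = NULL,
                  title = sprintf("%s primer map (%d bp construct)",
                                  object$mode, nchar(object$construct))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
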