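# Unified nearest-neighbor duplex thermodynamics (Allawi & SantaLucia 1997
# DNA/DNA stacking table; SantaLucia 1998 entropy salt correction). dH in
# kcal/mol, dS in cal/(mol K). The ten unique stacks are expanded to all 16
# dinucleotides via the complementary-stack identity so lookups never need a
# reverse-complement branch.
.nn_unified <- local({
  dh10 <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
            "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0)
  ds10 <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7,
            "GT" = -22.4, "CT" = -21.0, "GA" = -22.2, "CG" = -27.2,
            "GC" = -24.4, "GG" = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc2 <- function(p) paste0(comp[substr(p, 2, 2)], comp[substr(p, 1, 1)])
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  dh <- ds <- stats::setNames(numeric(16), all16)
  for (p in all16) {
    key <- if (p %in% names(dh10)) p else rc2(p)
    dh[p] <- dh10[[key]]
    ds[p] <- ds10[[key]]
  }
  list(dh = dh, ds = ds,
       # terminal initiation corrections, per duplex end
       init_dh = c(AT = 2.3, GC = 0.1), init_ds = c(AT = 4.1, GC = -2.8))
})

#' Thermodynamic parameters for melting-temperature calculation
#'
#' Defaults mirror the widely used sequence-utilities melting-temperature
#' routine: unified nearest-neighbor table, 25 nM primer and 25 nM template,
#' 50 mM monovalent cation, no divalents or dNTPs, and the SantaLucia (1998)
#' entropy salt correction `dS + 0.368 (N-1) ln[Mon+]`.
#'
#' Divalent cations are folded into the effective monovalent concentration as
#' `120 * sqrt(max(Mg - dNTP, 0))` (von Ahsen's approximation) so a PCR-like
#' buffer can be described without a separate correction mode.
#'
#' @param monovalent_mM Monovalent cation concentration (Na+ equivalents), mM.
#' @param divalent_mM Divalent cation (Mg2+) concentration, mM.
#' @param dNTP_mM Total dNTP concentration, mM (chelates Mg2+).
#' @param primer_nM Primer strand concentration, nM (must be > 0).
#' @param template_nM Template strand concentration, nM.
#' @return An object of class `tm_params` (a named list).
#' @export
tm_params <- function(monovalent_mM = 50, divalent_mM = 0, dNTP_mM = 0,
                      primer_nM = 25, template_nM = 25) {
  stopifnot(monovalent_mM >= 0, divalent_mM >= 0, dNTP_mM >= 0,
            primer_nM > 0, template_nM >= 0)
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 dNTP_mM = dNTP_mM, primer_nM = primer_nM,
                 template_nM = template_nM),
            class = "tm_params")
}

#' Melting-temperature range targeted by the designer
#'
#' @param lo,hi Inclusive bounds in degrees Celsius; default 55-65.
#' @return An object of class `tm_range`.
#' @export
tm_range <- function(lo = 55, hi = 65) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(lo = lo, hi = hi), class = "tm_range")
}

#' Nearest-neighbor melting temperature of a primer-template duplex
#'
#' Sums unified nearest-neighbor dH/dS stacking contributions plus terminal
#' initiation terms, applies the entropy salt correction, and converts to Tm
#' via `Tm = 1000 dH / (dS + R ln(CT)) - 273.15` with `R = 1.987`
#' cal/(mol K) and `CT = (primer - template/2) 1e-9` mol/L, the excess-primer
#' convention for non-self-complementary duplexes.
#'
#' @param s Character vector of DNA sequences (each >= 6 nt; the model is
#'   unreliable below that).
#' @param params A [tm_params()] object.
#' @return Numeric vector of melting temperatures, degrees Celsius.
#' @examples
#' tm_nn("ACGTACGTACGTACGTACGT")
#' @export
tm_nn <- function(s, params = tm_params()) {
  stopifnot(is.character(s), inherits(params, "tm_params"))
  vapply(s, tm_nn1, numeric(1), params = params, USE.NAMES = FALSE)
}

tm_nn1 <- function(s, params) {
  n <- nchar(s)
  if (n < 6L)
    stop("sequence of length ", n,
         " is below the 6-nt minimum for the nearest-neighbor model",
         call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop("tm_nn requires a sanitized A/C/G/T sequence", call. = FALSE)
  tab <- .nn_unified
  ends <- ifelse(c(substr(s, 1L, 1L), substr(s, n, n)) %in% c("A", "T"),
                 "AT", "GC")
  dh <- sum(tab$init_dh[ends])
  ds <- sum(tab$init_ds[ends])
  stacks <- substring(s, 1:(n - 1L), 2:n)
  dh <- dh + sum(tab$dh[stacks])
  ds <- ds + sum(tab$ds[stacks])
  mon <- params$monovalent_mM +
    120 * sqrt(max(params$divalent_mM - params$dNTP_mM, 0))
  if (mon <= 0)
    stop("effective monovalent cation concentration must be positive",
         call. = FALSE)
  ds <- ds + 0.368 * (n - 1L) * log(mon / 1000)
  ct <- (params$primer_nM - params$template_nM / 2) * 1e-9
  if (ct <= 0)
    stop("primer concentration must exceed half the template concentration",
         call. = FALSE)
  1000 * dh / (ds + 1.987 * log(ct)) - 273.15
}
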