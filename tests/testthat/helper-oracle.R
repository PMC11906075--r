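# Independent oracles, deliberately coded apart from the package internals.

# Reverse complement via base R only.
oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    if (!nzchar(x)) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Unified nearest-neighbor Tm, transcribed directly from the published
# parameter set (all 16 dinucleotide stacks written out; terminal A/T and
# G/C initiation corrections; entropy salt correction 0.368 (N-1) ln[Mon+];
# total strand concentration CT = (primer - template/2) nM).
oracle_tm <- function(s, mon_M = 0.05, primer_nM = 25, template_nM = 25) {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  vapply(s, function(x) {
    n <- nchar(x)
    b <- strsplit(x, "")[[1]]
    pairs <- paste0(b[-n], b[-1])
    H <- sum(dH[pairs])
    S <- sum(dS[pairs])
    for (end in b[c(1, n)]) {
      if (end %in% c("A", "T")) { H <- H + 2.3; S <- S + 4.1 }
      else { H <- H + 0.1; S <- S - 2.8 }
    }
    S <- S + 0.368 * (n - 1) * log(mon_M)
    ct <- (primer_nM - template_nM / 2) * 1e-9
    1000 * H / (S + 1.987 * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Seeded random DNA for property tests (independent of gen_case).
oracle_random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
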