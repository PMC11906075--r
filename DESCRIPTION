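Package: licprimers
Title: Primer Design for Ligation-Independent (FastCloning-Style) PCR Cloning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs primers for restriction- and ligation-independent PCR
    cloning in which vector and insert (or a template carrying a deletion
    and/or a small insertion) are amplified with primers bearing mutually
    complementary 16-bp terminal overlaps. Parses marker-annotated construct
    sequences, sizes annealing regions with a unified nearest-neighbor
    melting-temperature model, builds the primer sets for vector+insert
    chimeras and for deletion/insertion mutagenesis, and verifies every
    design with an in-silico PCR and overlap-assembly simulation. Emits a
    plain-text report, construct FASTA, three-frame translations and
    machine-readable JSON, from R or from a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
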