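# Worked inputs reproduced from the installed example fixtures, shared
# across test files.

read_example <- function(name) {
  paste(readLines(system.file("extdata", name, package = "licprimers"),
                  warn = FALSE), collapse = "\n")
}

example_class1_raw <- function() read_example("class1_example.txt")
example_class2_raw <- function() read_example("class2_del_ins.txt")
example_insertion_raw <- function() read_example("class2_insertion_only.txt")
example_deletion_raw <- function() read_example("class2_deletion_only.txt")

example_linkers <- function() {
  read.delim(system.file("extdata", "linkers.tsv", package = "licprimers"),
             stringsAsFactors = FALSE)
}

example_published_primers <- function() {
  read.delim(system.file("extdata", "published_primers.tsv",
                         package = "licprimers"), stringsAsFactors = FALSE)
}

# Class-2 input for the deletion of the TAA stop codon after ...AAACAAATGACT,
# built from the deletion+insertion example's unmodified template.
stop_deletion_raw <- function() {
  inp <- parse_class2(example_class2_raw())
  full <- paste0(inp$upstream, inp$deletion, inp$downstream)
  paste0(sub("AAACAAATGACTTAACTCGAG", "AAACAAATGACT*TAA*CTCGAG", full,
             fixed = TRUE), "*")
}

# Deletion+insertion input with the L0 linker replaced by another linker.
linker_swap_raw <- function(linker_seq) {
  inp <- parse_class2(example_class2_raw())
  paste0(inp$upstream, "*", inp$deletion, "*", inp$downstream, "*",
         linker_seq)
}
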