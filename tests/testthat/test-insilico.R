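test_that("class-2 whole-plasmid PCR yields one amplicon with 16-bp terminal redundancy", {
  inp <- parse_class2(example_class2_raw())
  d <- design_class2(inp)
  amps <- simulate_products(d)
  expect_identical(nrow(amps), 1L)
  a <- amps$sequence
  pr <- tidy(d)
  expect_true(startsWith(a, pr$sequence[pr$name == "F"]))
  expect_true(endsWith(a, revcomp(pr$sequence[pr$name == "R"])))
  expect_identical(substr(a, 1, 16),
                   substr(a, nchar(a) - 15, nchar(a)))
  # the amplicon is the plasmid minus the deletion, plus the redundancy
  expect_identical(nchar(a), nchar(assemble_construct(inp)) + 16L)
})

test_that("class-1 PCR yields two amplicons with pairwise 16-bp end identities", {
  inp <- parse_class1(example_class1_raw())
  amps <- simulate_products(design_class1(inp))
  expect_identical(nrow(amps), 2L)
  vec <- amps$sequence[amps$template == "vector"]
  ins <- amps$sequence[amps$template == "insert"]
  expect_identical(substr(vec, nchar(vec) - 15, nchar(vec)),
                   substr(ins, 1, 16))
  expect_identical(substr(ins, nchar(ins) - 15, nchar(ins)),
                   substr(vec, 1, 16))
})

test_that("a mutated annealing base is a simulation error, not a silent pass", {
  d <- design_class2(parse_class2(example_class2_raw()))
  a <- d$primers$anneal[1]
  base <- substr(a, 5, 5)
  substr(a, 5, 5) <- setdiff(c("A", "C", "G", "T"), base)[1]
  d$primers$anneal[1] <- a
  expect_error(simulate_products(d), "no exact match")
})

test_that("assembly verification passes on correct designs and localizes corruption", {
  inp <- parse_class2(example_class2_raw())
  d <- design_class2(inp)
  amps <- simulate_products(d)
  intended <- assemble_construct(inp)
  expect_true(verify_assembly(amps, intended)$pass)
  # corrupt each base of the 5' junction copy in turn: every flip must fail
  a <- amps$sequence
  for (pos in 1:16) {
    bad <- a
    substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(a, pos, pos))[1]
    v <- verify_assembly(bad, intended)
    expect_false(v$pass)
    expect_match(v$diagnostics, "junction|mismatch|length")
  }
  # a corrupted internal base fails with a positional diagnostic
  mid <- a
  substr(mid, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                   substr(a, 200, 200))[1]
  v <- verify_assembly(mid, intended)
  expect_false(v$pass)
  expect_match(v$diagnostics, "position")
})

test_that("verification is rotation-invariant for the circular product", {
  inp <- parse_class1(example_class1_raw())
  d <- design_class1(inp)
  amps <- simulate_products(d)
  # intended construct starts at part1, amplicons start at part2: still a pass
  expect_true(verify_assembly(amps, assemble_construct(inp))$pass)
})

test_that("synthetic cases are deterministic and respect size thresholds", {
  a <- gen_case(1, "class2")
  b <- gen_case(1, "class2")
  expect_identical(a$raw_input, b$raw_input)
  expect_identical(parse_class2(a$raw_input)$insert,
                   parse_class2(b$raw_input)$insert)
  edge <- gen_case(2, "class2", insert_len = 119)
  expect_identical(nchar(parse_class2(edge$raw_input)$insert), 119L)
  expect_error(gen_case(3, "class2", insert_len = 120), "infeasible")
  expect_error(gen_case(3, "class2", insert_len = 0, deletion_len = 0),
               "infeasible")
  expect_error(gen_case(3, "class1", insert_len = 99), "infeasible")
})

test_that("a pure-deletion synthetic case designs 8+8 cross-tails", {
  case <- gen_case(1, "class2", insert_len = 0)
  d <- design_class2(parse_class2(case$raw_input))
  expect_identical(nchar(d$primers$tail), c(8L, 8L))
  expect_true(verify_assembly(simulate_products(d),
                              case$expected_construct)$pass)
})

test_that("case FASTA fixtures round-trip through the expected construct", {
  case <- gen_case(8, "class1")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_case_fasta(case, path)
  recs <- Biostrings::readDNAStringSet(path)
  expect_true(any(grepl("expected_construct", names(recs))))
  expect_identical(
    as.character(recs[[grep("expected_construct", names(recs))]]),
    case$expected_construct)
})
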