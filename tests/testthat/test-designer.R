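test_that("overlap window geometry matches the scheme's worked sizes", {
  w15 <- overlap_window(15)
  expect_identical(w15[c("u", "d", "s", "k_f", "k_r")],
                   list(u = 0L, d = 1L, s = 0L, k_f = 15L, k_r = 16L))
  w0 <- overlap_window(0)
  expect_identical(w0[c("u", "d", "k_f", "k_r")],
                   list(u = 8L, d = 8L, k_f = 8L, k_r = 8L))
  w36 <- overlap_window(36)
  expect_identical(w36[c("u", "d", "s", "k_f", "k_r")],
                   list(u = 0L, d = 0L, s = 10L, k_f = 26L, k_r = 26L))
  w2 <- overlap_window(2)
  expect_identical(w2[c("u", "d", "k_f", "k_r")],
                   list(u = 7L, d = 7L, k_f = 9L, k_r = 9L))
  w16 <- overlap_window(16)
  expect_identical(w16[c("s", "k_f", "k_r")],
                   list(s = 0L, k_f = 16L, k_r = 16L))
})

test_that("the 16-base overlap conservation law holds for every legal insert length", {
  for (Li in 0:119) {
    w <- overlap_window(Li)
    expect_identical(w$k_f + w$k_r - Li, 16L)
    expect_true(w$u >= 0 && w$d >= 0 && w$s >= 0)
    expect_true(w$k_f >= 1 && w$k_r >= 1)
  }
  expect_error(overlap_window(120), "\\[0, 120\\)")
  expect_error(overlap_window(-1), "\\[0, 120\\)")
})

test_that("annealing extension returns the first length crossing the Tm floor", {
  set.seed(321)
  for (i in 1:25) {
    template <- oracle_random_dna(90, runif(1, 0.3, 0.7))
    for (dir in c("right", "left")) {
      ext <- extend_anneal(template, dir)
      n <- nchar(ext$anneal)
      expect_gte(n, 18L)
      if (dir == "right") expect_identical(ext$anneal,
                                           substr(template, 1, n))
      else expect_identical(ext$anneal,
                            substr(template, nchar(template) - n + 1,
                                   nchar(template)))
      expect_gte(ext$tm, 55)
      expect_equal(ext$tm, oracle_tm(ext$anneal), tolerance = 1e-8)
      if (n > 18L) {
        shorter <- if (dir == "right") substr(template, 1, n - 1)
                   else substr(template, nchar(template) - n + 2,
                               nchar(template))
        expect_lt(tm_nn(shorter), 55)
      }
    }
  }
})

test_that("extension fails cleanly when the Tm floor is unreachable", {
  # an AT-only 40-mer never reaches 55 degC (Tm at full length ~50.8)
  expect_error(extend_anneal(strrep("A", 40), "right"), "cannot reach Tm")
  expect_error(extend_anneal("ACGTACGTACGT", "right"),
               "shorter than the minimum")
})

test_that("a narrow Tm window yields an overshoot warning, not a failure", {
  set.seed(17)
  narrow <- tm_range(55, 55.2)
  hits <- 0L
  for (i in 1:10) {
    ext <- extend_anneal(oracle_random_dna(90, 0.6), "right", range = narrow)
    expect_gte(ext$tm, 55)
    if (ext$tm > 55.2) {
      hits <- hits + 1L
      expect_match(ext$warning, "overshoot")
    }
  }
  expect_gt(hits, 0L)
})

test_that("class-1 design carries the 16-bp vector-derived overhangs", {
  inp <- parse_class1(example_class1_raw())
  d <- design_class1(inp)
  pr <- tidy(d)
  expect_identical(pr$name, c("VF", "VR", "IF", "IR"))
  p1 <- inp$vector_part1; p2 <- inp$vector_part2
  expect_identical(pr$tail[pr$name == "IF"],
                   substr(p1, nchar(p1) - 15, nchar(p1)))
  expect_identical(pr$tail[pr$name == "IR"], revcomp(substr(p2, 1, 16)))
  expect_identical(pr$tail[pr$name %in% c("VF", "VR")], c("", ""))
  # IF's tail (box r1c) is the exact reverse complement of VR's 3' terminus
  vr <- pr$sequence[pr$name == "VR"]
  expect_identical(pr$tail[pr$name == "IF"],
                   revcomp(substr(vr, 1, 16)))
  expect_identical(unname(junction_overlap(d)), c(16L, 16L))
})

test_that("class-1 annealing regions sit on their templates in the Tm window", {
  inp <- parse_class1(example_class1_raw())
  d <- design_class1(inp)
  pr <- tidy(d)
  expect_true(startsWith(inp$vector_part2, pr$anneal[pr$name == "VF"]))
  expect_true(endsWith(inp$vector_part1,
                       revcomp(pr$anneal[pr$name == "VR"])))
  expect_true(startsWith(inp$insert, pr$anneal[pr$name == "IF"]))
  expect_true(endsWith(inp$insert, revcomp(pr$anneal[pr$name == "IR"])))
  expect_true(all(pr$tm_anneal >= 55))
  expect_true(all(pr$tm_anneal <= 65) || length(d$warnings) > 0)
  sense <- c(pr$anneal[pr$name == "VF"],
             revcomp(pr$anneal[pr$name == "VR"]),
             pr$anneal[pr$name == "IF"],
             revcomp(pr$anneal[pr$name == "IR"]))
  expect_equal(pr$tm_anneal, oracle_tm(sense), tolerance = 1e-8)
})

test_that("class-2 deletion+insertion reproduces the printed junction tails", {
  d <- design_class2(parse_class2(example_class2_raw()))
  pr <- tidy(d)
  expect_identical(pr$name, c("F", "R"))
  expect_identical(pr$tail[1], "GGTTCTCCAGGTTCT")
  expect_identical(pr$tail[2], "TAGAACCTGGAGAACC")
  expect_match(pr$anneal[1], "^ACTTTATCTCGTTGG")
  expect_match(pr$anneal[2], "^TTTAACTTT")
  expect_identical(unname(junction_overlap(d)), 16L)
})

test_that("a 36-bp linker insert places the window inside the insert", {
  linkers <- example_linkers()
  l4 <- sanitize_seq(linkers$sequence[linkers$name == "L4"])
  expect_identical(nchar(l4), 36L)
  d <- design_class2(parse_class2(linker_swap_raw(l4)))
  pr <- tidy(d)
  expect_identical(pr$tail[1], "GTTCTGCTGCTGGTTCTGGTGAATTC")
  expect_identical(pr$tail[2], "GAACCAGCAGCAGAACCAGCAGAACC")
  expect_identical(unname(junction_overlap(d)), 16L)
})

test_that("pure deletion degenerates to symmetric 8+8 cross-tails", {
  d <- design_class2(parse_class2(stop_deletion_raw()))
  pr <- tidy(d)
  expect_identical(pr$tail[1], "AAATGACT")
  expect_identical(pr$tail[2], "TGCTCGAG")
  expect_identical(unname(junction_overlap(d)), 16L)
})

test_that("constructs splice deletion out and insert in", {
  inp <- parse_class2(example_class2_raw())
  cons <- assemble_construct(inp)
  expect_identical(cons, paste0(inp$upstream, inp$insert, inp$downstream))
  expect_true(grepl("GTTAAAGGTTCTCCAGGTTCTACTTTATCTCGTTGG", cons,
                    fixed = TRUE))
  expect_false(grepl(inp$deletion, cons, fixed = TRUE))
  c1 <- parse_class1(example_class1_raw())
  expect_identical(nchar(assemble_construct(c1)),
                   nchar(c1$vector_part1) + nchar(c1$insert) +
                     nchar(c1$vector_part2))
  case <- gen_case(3, "class2", insert_len = 0)
  inp0 <- parse_class2(case$raw_input)
  expect_identical(assemble_construct(inp0),
                   paste0(inp0$upstream, inp0$downstream))
})
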