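---
title: "Designing ligation-independent cloning primers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ligation-independent cloning primers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(licprimers)
```

## The cloning scheme this package serves

Ligation-independent (FastCloning-style) cloning builds a construct from
PCR products alone. For a vector + insert chimera, both molecules are
amplified; the insert primers carry 5' tails copied from the vector ends so
the insert amplicon terminates in 16 bp identical to each vector end. For
a deletion and/or a small insertion, a single primer pair amplifies the
whole plasmid around the edit; the primers' 5' tails span the junction and
overlap each other by 16 complementary bases, so the linear product's two
ends are redundant over 16 bp. After DpnI removal of the methylated
parental plasmid, the overlapping ends direct recombination in vivo.

The design problem is therefore two-fold: place the 16-bp junction overlap
correctly around the edit, and size each primer's 3' annealing region so
its melting temperature lands in a usable window. Both are exact,
deterministic computations; this package implements them and then *checks*
every design by simulating the PCR products and reassembling them.

## Melting-temperature model

Annealing Tm uses the unified nearest-neighbor DNA/DNA thermodynamics
(the Allawi–SantaLucia stacking table): duplex ΔH and ΔS are the sums of
dinucleotide stack contributions plus terminal initiation terms (+2.3
kcal/mol, +4.1 cal/mol·K per A/T end; +0.1, −2.8 per G/C end), entropy is
salt-corrected by `ΔS += 0.368 (N−1) ln[Mon+]`, and

    Tm = 1000 ΔH / (ΔS + R ln CT) − 273.15,  R = 1.987 cal/(mol K)

with `CT = ([primer] − [template]/2)·1e−9` mol/L, the excess-strand
convention for non-self-complementary duplexes. Defaults — 50 mM
monovalent cation, no Mg²⁺ or dNTPs, 25 nM of each strand — mirror the
documented defaults of the widely used sequence-utilities Tm routine, so
lengths agree with what most bench scientists' calculators report.
Divalent cations, if supplied, fold into the effective monovalent
concentration as `120·sqrt(Mg − dNTP)` mM. No symmetry correction is
applied (primers are treated as the excess strand, not as
self-complementary duplexes). All parameters are exposed via `tm_params()`
and the YAML config (`tm.*` keys).

Two deliberate modelling choices:

* **Tails never enter the Tm.** A 5' tail does not hybridize to the
  template in the early cycles, so only the 3' annealing region is scored.
* **Minimum evaluable length 6 nt** — the nearest-neighbor model is
  unreliable below that; the designer never requests fewer than
  `min_anneal_len` (18) anyway.

The implementation is validated two ways in the test suite: against a
second, independently coded transcription of the same published constants,
and against a frozen 100-sequence panel computed with an independent
literature-parameter implementation, both to within 0.01 °C.

## Annealing extension

`extend_anneal()` starts at `min_anneal_len = 18` nt and extends one base
at a time toward `max_anneal_len = 60` nt (the 18–60 bracket covers any
primer a practitioner would order), returning the **first** length whose
Tm reaches the window floor. Endpoints are inclusive. If that
first-crossing Tm already exceeds the ceiling — a single G/C base can jump
a narrow window — the primer is emitted with an overshoot warning rather
than refused: a usable primer with a slightly hot Tm beats no primer. If
the floor is unreachable at `max_anneal_len`, or the template runs out
first, the design fails with an explicit error. Extension clips at the
template end: a 40-bp vector part is legal input, and designable whenever
its Tm at ≤ 40 nt reaches the floor.

Reverse primers are handled with one orientation convention: all leftward
extensions are computed on the sense strand and reverse-complemented once,
at primer construction. Tails and annealing regions then concatenate in
primer orientation without case analysis.

## Junction geometry

The overlap length is fixed at 16 bp (exposed as
`design.overlap_length` for power users; the pure-deletion limit uses the
symmetric 8+8 split). For a class-2 insert of length `Li` at positions
`p..q` of the intended construct:

* `Li < 16`: the window recruits `u = ⌊(16−Li)/2⌋` upstream and
  `d = ⌈(16−Li)/2⌉` downstream flanking bases — the odd base goes
  downstream. Forward tail `k_f = u + Li`, reverse tail `k_r = Li + d`.
* `Li ≥ 16`: the window sits inside the insert, offset
  `s = ⌈(Li−16)/2⌉` from its 5' end — the odd base toward 5'.
  `k_f = Li − s`, `k_r = s + 16`.

Both tie-breaks are forced by the published primer sets this package
reproduces in its regression tests (a 15-bp insert gives tails of 15 and
16; a 36-bp insert gives 26 and 26; a 2-bp replacement gives 9 and 9; a
pure deletion 8 and 8). In every case `k_f + k_r − Li = 16`, asserted for
all `Li ∈ [0, 120)`.

Class-1 vector primers carry no tails: the junction overlap rides entirely
on the insert primers (`IF` tail = last 16 bases of vector part-1; `IR`
tail = reverse complement of vector part-2's first 16 bases). Vector
primer pairs decorated with extra features (restriction sites, manual
edits) are out of scope.

## Input grammar decisions

* A terminal sentence period and any whitespace, digits or `-` gaps are
  stripped before marker splitting; letter case is normalized. Parsing is
  therefore insensitive to codon spacing and line wrapping.
* `**` parses as two adjacent `*` delimiting an empty deletion — all three
  class-2 syntaxes (replacement, pure insertion, pure deletion) are the
  single rule "exactly three stars, segments may be empty". A job with
  both deletion and insert empty is rejected as a no-op.
* Size thresholds are inclusive as stated: vector parts ≥ 40 bp and
  class-1 insert ≥ 100 bp accepted; class-2 insert < 120 bp (120 is the
  smallest rejected value). Class-2 upstream/downstream segments must be
  ≥ `min_anneal_len + 8` bp (26 by default) — enough to host a junction
  tail plus a minimal annealing region; published deletion-only examples
  with a 40-bp downstream segment remain valid under this rule.
* The IUPAC alphabet is restricted to A/C/G/T. Ambiguity codes are
  rejected with a position, because both the Tm model and the exact 16-bp
  junction identity require fully specified bases.

## The in-silico verifier

`simulate_products()` is the package's correctness oracle, written as
plain string arithmetic independent of the designer's internal geometry:
it locates each annealing region on its unmodified template by exact
match (a missing match is an error — the designer guarantees template
identity, so the oracle is strict by design), and constructs each
amplicon as `fwd tail ++ template span ++ revcomp(rev tail)`. The class-2
template and the class-1 vector are treated as circles; since the input
format carries no backbone between the two vector parts, the vector
circle is `part2 ++ part1` joined directly — the junction logic is
unaffected by the missing backbone. `verify_assembly()` merges amplicons
on 16-bp terminal identities, circularizes, and compares with the
intended construct rotation-invariantly, reporting the first mismatch
position when alignment is possible.

One known approximation: annealing sites are located by *first* exact
occurrence. A pathological template in which an 18+ nt annealing region
recurs elsewhere could mislead the simulator (not the designer); random
sequences made by the case generator make this vanishingly unlikely, and
real inputs would fail loudly at the assembly comparison.

## Synthetic cases: what they emulate and what they don't

`gen_case()` draws uniform random bases with a GC fraction sampled in
[0.3, 0.7] — within that range the default Tm window is always reachable
inside the 18–60 nt annealing bracket. Default segment sizes (120-bp
vector parts and hosts, 150-bp class-1 inserts, class-2 inserts uniform
on 0–119 bp with deletions of 0–30 bp) sit comfortably above the grammar
thresholds so every generated case is designable. The generator is
deterministic per seed.

The property suite runs 200 seeded cases per class through design →
simulation → assembly, plus corruption tests flipping every base of a
16-bp junction. Passing it shows the geometry, orientation conventions
and Tm sizing are self-consistent end to end. It does **not** show that
the primers will work at the bench on arbitrary natural sequences:
uniform random DNA has no long homopolymers, repeats, or secondary
structure, and the simulator's perfect-match annealing ignores
mispriming. Extreme-composition natural templates (e.g. AT-rich
stretches) can legitimately fail with "cannot reach Tm", which is a
correct refusal, not a bug.

## Reporting

Reports list primers in a stable order (VF, VR, IF, IR; or F, R) with Tm
to two decimals and lengths in nt, tails lowercase and annealing regions
uppercase (disable with `--no-case`), then the construct as 70-column
FASTA, the three forward-frame translations (standard genetic code,
trailing partial codons dropped, stops as `*`), and the input echo. A
WARNINGS section appears only when warnings exist. Reports are
byte-identical for identical input and configuration; for that reason the
timestamp is opt-in (`timestamp = TRUE`) rather than default. The JSON
mirror (`design_to_json()`) round-trips through `design_from_json()` far
enough to re-run the simulator on a saved design.

## Limitations

* No screening for hairpins, homo-/heterodimers or GC clamps, and no
  primer-pair Tm balancing — annealing regions are sized independently.
* No mismatch thermodynamics; the verifier's annealing model is
  all-or-nothing.
* Reverse-strand reading frames are not translated (forward frames only).
* Multi-insert assemblies and multi-record FASTA are out of scope.
```{r}
design <- design_class2(parse_class2(paste(readLines(
  system.file("extdata", "class2_del_ins.txt", package = "licprimers")),
  collapse = "\n")))
tidy(design)
junction_overlap(design)
verify_assembly(simulate_products(design), assemble_construct(design$input))
```
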