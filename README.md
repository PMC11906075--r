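# licprimers

Primer design for restriction- and ligation-independent PCR cloning
(FastCloning-style). In this method the vector and the insert — or, for
mutagenesis, the whole plasmid around a deletion/insertion site — are PCR
amplified with primers whose 5' tails make the fragment ends mutually
complementary over **16 bp**; after DpnI digestion of the parental template,
the overlapping ends recombine in vivo. No restriction sites, no ligase.
Getting those primers right by hand is fiddly: the 16-bp junction must be
split correctly around the edit and every annealing region must land in a
melting-temperature window. `licprimers` automates both, and proves each
design correct with an in-silico PCR and assembly simulation.

## What it computes

**Annealing regions.** Each primer's 3' annealing region is grown one base
at a time (18–60 nt) until its melting temperature reaches the requested
window (default 55–65 °C, inclusive). Tm is the unified nearest-neighbor
model: duplex ΔH and ΔS are summed over dinucleotide stacks with terminal
initiation terms, the entropy is salt-corrected by
`ΔS + 0.368 (N−1) ln[Mon⁺]`, and

```
Tm = 1000 ΔH / (ΔS + R ln CT) − 273.15,   CT = [primer] − [template]/2
```

with defaults 50 mM monovalent salt and 25 nM of each strand. Tails are
never included in the Tm — they do not hybridize to the template in the
early cycles. The first length to cross the floor is kept; if that length
already exceeds the ceiling the primer is emitted with an overshoot
warning rather than refused.

**Junction geometry.** Two design classes:

* **Class 1** — insert (≥ 100 bp) into a linearized vector, input
  `vector-part-1 + insert + vector-part-2`. Four primers: plain vector
  primers `VF`/`VR`, and insert primers `IF`/`IR` whose 5' tails are the
  last 16 bases of part-1 and the reverse complement of the first 16 bases
  of part-2, so each insert amplicon end is identical to 16 bases of a
  vector end.
* **Class 2** — deletion and/or small insertion (< 120 bp), input
  `upstream * deletion * downstream * insert` (empty deletion = pure
  insertion; empty insert = pure deletion). One primer pair sharing exactly
  16 complementary bases across the junction: an insert of length `Li < 16`
  recruits `⌊(16−Li)/2⌋` upstream and `⌈(16−Li)/2⌉` downstream flanking
  bases; `Li ≥ 16` places the window inside the insert, `⌈(Li−16)/2⌉` from
  its 5' end; a pure deletion degenerates to symmetric 8+8 cross-tails.
  Always `k_f + k_r − Li = 16`.

**Verification.** `simulate_products()` performs exact-match primer
extension on the unmodified (circular) templates; `verify_assembly()`
merges the amplicons on their 16-bp terminal identities and compares the
resulting circle, rotation-invariantly, with the intended construct.

## Worked example

Replacing a 21-bp linker with a 15-bp one (a deletion + insertion job; the
input file marks the deleted region with `*…*` and appends the insert after
a third `*`):

```r
library(licprimers)

raw <- paste(readLines(system.file("extdata", "class2_del_ins.txt",
                                   package = "licprimers")), collapse = "\n")
design <- design_class2(parse_class2(raw))
design
#> <fc_design> class2 | 2 primers | construct 845 bp | Tm window 55-65 degC
#>   F     39 nt  Tm  55.87 C  ggttctccaggttctACTTTATCTCGTTGGACTGGTCGT
#>   R     65 nt  Tm  55.26 C  tagaacctggagaaccTTTAACTTTTTTTTTAGTATCATTCATATAAATAATATCATCTAAAGCT
```

`F` carries the whole 15-bp insert as its 5' tail (lowercase) and anneals
downstream of the junction at 55.87 °C; `R` carries the reverse complement
of the insert plus one downstream base (16 bases) and anneals on the
upstream side. Mapped onto the construct the two primers overlap over
exactly the 16 junction bases, and the simulated whole-plasmid amplicon
reassembles the intended construct:

```r
junction_overlap(design)
#> FR
#> 16
verify_assembly(simulate_products(design), assemble_construct(design$input))
#> assembly verified: amplicons reproduce the intended construct
```

`tidy(design)` returns the primer table as a tibble, `glance(design)` a
one-row summary, `autoplot(design)` a primer map, and `write_report()` /
`write_construct_fasta()` / `design_to_json()` emit the report (primers
with Tm and lengths, construct FASTA, three forward-frame translations,
input echo), the construct, and a machine-readable mirror.

## Command line

```sh
Rscript inst/cli/licprimers.R design --mode class2 \
    --input inst/extdata/class2_del_ins.txt --tm 55:65 \
    --out report.txt --fasta construct.fasta --json design.json
Rscript inst/cli/licprimers.R simulate --result design.json
Rscript inst/cli/licprimers.R gen-fixture --seed 7 --mode class1
```

Exit codes: 0 success, 2 validation/usage error, 1 internal error.

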