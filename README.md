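# scanmut

Scanning mutagenesis — substituting every residue of a protein in turn,
classically by alanine — needs hundreds of mutagenic primer pairs, and
afterwards hundreds of Sanger reads checked for the intended codon change.
`scanmut` automates the desk work of that pipeline for R users:

* **Mutagenic primer design** for whole-plasmid overlapping PCR.  The
  plasmid is amplified with a forward/reverse pair that both carry the new
  codon near overlapping 5' ends; the linear product ends in 13–15 bp of
  identical sequence and recircularises by end repair after transformation.
* **Sequencing verification**: a gapless offset-scan aligner scores a read
  against the reference ORF, flags non-productive clones (duplications,
  deletions) by multiple score peaks, and calls mutations codon by codon.
* **Seamless cloning primers**: quartets (`pv5`, `pv3`, `pi5`, `pi3`) that
  amplify a vector backbone and an insert with ~15 bp identical ends for
  ligation-independent assembly, with optional inclusion sequences and
  three overhang-placement strategies.

## The rules at the core

Melting temperature uses the GC-fraction rule

    Tm = 64.9 °C + 41 °C · (n_GC − 16.4) / L

applied twice per mutagenic primer: once over the bases that still match
the wild-type template (`Tm`, relevant in early PCR cycles) and once over
the full primer (`Tm_full`, later cycles).

The GC clamp at the 3' terminus is scored by the trinucleotide pattern
rules `[GC][GC][GC] = 0`, `[ATGC][ATGC][AT] = 1`, `[ATGC][AT][GC] = 2`,
`[AT][GC][GC] = 3` (0 worst, 3 best); the four patterns partition all 64
trinucleotides.

The designer enumerates every pair geometry — overlap length 13–15 bp,
overlap placement, both primer lengths — and keeps the candidates whose
lengths, annealing Tm window, Tm difference, 3'-annealing distance from the
mutated codon (≥ 15 bp) and GC clamp all pass, ranked shortest-first with
Tm as close to `min_tm` as possible.  An adaptive mode relaxes `min_tm` in
1 °C steps for positions that are otherwise infeasible.

Read verification scores a read at every offset against the reference by
counting sliding 7-nucleotide windows that match perfectly; gaps are not
modelled, so indels and duplications show up as multiple peaks (a
non-productive clone) rather than as spurious calls.

## Worked example

A 600 bp demo plasmid (seeded synthetic sequence, ORF at position 151)
ships with the package:

```r
library(scanmut)
plasmid <- read_fasta(system.file("extdata", "demo_plasmid.fasta",
                                  package = "scanmut"))
ctx    <- template_context(plasmid, orf_start = 151)
batch  <- batch_design(ctx, 10, 12, design_params())
writeLines(render_short(batch_pairs(batch)))
#> V10A_F	CCTGGTGCTGTCCAATCAACACAGACG
#> V10A_R	GGACAGCACCAGGTGTGTACTGAAACG
#> V11A_F	GGTGTGGCCCAATCAACACAGACGG
#> V11A_R	GATTGGGCCACACCAGGTGTGTACTG
#> Q12A_F	CGCTTCAACACAGACGGTTCCACGTGC
#> Q12A_R	CTGTGTTGAAGCGACCACACCAGGTGTG
```

Each name is `<wtAA><position><mutAA>_F/_R`; the `Long2` format adds the
coding-strand rendering (mutated codon capitalised, substituted bases as
`X`), length, both Tm values, clamp score and 3'-annealing length:

```r
writeLines(render_long2(batch_pairs(batch)[1]))
#> name	strand	coding_strand	length	tm	tm_full	gc_clamp_score	anneal_len_3prime	overlap_len	primer
#> V10A_F	forward	cctggtGXXgtccaatcaacacagacg	27	60.96	62.77	3	18	13	CCTGGTGCTGTCCAATCAACACAGACG
#> V10A_R	reverse	cgtttcagtacacacctggtGXXgtcc	27	60.96	62.77	3	20	13	GGACAGCACCAGGTGTGTACTGAAACG
```

So the V10A pair is 27 nt on each side, anneals at 60.96 °C against the
wild-type template (62.77 °C once the mutation is established), shares a
13 bp product overlap and keeps 18/20 bp between the mutated codon and the
3' ends.  The in-silico round trip closes the loop — simulate the PCR and
recircularisation, then call the mutation back from a "read" of the mutant:

```r
pair   <- batch_pairs(batch)[[1]]
mutant <- simulate_mutagenesis(ctx, pair)
ref    <- reference_context(substr(plasmid, 151, 450))
align_and_call(ref, substr(mutant, 100, 320))
#> best offset -51, max score 156, 1 peak(s)
#> calls: V10A
```

A thin command line mirrors the library (`design`, `check`, `clone`,
`fixtures` subcommands; see `inst/cli/scanmut`).

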