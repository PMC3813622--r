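---
title: "Designing and verifying scanning mutagenesis with scanmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying scanning mutagenesis with scanmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanmut)
```

## The problem

An alanine scan of a 400-residue protein needs ~400 mutagenic primer
pairs and, at one or two sequenced colonies per mutant, a comparable pile
of Sanger reads to check.  `scanmut` covers the three desk-side tasks of
that workflow: designing the primer pairs for whole-plasmid overlapping
PCR, verifying the sequencing results semi-automatically, and designing
primer quartets for seamless (ligation-independent) cloning.

The wet-lab model behind the designer: the whole plasmid is amplified with
two primers that both span the mutation site.  The linear product carries
a short stretch of identical sequence at both ends (the *overlap*, 13–15
bp); inside a suitable *E. coli* strain the ends recombine and restore a
circular plasmid that now carries the substitution.  Overlaps below ~11 bp
repair inefficiently, very long overlaps promote primer self-annealing —
hence a narrow default window, and `design_params()` warns below 11 bp.

## The melting-temperature model

Both designers use the GC-fraction rule

$$T_m = 64.9\,°C + 41\,°C \cdot (n_{GC} - 16.4)/L$$

with $n_{GC}$ the number of G/C bases and $L$ the primer length.  It is
applied verbatim at any length — short or AT-rich oligos legitimately get
low or even negative values, which the Tm window then rejects; there is no
clamping or salt correction.  Nearest-neighbour thermodynamics and
secondary-structure screening are deliberately out of scope: primer
hairpin/homodimer stability shows no strong relationship with mutagenesis
success in practice, and the simple rule keeps the search space exactly
rankable.

A mutagenic primer gets two temperatures.  `tm_full` is the rule over the
whole primer, the relevant quantity once the mutant template dominates the
reaction.  `tm_anneal` describes the early cycles, when the primer sits on
the wild-type template with mismatches at the substituted bases.  The rule
says nothing about mismatch energetics, so a convention is needed: the
mismatched positions are deleted and the rule is applied to the remaining
bases (reduced length, reduced GC count).  An equally defensible variant
would keep the full length and count mismatches as non-GC; the choice is
isolated in `tm_pair_for_primer()` so it can be swapped in one line.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` | 25, 45 bp | allowed primer lengths |
| `min_tm`, `max_tm` | 60, 75 °C | annealing-Tm window; design aims at `min_tm` |
| `max_delta_tm` | 3 °C | max Tm difference within a pair |
| `min_anneal_len` | 15 bp | mutated codon to 3' end, per carrying primer |
| `min_gc_clamp` | 0 | required 3' G/C run; 0 disables |
| `use_optimised_gc_clamp` | off | rank by the 0–3 clamp quality score |
| `min_overlap`, `max_overlap` | 13, 15 bp | product end identity |
| `max_suggestions` | 1 | ranked geometries returned per residue |
| `adaptive_tm` | off | relax `min_tm` by 1 °C steps where needed |

The overlap window, the 15 bp annealing distance and the 1 °C relaxation
step are fixed by the method; the length and temperature windows have no
canonical values, and the defaults above are the package's own choice: a
60 °C floor is the usual annealing target for mutagenic primers under this
Tm rule, 45 nt is a routine synthesis length, and 3 °C keeps a pair
co-functional in one reaction.  Every value is a constructor argument.

Codon choice: two primary codons (default `GCT`/`GCC`, alanine) and two
fallback codons (default `GGT`/`GGC`, glycine) for residues that already
are the primary target.  Among the applicable two, the codon with fewer
mismatches against the template wins; ties go to the first listed, so the
preference order is in the user's hands.

## The search and its ranking

`enumerate_pairs()` enumerates every geometry: overlap length $k \in
[13,15]$, overlap start $s$, forward primer extending right from $s$,
reverse primer (on the bottom strand) whose top-strand window ends at
$s+k-1$ and extends left.  The mutated codon may sit anywhere covered —
inside the overlap (both primers carry it, identically) or in one primer's
3' extension; a geometry in which a primer covers only part of the codon
is discarded outright, since it would synthesise an unintended codon.

"Shortest primers with Tm as close to `min_tm` as possible" fixes the top
of the ranking but not the ties, so the order is made fully deterministic:
(1) smaller maximal primer length, (2) smaller total length, (3) smaller
total Tm excess over the (possibly relaxed) floor, (4) with the optimised
clamp enabled, larger summed clamp score, then (5) leftmost overlap start.
The test suite holds the implementation to this ranking with an
independent exhaustive search over raw substrings.

The adaptive mode stops 10 °C below `min_tm`.  The relaxation is
per-position and reported in the result (`relaxed_min_tm`); unbounded
relaxation would only produce primers nobody should order — lengthening
`max_len` is the better lever.

Templates are treated as linear with user-provided flanks (≥ `max_len` on
each side of any targeted codon; `enumerate_pairs()` refuses positions
closer to an edge).  Circularity enters where a product necessarily
crosses the origin: `simulate_mutagenesis()` and the two-fragment design,
which also raises the mutagenic overlap to ≥ 15 bp because its junctions
are joined in vitro by 15 bp assembly overlaps rather than by in-cell end
repair.

## Read verification

`window_score()` counts, inside the ungapped overlap at a given offset,
the positions of a sliding 7-nt window at which all seven aligned bases
match; `score_profile()` scans all offsets.  The aligner is deliberately
gapless: the goal is to confirm a codon substitution, and indels or
duplications should *fail* alignment visibly instead of being smoothed
over.  They do so as multiple profile peaks; any offset scoring at least
half the maximum counts as a peak (the fraction is an argument — the
notion of "multiple peaks" needs a threshold and 0.5 is conservative for
the sharp profiles this score produces), and several peaks flag the read
as a non-productive clone.  An `N` never supports a window, so low-quality
tails weaken alignment rather than fabricate support; codons touched by an
`N` over a difference are reported as uncallable, never as mutations.
Ties on the maximal score resolve to the smallest offset, and auto
orientation prefers the given strand on ties — both arbitrary but fixed.

Calls are grouped per reference codon: reference codon, observed codon,
both translations, the nucleotide changes, and a silent flag.
`batch_check()` condenses each read to one row with a verdict in
`{expected-mutation-present, clean, unexpected, ambiguous, no-overlap}`;
verdict precedence puts alignment pathology (`no-overlap`, `ambiguous`)
before content.

## Cloning quartets

`design_quartet()` names its four primers by what they anneal to: `pv5`
the 5' end of the (linearised) vector, `pv3` its 3' end, `pi5`/`pi3` the
insert ends.  The vector amplicon runs from the downstream vector part
around the circle to the upstream part, so `pv5` is a sense prefix of the
downstream part and `pv3` the reverse complement of the upstream part's
suffix.  Annealing cores are the shortest prefixes/suffixes meeting the
Tm and clamp constraints.

At each junction the construct contains the inclusion (possibly empty)
flanked by vector and insert sequence.  The junction sequence carried on
overhangs always totals `overlap_len + inclusion` bases, which makes the
terminal identity between the two amplicons exactly `overlap_len`
(default 15 bp) regardless of strategy: **A** puts all of it on the vector
primers (one vector pair serves many inserts), **B** on the insert primers
(one insert into many vectors), **C** splits it so the two primers at a
junction differ by at most 1 nt in length — the balance that matters when
a long inclusion would otherwise exceed comfortable synthesis lengths.
With strategy C the exact split is not derivable from first principles;
centring on total primer length is this package's convention.  Balance can
be geometrically impossible when the two annealing cores differ by more
than the junction sequence length; the split is then clamped and the
products remain correct, only less balanced.  Overhangs beyond 60 nt
(configurable) raise an error instead of a silently unorderable oligo.

`simulate_assembly()` rebuilds both amplicons from the primers, checks the
junction identities and asserts that the joined circle equals the
concatenated five-part target — the same product for all three strategies.

## The synthetic fixtures, and what passing means

`generate_fixture()` emulates the inputs of a real scanning project: a
plasmid with ≥ 60 bp flanks around an ORF (ATG start, no internal stop,
`TAA` appended), reads sliced around a planted codon substitution with 75
bp flanks, optional uniform base errors, and a truth table.  Bases are
i.i.d. at a set GC fraction (0.5 by default).  Real templates are not
i.i.d. — repeats, codon bias, GC gradients and chromatogram-quality tails
are absent — so green tests demonstrate the *algorithms* (optimality of
the search, exactness of the round trip, partitioning of the clamp
scores), not performance on pathological genomes.  Duplicated-block
fixtures cover the one pathology the aligner is designed to flag.

Problem sizes in the routine suite were picked to keep it quick while
exercising every code path: 500–700 bp templates with 80–150 residue
ORFs, 50 designer-vs-oracle templates, 100 round-trip substitutions, 100
ambiguity fixtures and 50 three-strategy cloning designs (the cloning
fixtures use 21 bp inclusions, the length of a protease-site coding
sequence and a regime where strategy C's balance is always achievable).

## Numerical and degenerate-input choices

* The Tm rule is exact double arithmetic; tests compare to an independent
  hand formula at 1e-12 and the designer's feasibility comparisons are
  exact (the enumeration and its oracle compute bit-identical values).
* Empty sequences: allowed by `normalize_sequence()` and
  `reverse_complement()`; an error for Tm and clamp operations.  A primer
  mismatching its template everywhere has no annealing Tm and errors.
* `N` is forbidden in design inputs, permitted in reads.
* All user-facing coordinates are 1-based inclusive (ORF start, residue
  numbers, template spans); conversions happen only at API boundaries.
* Every error is a typed condition (`scanmut_no_feasible_primer`,
  `scanmut_position_out_of_range`, ...), so batch drivers can separate
  per-position infeasibility from real failures; `batch_design()` records
  a failed residue and continues.

## Known limitations

No nearest-neighbour Tm, salt correction or secondary-structure ΔG; no
chromatogram parsing or quality trimming (inputs are base-called
sequences); no insertion/deletion alignment (by design); no multi-fragment
(> 2 part) assembly; codon choice is limited to the user's two+two codons
— no codon-usage tables or degenerate libraries.
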