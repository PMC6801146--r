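---
title: "Modular Golden Gate design and simulation for Yarrowia lipolytica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular Golden Gate design and simulation for Yarrowia lipolytica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yaligg)
library(dplyr)
```

## The model

Golden Gate cloning exploits Type IIS restriction enzymes, which cut at a
fixed offset *outside* their recognition sequence. BsaI recognises `GGTCTC`,
skips one nucleotide and cuts the top strand, then cuts the bottom strand
four nucleotides further on, leaving a 4-nt 5' overhang whose sequence is
chosen by the designer, not the enzyme. Because the recognition site leaves
with the donor backbone, digestion and ligation can run in one pot: correct
products accumulate because they contain no site left to recut.

The toolkit modelled here standardises this chemistry for *Yarrowia
lipolytica* pathway engineering as a circular junction grammar of thirteen
lettered overhangs:

```
Backbone -A- InsUp -B- Marker -C- Prom1 -D- Gene1 -E- Term1 -F-
Prom2 -G- Gene2 -H- Term2 -I- Prom3 -J- Gene3 -K- Term3 -L- InsDown -M-
```

Every brick is a donor plasmid whose payload is flanked by outward BsaI
sites cutting inward, so digestion releases
`left overhang + payload + right overhang`. A part's position in the final
plasmid is therefore fully determined by its letter pair, and a one-pot
reaction containing one brick per slot plus the destination vector closes
into exactly one circular product: up to three transcription units (TUs),
a selection marker and genome-integration flanks, assembled in a single
step. One- and two-TU designs reuse the same gene and promoter bricks by
closing the circle early with shortcut terminators carrying E-L or H-L
overhangs, giving pots of 7, 10 and 13 molecules for 1, 2 and 3 TUs.

```{r grammar}
junctions_for("3TU")
gg_grammar("1TU")
```

## Representation choices

Three conventions keep the simulator exactly testable:

* **Overhangs as top-strand text.** Every overhang is recorded as the 4-nt
  top-strand sequence at the junction. Physically a fragment's right-hand
  protrusion is on the bottom strand, but under this convention two ends
  ligate iff their strings are equal, so junction compatibility is string
  equality and Watson-Crick pairing is implicit.
* **Coordinates.** 0-based, half-open internally; converted to GenBank's
  1-based inclusive spans on output.
* **Canonical form for circles.** Assembly products have no natural origin
  or strand, so equality of circular molecules is tested on the
  lexicographically minimal rotation over both strands
  (`canonical_form()`). This is what makes "the preassembly route and the
  direct route give the same plasmid" a well-posed, exact assertion.

IUPAC ambiguity codes are rejected on ingest rather than expanded: bricks
are fully specified molecules, and an ambiguous junction base would have no
unique overhang.

## The overhang set

A junction set is usable when every sticky end is unique: all sequences of
length 4, pairwise distinct, none palindromic (a self-complementary
overhang ligates to itself in either orientation) and no two mutual reverse
complements (two different junctions would anneal). `validate_overhang_set()`
checks exactly these properties and itemises violations.

The physical toolkit's letter-to-sequence assignments are published in its
supplementary material, which this package does not reproduce; the packaged
default set is a repository-defined assignment that passes every constraint
above, and the manifest format accepts a substitute mapping verbatim. All
structural claims the package tests (junction counts, fragment counts,
closure uniqueness, route equivalence) depend only on the constraints, not
on the particular sequences.

## Assembly simulation

`simulate_one_pot()` digests every input plasmid with BsaI, keeps from each
exactly one released BsaI-free fragment (donor backbones and the
destination vector's RFP dropout retain recognition sites and drop out,
mirroring red/white counterselection in *E. coli*), then searches the
junction graph for circular closures that use every fragment once. Three
outcomes are contractual:

* exactly one closure: the annotated product is returned, BsaI-free by
  construction;
* an unsatisfiable overhang: an *open junction* error naming the letters;
* more than one closure (possible only with redundant overhangs): an
  *ambiguity* error listing the alternatives. True combinatorial pooling is
  expressed through `enumerate_designs()`, which enumerates or samples the
  Cartesian product of per-slot options, rather than by overloading one pot
  with interchangeable bricks -- this keeps the simulator's uniqueness
  contract testable.

The split preassembly route for three TUs fuses the three printed 4-part
groups -- (InsUp, Marker, Prom1, Gene1), (Term1, Prom2, Gene2, Term2),
(Prom3, Gene3, Term3, InsDown) -- into linear intermediates and then closes
them with the vector. The test-suite asserts canonical identity of both
routes on randomly drawn designs.

## Domestication and adapter primers

Parts destined for the system must be free of internal BsaI (and usually
NotI) sites. `domesticate_cds()` removes them from coding sequences by
synonymous single-codon substitution: sites are handled left to right, one
edit per site, candidate codons tried third-position ("wobble") changes
first and then any synonymous codon, lexicographic within each block, and
an edit is accepted only if it removes the site without creating a new one
anywhere (the sequence is re-scanned after every edit). This greedy order
is deterministic and gives the minimal one-edit-per-site solution whenever
one exists; a site spelled entirely by Met/Trp codons is reported as
unresolvable with its coordinates. Translation preservation is asserted by
an independent codon-by-codon comparison in the tests, never by the
editor's own bookkeeping.

`design_adapter_primers()` turns a clean template into a brick insert: each
primer tail is `GGTCTC` + a 1-nt spacer (`A`, matching the enzyme's 1/5
geometry with the shortest possible tail) + the slot overhang, and the
annealing region grows 3'-ward from 18 nt until the estimated melting
temperature reaches the target (default 55 C). The Tm estimate is the
Wallace rule (2 C per A/T, 4 C per G/C) -- deterministic, dependency-free
and adequate for 18-30 nt annealing regions; it is a `run_config()` field
so another rule can be swapped in. The designed pair round-trips by
construction: BsaI digestion of the simulated amplicon releases exactly the
requested overhangs, and the test-suite asserts this for random templates
and letters.

## Protocols and QC

`make_protocol()` reproduces the published bench recipes as fixed
constants: 50 pmol of every molecule (equimolar), and per stage

| stage | BsaI | T4 ligase | buffer | volume | cycling |
|---|---|---|---|---|---|
| standard one-pot | 5 U | 200 U | 2 ul | 20 ul | (37 C 5 min / 16 C 2 min) x 60 |
| preassembly | 5 U | 200 U | 1 ul | 10 ul | (37 C 3 min / 16 C 2 min) x 30 |
| multigene final | 20 U | 400 U | 4 ul | 40 ul | (37 C 5 min / 16 C 5 min) x 50 |

each followed by 55 C 5 min, 80 C 5 min and a hold. `pmol_to_mass()`
supports the pipetting table with the conventional 650 g/mol/bp
double-stranded weight (configurable).

`notI_release()` predicts the verification digest: integration cassettes
flanked by NotI-carrying bricks release as exactly two fragments, sizes
conserved; a NotI cut strictly inside the cassette is a warning with its
position. `colony_pcr()` predicts amplicon sizes with exact-match primers
only (degenerate or mismatched priming is out of scope), measured primer
start to primer start, across the origin on circular templates.

`integration_rate()` formats locus-replacement screening counts as whole
percents under an explicit policy because the published counts sit on the
boundary: 5/37 is 14% rounded but 13% truncated, and 11/24 is 46% rounded
but 45% truncated -- the printed 45% corresponds to truncation. The package
defaults to round-half-up and every report states its policy; silently
matching one printed figure would misstate the other.

## The synthetic fixture

`generate_toolkit()` builds a deterministic toolkit whose inventory matches
the published collection -- 64 bricks: 27 promoter (9 named promoters at
each of 3 positions), 14 terminator, 6 marker, 10 genome-insertion, 5 gene
bricks, 2 destination vectors -- with synthetic sequences. Choices made
where the inventory is not itemised:

* The 14 terminator bricks are reconstructed as TLip2 at all three
  positions plus the E-L and H-L shortcuts, TTef and T1Guo at all three
  positions, TSynth8 at two and one further terminator at position 1; the
  breakdown is flagged as a reconstruction in the brick notes.
* The 10 insertion bricks are the four up/down pairs (ZETA, LIP2, GSY1,
  MFE) plus NotI-flanked ZETA variants, which the flagship construct's
  layout string itself names.
* Payload lengths are realistic part sizes: promoters 300-800 nt,
  terminators 80-200 nt, markers 1000-1600 nt, insertion flanks 400-700 nt,
  backbones 2000-2500 nt; mock genes are random open reading frames of
  600-1500 nt (start codon, no internal stops, BsaI/NotI-free via the
  package's own domestication editor). Real promoter, marker and locus
  identities appear as annotations only; no external sequence is fetched.

What the fixture does *not* emulate: real sequence composition (codon
usage, GC skew, repeats), misligation of near-cognate overhangs, partial
digestion, star activity or methylation sensitivity. Passing tests
therefore demonstrate the combinatorial and geometric correctness of
designs -- junction closure, site freedom, sizes, layouts -- not wet-lab
efficiencies; the published transformation and expression figures are
metadata, not simulated quantities.

`generate_xylose_demo()` rebuilds the flagship application as a fixture: a
3-TU plasmid carrying mock xylitol dehydrogenase (position 1), xylose
reductase (position 2) and xylulokinase (position 3) under pTEF/TLip2 with
a URA3 marker and NotI-flanked ZETA arms, whose feature order reproduces
the published layout string and whose NotI digest yields two fragments.

```{r demo}
demo <- generate_xylose_demo(seed = 42)
count_fragments(demo$design, demo$toolkit)
tidy(demo$product) |> select(slot, name, start, end)
notI_release(demo$product)
```

## Numerical and degenerate-input policy

* Two cuts closer than the overhang length are a degenerate-geometry error
  (the ends would share residues), never silently merged.
* Zero recognition sites return the molecule intact as one fragment;
  linear-molecule termini carry empty overhangs and ligate to nothing.
* Sites running off the end of a linear molecule are an error rather than a
  partial cut.
* Residue conservation holds for every digest: fragment lengths minus one
  overhang length per junction sum to the parent length; the suite asserts
  this on a thousand random molecules alongside strand symmetry
  (digesting the reverse complement mirrors the fragment multiset).
* Closure search is exhaustive depth-first enumeration, feasible because
  pots are at most 13 fragments; the tests cross-check it against a
  permutation brute force on small pots and against the
  permutation-cycle-structure argument on the 13-fragment pot.

## Problem sizes in the test-suite

The property suites run at sizes that exercise the combinatorics without
waste: 1000 random molecules for digestion conservation/symmetry, 50
random 3-TU designs for route equivalence, 100 planted-site coding
sequences for domestication, 10-kb molecules for the scan oracle, and the
full 729-design promoter grid for enumeration. The complete suite runs in
about two minutes on one CPU.

## Limitations

* Ligation is all-or-nothing on exact 4/4 overhang equality; overhang
  fidelity (mismatch tolerance of real ligases) is not modelled, so the
  simulator cannot rank overhang sets by experimental fidelity, only
  accept or reject them structurally.
* The domestication editor edits coding sequence only; removing sites from
  promoters or terminators (where no synonymy exists) is the user's
  responsibility.
* GenBank support covers the package's own single-record files with
  `misc_feature` annotations, not the full flat-file grammar.
* Wet-lab outcomes -- colony counts, white/red ratios, expression strength,
  transformation efficiency -- are out of scope throughout.
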