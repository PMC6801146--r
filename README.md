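# yaligg

In-silico design, simulation and QC for a modular Golden Gate cloning
standard targeting the oleaginous yeast *Yarrowia lipolytica*.

The physical toolkit this package models assembles up to three
transcription units (TUs), a selection marker and genome-integration flanks
into one plasmid in a single one-pot BsaI/T4-ligase reaction. Order and
orientation are dictated by a circular grammar of thirteen 4-nt junction
overhangs, lettered A-M:

```
Backbone -A- InsUp -B- Marker -C- Prom1 -D- Gene1 -E- Term1 -F-
Prom2 -G- Gene2 -H- Term2 -I- Prom3 -J- Gene3 -K- Term3 -L- InsDown -M-
```

BsaI is a Type IIS enzyme: it recognises `GGTCTC`, skips one nucleotide and
leaves a 4-nt 5' overhang of the designer's choosing, so each brick's
flanking letter pair fixes its slot. Shortcut terminators carrying E-L or
H-L overhangs close the circle early, giving pots of 7, 10 or 13 DNA
molecules for 1-, 2- or 3-TU designs. `yaligg` simulates the whole
workflow: exact cut geometry, overhang-set validation, brick checking,
one-pot closure (with open-junction and ambiguity diagnosis), the split
preassembly route, combinatorial design enumeration, codon-preserving
domestication of coding sequences, adapter-primer design, bench protocol
generation, and construct QC (NotI cassette release, colony-PCR sizing).

For whom: synthetic biologists planning *Y. lipolytica* (or other
Golden-Gate-style) constructs who want their designs checked, their
products predicted and their paperwork (GenBank maps, manifests, recipes)
generated before touching a pipette.

No external sequence data is needed: a deterministic fixture generator
reproduces the published 64-brick inventory (27 promoter, 14 terminator,
6 marker, 10 genome-insertion, 5 gene bricks, 2 destination vectors) with
synthetic sequences, and a mock 3-gene xylose-utilization demonstration
mirrors the toolkit's flagship application.

## Worked example

```r
library(yaligg)
library(dplyr)

kit <- generate_toolkit(fixture_spec(seed = 42))
kit
#> <gg_toolkit> 64 bricks (destination_vector: 2, gene: 5, insertion_sequence: 10,
#>              marker: 6, promoter: 27, terminator: 14)

demo <- generate_xylose_demo(seed = 42, toolkit = kit)
count_fragments(demo$design, demo$toolkit)
#> [1] 13

glance(demo$product)
#> # A tibble: 1 × 5
#>   length_bp n_features n_junctions bsai_sites noti_sites
#> 1      9282         13          13          0          2

tidy(demo$product) |> select(slot, name, start, end)
#> # A tibble: 13 × 4
#>    slot     name           start   end
#>  1 Backbone GGE029             0  2308
#>  2 InsUp    ZETA_UP_NotI    2308  2829
#>  3 Marker   URA3            2829  4168
#>  4 Prom1    pTEF            4168  4520
#>  5 Gene1    ylXDH           4520  5253
#>  6 Term1    TLip2           5253  5375
#>  7 Prom2    pTEF            5375  5990
#>  8 Gene2    ylXR            5990  6921
#>  9 Term2    TLip2           6921  7020
#> 10 Prom3    pTEF            7020  7785
#> 11 Gene3    ylXK            7785  8593
#> 12 Term3    TLip2           8593  8679
#> 13 InsDown  ZETA_DOWN_NotI  8679  9282
```

Thirteen molecules (twelve bricks plus the destination vector) closed into
a single 9,282-bp circle with zero remaining BsaI sites; the feature order
reproduces the flagship layout
`ZUpNotI_URA_P1Tef_XDH_T1Lip2_P2Tef_XR_T2Lip2_P3Tef_XK_T3Lip2_ZDNotI`.
Verification and bench paperwork:

```r
notI_release(demo$product)   # cassette release before yeast transformation
#> # A tibble: 2 × 4
#>   start   end length is_cassette
#> 1  2314  9276   6966 TRUE
#> 2  9276  2314   2324 FALSE

make_protocol("standard_one_pot", 13)
#> <gg_protocol> standard_one_pot: 13 molecules x 50 pmol; BsaI 5 U,
#>               T4 ligase 200 U, buffer 2 ul, final 20 ul
#>   [37 C 5 min / 16 C 2 min] x 60, then 55 C 5 min, 80 C 5 min

integration_rate(5, 37, "round")     # locus-replacement screening arithmetic
#> [1] 14
integration_rate(11, 24, "truncate")
#> [1] 45
```

The two NotI fragments sum (counting each 4-nt junction once) to the
plasmid length; the 6,966-bp cassette carries the marker and all three TUs.
`write_genbank()` exports the annotated map; `autoplot(demo$product)` draws
it. A thin command-line wrapper is installed at
`inst/scripts/yaligg` (subcommands `validate`, `assemble`, `domesticate`,
`enumerate`, `protocol`, `qc`, `fixtures`, `demo`).

See the vignette `vignettes/golden-gate-design.Rmd` for the model,
conventions, fixture design and limitations.

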