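Package: yaligg
Title: Design and Simulation of Modular Golden Gate Assembly for Yarrowia lipolytica
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico companion to a modular Golden Gate cloning
    standard for the oleaginous yeast Yarrowia lipolytica. Implements the
    thirteen-letter (A-M) junction grammar for one-pot assembly of up to
    three transcription units plus a selection marker and genome-integration
    flanks, exact BsaI/NotI cut-geometry simulation, brick validation,
    codon-preserving domestication of coding sequences, adapter-primer
    design, combinatorial design enumeration, bench protocol generation and
    construct QC prediction (NotI cassette release, colony-PCR sizing). A
    deterministic fixture generator reproduces the toolkit's 64-brick
    inventory with synthetic sequences so the whole pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
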