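#' Fixture generation specification
#'
#' Controls the deterministic synthetic toolkit: seed, overhang set,
#' category counts and payload length ranges. The default counts reproduce
#' the published inventory (27 promoter, 14 terminator, 6 marker, 10
#' genome-insertion, 5 gene bricks and 2 destination vectors = 64); payload
#' lengths are realistic part sizes, with mock genes as 600-1500 nt open
#' reading frames. All sequences are synthetic: real promoter, marker and
#' locus identities appear as annotations only.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param overhangs Junction letter table (validated).
#' @param counts Named vector of category counts.
#' @param lengths Named list of `c(min, max)` payload lengths per category.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L,
                         overhangs = default_overhangs(),
                         counts = c(promoter = 27L, terminator = 14L,
                           marker = 6L, insertion = 10L, gene = 5L,
                           destination_vector = 2L),
                         lengths = list(
                           promoter = c(300L, 800L),
                           terminator = c(80L, 200L),
                           marker = c(1000L, 1600L),
                           insertion = c(400L, 700L),
                           gene = c(600L, 1500L),
                           backbone = c(2000L, 2500L),
                           dropout = c(600L, 800L))) {
  v <- validate_overhang_set(overhangs)
  if (!v$pass) {
    rlang::abort(paste0("overhang set fails validation:\n",
      paste(v$issues$detail, collapse = "\n")), class = "yaligg_bad_overhangs")
  }
  structure(list(seed = as.integer(seed), overhangs = overhangs,
    counts = counts, lengths = lengths), class = "fixture_spec")
}

# full deterministic 64-brick catalogue; per-category order puts the bricks
# a minimal kit needs first, so truncated counts stay assemblable
toolkit_catalog <- function() {
  prom_names <- c("pTEF", "pPGM", "pGAP", "2UAS-pTEF", "4UAS-pTEF",
    "8UAS-pTEF", "3UAS-pEYK1", "4UAS-pEYK1", "5UAS-pEYK1")
  prom_strength <- c("strong", "weak", "weak", "strong", "very_strong",
    "very_strong", "inducible", "inducible", "inducible")
  slot_letters <- list(
    Prom1 = c("C", "D"), Prom2 = c("F", "G"), Prom3 = c("I", "J"),
    Gene1 = c("D", "E"), Gene2 = c("G", "H"), Gene3 = c("J", "K"),
    Term1 = c("E", "F"), Term2 = c("H", "I"), Term3 = c("K", "L")
  )
  rows <- list()
  add <- function(id, category, slot, lr, name = id, strength = NA,
                  notes = NA, provides = slot) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, category = category, slot = slot,
      left_letter = lr[1], right_letter = lr[2], name = name,
      strength = strength, notes = notes, provides = list(provides))
  }
  # promoters: position 1 first so a 1-brick promoter kit drives TU1
  for (pos in 1:3) {
    for (i in seq_along(prom_names)) {
      slot <- paste0("Prom", pos)
      add(sprintf("%s_P%d", gsub("-", "", prom_names[i]), pos), "promoter",
        slot, slot_letters[[slot]], name = prom_names[i],
        strength = prom_strength[i])
    }
  }
  # terminators: shortcut bricks first (minimal kits are 1-TU)
  add("TLip2_EL", "terminator", "Term1", c("E", "L"), name = "TLip2",
    notes = "1-TU shortcut terminator")
  add("TLip2_HL", "terminator", "Term2", c("H", "L"), name = "TLip2",
    notes = "2-TU shortcut terminator")
  term_names <- c("TLip2", "TTef", "T1Guo", "TSynth8", "TSynth15")
  # 14 terminator bricks total; the per-position breakdown is a
  # reconstruction (flagged in notes)
  term_layout <- list(TLip2 = 1:3, TTef = 1:3, T1Guo = 1:3, TSynth8 = 1:2,
    TSynth15 = 1L)
  for (nm in term_names) {
    for (pos in term_layout[[nm]]) {
      slot <- paste0("Term", pos)
      add(sprintf("%s_T%d", nm, pos), "terminator", slot,
        slot_letters[[slot]], name = nm,
        notes = "position breakdown reconstructed to match inventory count")
    }
  }
  # markers
  marker_notes <- c(URA3 = NA, LEU2 = NA, LYS5 = NA,
    hph = "embeds pTEF promoter and TLip2 terminator",
    nat1 = "embeds pTEF promoter and TLip2 terminator",
    SUC2 = "metabolic marker: S. cerevisiae invertase, growth on sucrose")
  for (nm in names(marker_notes)) {
    add(nm, "marker", "Marker", c("B", "C"), notes = marker_notes[[nm]])
  }
  # genome-insertion flanks: ZETA plain + NotI-flanked variants, then the
  # locus-replacement pairs (integration deletes the locus)
  ins <- list(
    c("ZETA_UP", "insertion_up", "InsUp", "random integration (zeta docking)"),
    c("ZETA_DOWN", "insertion_down", "InsDown", "random integration (zeta docking)"),
    c("ZETA_UP_NotI", "insertion_up", "InsUp", "NotI-flanked for cassette release"),
    c("ZETA_DOWN_NotI", "insertion_down", "InsDown", "NotI-flanked for cassette release"),
    c("LIP2_UP", "insertion_up", "InsUp", "locus replacement: deletes LIP2"),
    c("LIP2_DOWN", "insertion_down", "InsDown", "locus replacement: deletes LIP2"),
    c("GSY1_UP", "insertion_up", "InsUp", "locus replacement: deletes GSY1"),
    c("GSY1_DOWN", "insertion_down", "InsDown", "locus replacement: deletes GSY1"),
    c("MFE_UP", "insertion_up", "InsUp", "locus replacement: deletes MFE"),
    c("MFE_DOWN", "insertion_down", "InsDown", "locus replacement: deletes MFE")
  )
  for (x in ins) {
    lr <- if (x[3] == "InsUp") c("A", "B") else c("L", "M")
    add(x[1], x[2], x[3], lr, notes = x[4])
  }
  # validation genes (fluorescent reporters)
  add("RedStarII_G1", "gene", "Gene1", slot_letters$Gene1, name = "RedStarII")
  add("YFP_G2", "gene", "Gene2", slot_letters$Gene2, name = "YFP")
  add("mTurquoise_G3", "gene", "Gene3", slot_letters$Gene3, name = "mTurquoise")
  add("RedStarII_G2", "gene", "Gene2", slot_letters$Gene2, name = "RedStarII")
  add("RedStarII_G3", "gene", "Gene3", slot_letters$Gene3, name = "RedStarII")
  # destination vectors
  add("GGE029", "destination_vector", "Backbone", c("M", "A"),
    notes = "RFP dropout between BsaI junctions A and M; AmpR + ColE1 mock backbone")
  add("GGE114", "destination_vector", "Backbone", c("L", "C"),
    notes = "preassembled: ZETA flanks + URA3 on the backbone, RFP dropout between URA3 and ZETA down",
    provides = c("Backbone", "InsUp", "Marker", "InsDown"))
  dplyr::bind_rows(rows)
}

# random ORF: ATG + non-stop codons + TAA, domesticated BsaI/NotI-free
random_orf <- function(len_range, table = codon_table()) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(names(table$codon_to_aa), stops)
  for (i in 1:20) {
    n_codons <- sample(seq(len_range[1] %/% 3, len_range[2] %/% 3), 1)
    body <- paste(sample(codons, n_codons - 2L, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, "TAA")
    dom <- tryCatch(
      domesticate_cds(orf, forbidden = list("BsaI", "NotI"), table = table),
      error = function(e) NULL)
    if (!is.null(dom)) return(dom$seq)
  }
  rlang::abort("could not generate a clean ORF", class = "yaligg_rng_fail")
}

rand_len <- function(range) sample(seq(range[1], range[2]), 1)

#' Generate the synthetic toolkit fixture
#'
#' Builds a complete, deterministic toolkit whose inventory matches the
#' published manifest (default 64 bricks) with synthetic sequences: every
#' brick passes [check_brick()], promoters/markers/loci carry their real
#' names as annotations, and the two destination vectors carry an RFP
#' dropout that is excluded from every assembly. Same seed, same bytes.
#'
#' @param spec A [fixture_spec()].
#' @return A `gg_toolkit`.
#' @examples
#' \donttest{
#' kit <- generate_toolkit(fixture_spec(seed = 42))
#' manifest_counts(kit)
#' }
#' @export
generate_toolkit <- function(spec = fixture_spec()) {
  catalog <- toolkit_catalog()
  counts <- spec$counts
  keep <- list(
    promoter = counts[["promoter"]],
    terminator = counts[["terminator"]],
    marker = counts[["marker"]],
    insertion = counts[["insertion"]],
    gene = counts[["gene"]],
    destination_vector = counts[["destination_vector"]]
  )
  cat_key <- ifelse(catalog$category %in% c("insertion_up", "insertion_down"),
    "insertion", catalog$category)
  sel <- unlist(purrr::map(names(keep), function(k) {
    idx <- which(cat_key == k)
    if (keep[[k]] > length(idx)) {
      rlang::abort(sprintf("catalogue has only %d %s bricks (%d requested)",
        length(idx), k, keep[[k]]), class = "yaligg_bad_spec")
    }
    idx[seq_len(keep[[k]])]
  }))
  catalog <- catalog[sort(sel), ]
  table <- codon_table()
  withr::with_seed(spec$seed, {
    bricks <- purrr::map(seq_len(nrow(catalog)), function(i) {
      row <- catalog[i, ]
      L <- spec$lengths
      payload <- switch(row$category,
        promoter = random_dna(rand_len(L$promoter), c("GGTCTC", "GCGGCCGC")),
        terminator = random_dna(rand_len(L$terminator), c("GGTCTC", "GCGGCCGC")),
        marker = random_orf(L$marker, table),
        gene = random_orf(L$gene, table),
        insertion_up = {
          body <- random_dna(rand_len(L$insertion), c("GGTCTC", "GCGGCCGC"))
          if (grepl("NotI", row$id)) paste0("GCGGCCGC", body) else body
        },
        insertion_down = {
          body <- random_dna(rand_len(L$insertion), c("GGTCTC", "GCGGCCGC"))
          if (grepl("NotI", row$id)) paste0(body, "GCGGCCGC") else body
        },
        destination_vector = random_dna(rand_len(L$backbone),
          c("GGTCTC", "GCGGCCGC"))
      )
      plasmid <- brick_plasmid(payload, row$left_letter, row$right_letter,
        spec$overhangs,
        stuffer_len = if (row$category == "destination_vector")
          rand_len(L$dropout) else 400L)
      gg_brick(row$id, row$category, row$slot, row$left_letter,
        row$right_letter, payload, spec$overhangs, plasmid = plasmid,
        name = row$name, strength = row$strength, notes = row$notes,
        provides = row$provides[[1]])
    })
    gg_toolkit(dplyr::bind_rows(bricks), spec$overhangs, meta = list(
      name = "yaligg synthetic toolkit fixture",
      provenance = "synthetic sequences; inventory mirrors the physical collection (Addgene 120730-120793)",
      seed = spec$seed
    ))
  })
}

#' Write a toolkit to disk (GenBank bricks + manifest)
#'
#' One GenBank file per brick donor plasmid (payload and flank features
#' annotated) plus `manifest.yaml`. Deterministic: no timestamps.
#'
#' @param toolkit A `gg_toolkit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toolkit <- function(toolkit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(toolkit$bricks))) {
    b <- toolkit$bricks[i, ]
    lo <- overhang_seq(b$left_letter, toolkit$overhangs)
    pay_start <- 7L + 4L  # GGTCTCA + left overhang
    feats <- tibble::tibble(
      start = c(pay_start - 4L, pay_start, pay_start + nchar(b$payload)),
      end = c(pay_start, pay_start + nchar(b$payload),
        pay_start + nchar(b$payload) + 4L),
      name = c(sprintf("overhang_%s", b$left_letter), b$name,
        sprintf("overhang_%s", b$right_letter)),
      slot = c(NA, b$slot, NA),
      category = c(NA, b$category, NA),
      letter = c(b$left_letter, NA, b$right_letter)
    )
    write_genbank(dna_seq(b$plasmid, circular = TRUE, name = b$id),
      file.path(dir, paste0(b$id, ".gb")), features = feats)
  }
  write_manifest(toolkit, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' The 3-gene xylose-pathway demonstration
#'
#' Mirrors the toolkit's flagship application: a single 3-TU plasmid
#' overexpressing the xylose utilization pathway (xylitol dehydrogenase
#' ylXDH in position 1, xylose reductase ylXR in position 2, xylulokinase
#' ylXK in position 3; the Y. lipolytica loci YALI0E12463g, YALI0D07634g
#' and YALIF10923g are cited as names only -- the payloads are mock ORFs).
#' The layout reproduces the published construct string
#' `ZUpNotI_URA_P1Tef_XDH_T1Lip2_P2Tef_XR_T2Lip2_P3Tef_XK_T3Lip2_ZDNotI`:
#' pTEF/TLip2 in every TU, URA3 marker, NotI-flanked ZETA integration
#' flanks, GGE029 destination vector.
#'
#' @param seed Seed for the gene-brick mock ORFs.
#' @param toolkit Toolkit fixture to extend (default: full fixture built
#'   from the same seed).
#' @return List with `design` (a [gg_design()]), `toolkit` (input toolkit
#'   plus the three gene bricks) and `product` (the assembled
#'   `gg_construct`).
#' @export
generate_xylose_demo <- function(seed = 42L,
                                 toolkit = generate_toolkit(fixture_spec(seed = seed))) {
  genes <- list(
    c("ylXDH", "Gene1", "D", "E", "xylitol dehydrogenase (locus YALI0E12463g, name only)"),
    c("ylXR", "Gene2", "G", "H", "xylose reductase (locus YALI0D07634g, name only)"),
    c("ylXK", "Gene3", "J", "K", "xylulokinase (locus YALIF10923g, name only)")
  )
  table <- codon_table()
  gene_seed <- (as.integer(seed) %% 2147483646L) + 1L  # distinct from the kit seed, within integer range
  gene_bricks <- withr::with_seed(gene_seed, {
    purrr::map(genes, function(g) {
      gg_brick(g[1], "gene", g[2], g[3], g[4],
        random_orf(c(600L, 1500L), table), toolkit$overhangs,
        name = g[1], notes = g[5])
    })
  })
  toolkit$bricks <- dplyr::bind_rows(toolkit$bricks, gene_bricks)
  design <- gg_design("3TU", c(
    InsUp = "ZETA_UP_NotI", Marker = "URA3",
    Prom1 = "pTEF_P1", Gene1 = "ylXDH", Term1 = "TLip2_T1",
    Prom2 = "pTEF_P2", Gene2 = "ylXR", Term2 = "TLip2_T2",
    Prom3 = "pTEF_P3", Gene3 = "ylXK", Term3 = "TLip2_T3",
    InsDown = "ZETA_DOWN_NotI"
  ), vector_id = "GGE029")
  list(design = design, toolkit = toolkit,
    product = simulate_one_pot(design, toolkit))
}
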