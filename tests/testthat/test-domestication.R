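test_that("the codon table matches the standard genetic code", {
  tab <- codon_table()
  expect_length(tab$codon_to_aa, 64)
  # spot-check translation against the Biostrings reference
  withr::with_seed(41, {
    for (i in 1:10) {
      n_codons <- sample(20:100, 1)
      s <- paste(sample(names(tab$codon_to_aa), n_codons, replace = TRUE),
        collapse = "")
      want <- as.character(Biostrings::translate(Biostrings::DNAString(s),
        no.init.codon = TRUE))
      expect_identical(translate_cds(s, tab), want)
    }
  })
})

test_that("a site spanning substitutable codons is removed by one synonymous edit", {
  # ...GGT CTC... : Gly-Leu across the BsaI site; both have synonyms
  cds <- paste0("ATG", "GGT", "CTC", "AAA", "TAA")
  expect_equal(nrow(find_recognition_sites(dna_seq(cds), "BsaI")), 1)
  out <- domesticate_cds(cds)
  edits <- attr(out, "edits")
  expect_equal(nrow(edits), 1)
  expect_equal(nrow(find_recognition_sites(out, "BsaI")), 0)
  expect_identical(translate_cds(out$seq), translate_cds(cds))
  # wobble-first preference: the third-position change GGT->GGC kills the site
  expect_equal(edits$from, "GGT")
  expect_equal(substr(edits$to, 1, 2), "GG")
})

test_that("clean sequences come back unchanged with an empty edit log", {
  cds <- "ATGGCTGCAAAGTAA"
  out <- domesticate_cds(cds)
  expect_identical(out$seq, cds)
  expect_equal(nrow(attr(out, "edits")), 0)
})

test_that("domestication contract: non-triplet length errors, missing ATG warns", {
  expect_error(domesticate_cds("ATGGC"), class = "yaligg_bad_cds")
  expect_warning(domesticate_cds("CCTGGTAAACCT"), "ATG")
})

test_that("100 random CDSs with planted sites all come out site-free and translation-identical", {
  tab <- codon_table()
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(names(tab$codon_to_aa), stops)
  withr::with_seed(202, {
    n_unresolvable <- 0
    for (i in 1:100) {
      n_codons <- sample(60:200, 1)
      s <- paste0("ATG",
        paste(sample(codons, n_codons, replace = TRUE), collapse = ""), "TAA")
      # plant 1-3 sites at codon boundaries or mid-codon
      for (k in seq_len(sample(1:3, 1))) {
        p <- sample(seq(4, nchar(s) - 12), 1)
        motif <- sample(c("GGTCTC", "GAGACC", "GCGGCCGC"), 1)
        s <- paste0(substr(s, 1, p - 1), motif,
          substr(s, p + nchar(motif), nchar(s)))
      }
      aa_before <- translate_cds(s, tab)
      out <- tryCatch(
        suppressWarnings(domesticate_cds(s, forbidden = list("BsaI", "NotI"), table = tab)),
        error = function(e) e)
      if (inherits(out, "yaligg_unresolvable_site")) {
        n_unresolvable <- n_unresolvable + 1
        next
      }
      expect_equal(nrow(find_recognition_sites(out, "BsaI")), 0)
      expect_equal(nrow(find_recognition_sites(out, "NotI")), 0)
      # translation preservation checked codon-by-codon against the
      # reference translator, not the editor's own bookkeeping
      expect_identical(
        as.character(Biostrings::translate(Biostrings::DNAString(out$seq),
          no.init.codon = TRUE)),
        aa_before)
    }
    # planted sites overwhelmingly span editable codons
    expect_lt(n_unresolvable, 10)
  })
})

test_that("unresolvable sites raise an error with coordinates", {
  # a BsaI site over editable codons (Val/Ser) must succeed ...
  cds <- paste0("ATG", "GTC", "TCG", "TAA")
  expect_equal(nrow(find_recognition_sites(dna_seq(cds), "BsaI")), 1)
  expect_equal(nrow(find_recognition_sites(domesticate_cds(cds), "BsaI")), 0)
  # ... whereas a site spelled entirely by Met/Trp codons (no synonyms)
  # cannot be removed; GGTCTC cannot sit on Met/Trp alone, so use a custom
  # Type IIS spec whose recognition TGGATG lies on a Trp-Met pair
  enz <- enzyme_spec("TrpMetI", "TGGATG", spacer_len = 1, overhang_len = 4,
    cut_kind = "downstream_typeIIS")
  cds2 <- paste0("ATG", "TGG", "ATG", "AAA", "AAA", "TAA")
  expect_error(domesticate_cds(cds2, forbidden = list(enz)),
    class = "yaligg_unresolvable_site")
  err <- tryCatch(domesticate_cds(cds2, forbidden = list(enz)),
    error = function(e) e)
  expect_match(conditionMessage(err), "position 3")
})

test_that("adapter primers round-trip: digesting the amplicon releases the slot overhangs", {
  oh <- default_overhangs()
  withr::with_seed(61, {
    for (i in 1:10) {
      letters2 <- sample(oh$letter, 2)
      tpl <- random_dna(sample(60:400, 1), avoid = c("GGTCTC", "GCGGCCGC"))
      pp <- design_adapter_primers(tpl, letters2[1], letters2[2], oh)
      amp <- attr(pp, "amplicon")
      d <- digest(dna_seq(amp), "BsaI")
      mid <- d[!is.na(d$left_overhang) & d$left_overhang != "" &
        d$right_overhang != "", ]
      expect_equal(nrow(mid), 1)
      expect_equal(mid$left_overhang, oh$sequence[oh$letter == letters2[1]])
      expect_equal(mid$right_overhang, oh$sequence[oh$letter == letters2[2]])
      expect_equal(mid$seq, paste0(
        oh$sequence[oh$letter == letters2[1]], tpl,
        oh$sequence[oh$letter == letters2[2]]))
      # and the simulated cloned brick passes check_brick
      brick <- gg_brick(paste0("rt", i), "promoter", "Prom1", letters2[1],
        letters2[2], tpl, oh)
      brick$left_letter <- letters2[1]
      v <- check_brick(brick, oh)
      expect_true(all(setdiff(tidy(v)$check, "slot_letters") == ""))
    }
  })
})

test_that("annealing length floors at 18 nt and grows to meet the Tm target", {
  tpl <- strrep("AT", 60)  # Tm grows 4 C per 2 nt
  pp <- design_adapter_primers(tpl, "D", "E", tm_target = 0)
  expect_equal(pp$anneal_len, c(18L, 18L))
  pp <- design_adapter_primers(tpl, "D", "E", tm_target = 50)
  expect_true(all(pp$anneal_len > 18))
  expect_true(all(pp$tm >= 50))
  expect_equal(pp$tm, tm_wallace(pp$anneal))
})

test_that("primer design warns on internal BsaI sites and rejects short templates", {
  expect_error(design_adapter_primers(strrep("A", 30), "D", "E"),
    class = "yaligg_bad_template")
  dirty <- paste0(strrep("ACGT", 15), "GGTCTC", strrep("TGCA", 15))
  expect_warning(design_adapter_primers(dirty, "D", "E"), "domesticate")
})
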