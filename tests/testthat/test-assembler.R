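test_that("fragment counts are 7, 10 and 13 for 1-, 2- and 3-TU designs", {
  kit <- test_toolkit()
  expect_equal(count_fragments(test_design_3tu(), kit), 13)
  expect_equal(count_fragments(test_design_2tu(), kit), 10)
  expect_equal(count_fragments(test_design_1tu(), kit), 7)
})

test_that("a preassembled destination vector reduces the pot accordingly", {
  kit <- test_toolkit()
  design <- gg_design("3TU", c(
    Prom1 = "pTEF_P1", Gene1 = "RedStarII_G1", Term1 = "TLip2_T1",
    Prom2 = "pTEF_P2", Gene2 = "YFP_G2", Term2 = "TLip2_T2",
    Prom3 = "pTEF_P3", Gene3 = "mTurquoise_G3", Term3 = "TLip2_T3"
  ), vector_id = "GGE114")
  expect_equal(count_fragments(design, kit), 10)
  product <- simulate_one_pot(design, kit)
  expect_equal(nrow(find_recognition_sites(product$plasmid, "BsaI")), 0)
})

test_that("one-pot simulation of a full 3-TU design gives one clean circular product", {
  kit <- test_toolkit()
  design <- test_design_3tu()
  product <- simulate_one_pot(design, kit)
  expect_s3_class(product, "gg_construct")
  expect_true(product$plasmid$circular)
  expect_equal(nrow(find_recognition_sites(product$plasmid, "BsaI")), 0)
  expect_equal(nrow(product$features), 13)
  # features tile the circle without gaps
  expect_equal(product$features$start[-1], product$features$end[-13])
  # junction letters appear in grammar order
  expect_identical(product$junctions$letter, c("M", LETTERS[1:12]))
  expect_identical(sort(product$junctions$letter), sort(LETTERS[1:13]))
  # length accounting: payloads + 13 junctions
  b <- kit$bricks
  pay <- sum(nchar(b$payload[match(design$brick_id, b$id)]))
  expect_equal(length(product$plasmid), pay + 13 * 4)
})

test_that("omitting a brick raises an open-junction error naming its letters", {
  kit <- test_toolkit()
  design <- test_design_3tu()
  broken <- design[design$slot != "Gene2", ]
  attr(broken, "topology") <- "3TU"
  expect_error(validate_design(broken, kit), class = "yaligg_bad_design")
  # bypass design validation to exercise the ligation-level diagnosis
  frs <- dplyr::bind_rows(purrr::map(broken$brick_id, function(id) {
    yaligg:::released_fragment(yaligg:::toolkit_brick(kit, id))
  }))
  err <- tryCatch(ligate_fragments(frs, kit$overhangs), error = function(e) e)
  expect_s3_class(err, "yaligg_open_junction")
  expect_match(conditionMessage(err), "G")
  expect_match(conditionMessage(err), "H")
})

test_that("the RFP dropout never appears in a product", {
  kit <- test_toolkit()
  vec <- kit$bricks[kit$bricks$id == "GGE029", ]
  d <- digest(dna_seq(vec$plasmid, circular = TRUE), "BsaI")
  dropout <- d$seq[vapply(d$seq, function(s) grepl("GGTCTC", s) || grepl("GAGACC", s), TRUE)]
  core <- substr(dropout, 20, nchar(dropout) - 20)  # interior, flank-agnostic
  for (design in list(test_design_1tu(), test_design_2tu(), test_design_3tu())) {
    product <- simulate_one_pot(design, kit)
    expect_false(grepl(core, product$plasmid$seq, fixed = TRUE))
  }
})

test_that("input order never changes the canonical product", {
  kit <- test_toolkit()
  design <- test_design_3tu()
  ref <- simulate_one_pot(design, kit)$canonical
  withr::with_seed(31, {
    for (i in 1:5) {
      shuffled <- design[sample(nrow(design)), ]
      attr(shuffled, "topology") <- "3TU"
      expect_identical(simulate_one_pot(shuffled, kit)$canonical, ref)
    }
  })
})

test_that("closure uniqueness matches brute-force cycle enumeration", {
  kit <- test_toolkit()
  # small pots: permutation brute force
  for (design in list(test_design_1tu())) {
    frs <- dplyr::bind_rows(purrr::map(design$brick_id, function(id) {
      yaligg:::released_fragment(yaligg:::toolkit_brick(kit, id))
    }))
    expect_equal(oracle_closure_count(frs$left_overhang, frs$right_overhang), 1)
    expect_s3_class(ligate_fragments(frs, kit$overhangs)$plasmid, "dna_seq")
  }
  # 13-fragment pot: with unique overhangs the successor map is a
  # permutation; a unique closure is exactly a single 13-cycle
  design <- test_design_3tu()
  frs <- dplyr::bind_rows(purrr::map(design$brick_id, function(id) {
    yaligg:::released_fragment(yaligg:::toolkit_brick(kit, id))
  }))
  succ <- match(frs$right_overhang, frs$left_overhang)
  expect_false(anyNA(succ))
  expect_equal(sort(succ), seq_len(13))  # a permutation
  cyc_len <- 1
  at <- succ[1]
  while (at != 1) { at <- succ[at]; cyc_len <- cyc_len + 1 }
  expect_equal(cyc_len, 13)
})

test_that("redundant overhangs are diagnosed as ambiguous closures", {
  # two interchangeable middle fragments: x-A-y-B-x and x-A-y'-B-x both close
  frs <- tibble::tibble(
    seq = c("AAAACCCCGGGG", "GGGGTTTTAAAA", "GGGGACGTACGTAAAA"),
    left_overhang = c("AAAA", "GGGG", "GGGG"),
    right_overhang = c("GGGG", "AAAA", "AAAA"),
    source = c("anchor", "alt1", "alt2")
  )
  err <- tryCatch(ligate_fragments(frs), error = function(e) e)
  # three fragments cannot all be used in one circle here: this is an open
  # junction (no single Hamiltonian closure), not ambiguity
  expect_s3_class(err, "yaligg_open_junction")
  # a genuinely ambiguous pot: two interchangeable A->B / B->A pairs admit
  # two distinct circular closures using every fragment
  frs4 <- tibble::tibble(
    seq = c("AAAACCCCGGGG", "GGGGTTTTAAAA", "AAAACGCGGGGG", "GGGGTATAAAAA"),
    left_overhang = c("AAAA", "GGGG", "AAAA", "GGGG"),
    right_overhang = c("GGGG", "AAAA", "GGGG", "AAAA"),
    source = c("a", "b1", "c", "b2")
  )
  err <- tryCatch(ligate_fragments(frs4), error = function(e) e)
  expect_s3_class(err, "yaligg_ambiguous_closure")
  expect_equal(oracle_closure_count(frs4$left_overhang, frs4$right_overhang), 2)
})

test_that("preassembly plan reproduces the printed three 4-part groups", {
  kit <- test_toolkit()
  design <- test_design_3tu()
  plan <- plan_preassembly(design, kit)
  expect_equal(as.integer(table(plan$reaction)), c(4L, 4L, 4L))
  expect_identical(plan$slot[plan$reaction == 1],
    c("InsUp", "Marker", "Prom1", "Gene1"))
  expect_identical(plan$slot[plan$reaction == 2],
    c("Term1", "Prom2", "Gene2", "Term2"))
  expect_identical(plan$slot[plan$reaction == 3],
    c("Prom3", "Gene3", "Term3", "InsDown"))
  expect_identical(attr(plan, "final_inputs")[4], "GGE029")
  expect_error(plan_preassembly(test_design_1tu(), kit),
    class = "yaligg_unsupported_topology")
})

test_that("preassembly and direct routes give canonically identical plasmids", {
  kit <- test_toolkit()
  withr::with_seed(77, {
    for (i in 1:10) {
      design <- random_design_3tu(kit)
      direct <- simulate_one_pot(design, kit)
      split <- simulate_preassembly(design, kit)
      expect_identical(split$canonical, direct$canonical)
      expect_identical(split$features$brick_id, direct$features$brick_id)
    }
  })
})

test_that("design enumeration counts the Cartesian product and samples deterministically", {
  opts9 <- stats::setNames(rep(list("x"), 12), setdiff(gg_slots(), "Backbone"))
  for (s in c("Prom1", "Prom2", "Prom3")) {
    opts9[[s]] <- sprintf("p%02d", 1:9)
  }
  grid <- enumerate_designs(opts9, "3TU", "V")
  expect_equal(attr(grid, "n_designs"), 729)
  expect_equal(nrow(grid), 729)
  expect_false(anyDuplicated(grid) > 0)

  one <- purrr::map(opts9, ~ .x[1])
  g1 <- enumerate_designs(one, "3TU", "V")
  expect_equal(attr(g1, "n_designs"), 1)

  expect_error(enumerate_designs(one[-3], "3TU", "V"), class = "yaligg_bad_design")
  bad <- one
  bad$Prom1 <- character()
  expect_error(enumerate_designs(bad, "3TU", "V"), class = "yaligg_bad_design")

  # random grids: count equals the product of option counts
  withr::with_seed(13, {
    for (i in 1:10) {
      opts <- purrr::map(stats::setNames(
        rep(list(NULL), 12), setdiff(gg_slots(), "Backbone")),
        ~ sprintf("b%d", seq_len(sample(1:4, 1))))
      grid <- enumerate_designs(opts, "3TU", "V")
      expect_equal(attr(grid, "n_designs"), prod(lengths(opts)))
      expect_equal(nrow(dplyr::distinct(grid)), nrow(grid))
    }
  })

  # seeded sampling is reproducible and within the space
  s1 <- enumerate_designs(opts9, "3TU", "V", sample_k = 20, seed = 99)
  s2 <- enumerate_designs(opts9, "3TU", "V", sample_k = 20, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20)
  expect_true(all(s1$Prom1 %in% opts9$Prom1))
})

test_that("27 distinct promoter bricks cover 9 options at each of three positions", {
  kit <- test_toolkit()
  proms <- kit$bricks[kit$bricks$category == "promoter", ]
  expect_equal(nrow(proms), 27)
  expect_equal(as.integer(table(proms$slot)[c("Prom1", "Prom2", "Prom3")]), c(9L, 9L, 9L))
  expect_equal(length(unique(proms$id)), 27)
  opts <- list(
    Prom1 = proms$id[proms$slot == "Prom1"],
    Prom2 = proms$id[proms$slot == "Prom2"],
    Prom3 = proms$id[proms$slot == "Prom3"],
    Gene1 = "RedStarII_G1", Gene2 = "YFP_G2", Gene3 = "mTurquoise_G3",
    Term1 = "TLip2_T1", Term2 = "TLip2_T2", Term3 = "TLip2_T3",
    InsUp = "ZETA_UP", InsDown = "ZETA_DOWN", Marker = "URA3"
  )
  expect_equal(attr(enumerate_designs(opts, "3TU", "GGE029"), "n_designs"), 729)
})
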