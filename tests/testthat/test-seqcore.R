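test_that("sequence ingest rejects ambiguity and revcomp is an involution", {
  expect_error(dna_seq("ACGTN"), class = "yaligg_ambiguous_base")
  expect_error(dna_seq("ACGRT"), class = "yaligg_ambiguous_base")
  expect_error(dna_seq(""), class = "yaligg_empty_seq")
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- random_dna(sample(1:200, 1))
      expect_identical(revcomp(revcomp(s)), s)
    }
  })
  # cross-check against Biostrings on a few molecules
  withr::with_seed(8, {
    for (i in 1:5) {
      s <- random_dna(500)
      expect_identical(revcomp(s),
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
    }
  })
})

test_that("recognition-site scan finds literal and bottom-strand hits once each", {
  hits <- find_recognition_sites(dna_seq("GGTCTCAAATT"), "BsaI")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 0)
  expect_equal(hits$strand, "top")

  hits <- find_recognition_sites(dna_seq("AAGAGACCAA"), "BsaI")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "bottom")

  # palindromic NotI site reported once
  hits <- find_recognition_sites(dna_seq("TTGCGGCCGCTT"), "NotI")
  expect_equal(nrow(hits), 1)
})

test_that("site scan matches a brute-force sliding-window oracle on random 10 kb sequences", {
  withr::with_seed(101, {
    for (circ in c(FALSE, TRUE)) {
      s <- random_dna(10000)
      # plant a few sites so the scan is not vacuous
      for (p in sample(1:9900, 4)) {
        motif <- sample(c("GGTCTC", "GAGACC"), 1)
        s <- paste0(substr(s, 1, p - 1), motif, substr(s, p + 6, nchar(s)))
      }
      got <- find_recognition_sites(dna_seq(s, circular = circ), "BsaI")
      want <- oracle_scan(s, "GGTCTC", circular = circ)
      want <- want[order(want$position, want$strand), ]
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
    }
  })
})

test_that("circular scan reports origin-spanning sites", {
  # GGTCTC split across the origin: ...TC | GGTC...
  s <- paste0("TCAAAAAAAAAAGG")  # circular: GG + TC = GGTC TC? build precisely
  s <- paste0("TCTCAAAAAAAAGG")  # rotation: GG|TCTC... -> GGTCTC at origin
  hits <- find_recognition_sites(dna_seq(s, circular = TRUE), "BsaI")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 12)
  expect_equal(nrow(find_recognition_sites(dna_seq(s, circular = FALSE), "BsaI")), 0)
})

test_that("BsaI digestion has exact 1/5 cut geometry", {
  # GGTCTC + 1-nt spacer, then the 4-nt overhang AATT
  d <- digest(dna_seq("AAAAGGTCTCAAATTGGGGCC"), "BsaI")
  expect_equal(nrow(d), 2)
  expect_equal(d$right_overhang[1], "AATT")
  expect_equal(d$left_overhang[2], "AATT")
  expect_equal(d$seq[2], "AATTGGGGCC")
  # blunt molecule ends
  expect_equal(d$left_overhang[1], "")
  expect_equal(d$right_overhang[2], "")
})

test_that("digestion conserves residues and is rotation-invariant on circles", {
  s <- paste0("AAAAGGTCTCAAATT", strrep("C", 30), "AAGAGACCTTTT", strrep("G", 20))
  circ <- dna_seq(s, circular = TRUE)
  d <- digest(circ, "BsaI")
  expect_equal(nrow(d), 2)
  expect_equal(sum(d$length) - 4 * nrow(d), nchar(s))
  for (by in c(3, 17, 40)) {
    d2 <- digest(rotate_seq(circ, by), "BsaI")
    expect_setequal(d2$seq, d$seq)
  }
})

test_that("zero-site digestion returns the molecule intact", {
  d <- digest(dna_seq("ACGTACGTACGT"), "BsaI")
  expect_equal(nrow(d), 1)
  expect_true(is.na(d$left_overhang))
  expect_equal(d$seq, "ACGTACGTACGT")
})

test_that("overlapping cuts raise a degenerate-geometry error", {
  # two convergent sites whose cuts land within 4 nt of each other
  s <- paste0("GGTCTC", "A", "AT", "T", "GAGACC", strrep("A", 20))
  expect_error(digest(dna_seq(s, circular = TRUE), "BsaI"),
    class = "yaligg_degenerate_geometry")
})

test_that("destination-vector digestion yields backbone A/M and complementary dropout", {
  kit <- test_toolkit()
  vec <- kit$bricks[kit$bricks$id == "GGE029", ]
  d <- digest(dna_seq(vec$plasmid, circular = TRUE), "BsaI")
  expect_equal(nrow(d), 2)
  oh <- kit$overhangs
  seq_of <- function(l) oh$sequence[oh$letter == l]
  free <- !vapply(d$seq, function(s) grepl("GGTCTC", s) || grepl("GAGACC", s), TRUE)
  backbone <- d[free, ]
  dropout <- d[!free, ]
  expect_equal(backbone$left_overhang, seq_of("M"))
  expect_equal(backbone$right_overhang, seq_of("A"))
  expect_equal(dropout$left_overhang, seq_of("A"))
  expect_equal(dropout$right_overhang, seq_of("M"))
})

test_that("canonical form identifies circular molecules up to rotation and strand", {
  expect_identical(canonical_form("ATGC", circular = TRUE),
    canonical_form("GCAT", circular = TRUE))
  expect_identical(canonical_form("AAAA", circular = TRUE), "AAAA")
  expect_identical(canonical_form("ACGT", circular = FALSE), "ACGT")
  withr::with_seed(11, {
    for (i in 1:200) {
      s <- random_dna(sample(10:300, 1))
      r <- rotate_seq(s, sample(0:nchar(s), 1))
      v <- if (runif(1) < 0.5) r else revcomp(r)
      expect_identical(canonical_form(s, circular = TRUE),
        canonical_form(v, circular = TRUE))
    }
    # all-rotations oracle on a handful of short molecules
    for (i in 1:10) {
      s <- random_dna(sample(4:12, 1))
      rots <- vapply(0:(nchar(s) - 1), function(b) rotate_seq(s, b), "")
      rots <- c(rots, revcomp(rots))
      expect_identical(canonical_form(s, circular = TRUE), min(rots))
    }
  })
})

test_that("digesting the reverse complement mirrors the fragment multiset", {
  withr::with_seed(303, {
    for (i in 1:25) {
      n_sites <- sample(0:3, 1)
      s <- random_dna(sample(150:600, 1), avoid = "GGTCTC")
      for (k in seq_len(n_sites)) {
        p <- sample(10:(nchar(s) - 20), 1)
        s <- paste0(substr(s, 1, p), sample(c("GGTCTC", "GAGACC"), 1),
          substr(s, p + 1, nchar(s)))
      }
      for (circ in c(FALSE, TRUE)) {
        d1 <- tryCatch(digest(dna_seq(s, circular = circ), "BsaI"),
          error = function(e) NULL)
        d2 <- tryCatch(digest(dna_seq(revcomp(s), circular = circ), "BsaI"),
          error = function(e) NULL)
        if (is.null(d1)) {
          expect_null(d2)  # degenerate geometry on both strands alike
        } else {
          expect_setequal(revcomp(d2$seq), d1$seq)
          expect_equal(sum(d1$length), sum(d2$length))
        }
      }
    }
  })
})
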