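# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

test_toolkit <- function() {
  if (is.null(.fixture_cache$kit)) {
    .fixture_cache$kit <- generate_toolkit(fixture_spec(seed = 42))
  }
  .fixture_cache$kit
}

test_demo <- function() {
  if (is.null(.fixture_cache$demo)) {
    .fixture_cache$demo <- generate_xylose_demo(seed = 42, toolkit = test_toolkit())
  }
  .fixture_cache$demo
}

# a complete 3-TU design over the full fixture kit
test_design_3tu <- function(gene1 = "RedStarII_G1", gene2 = "YFP_G2",
                            gene3 = "mTurquoise_G3") {
  gg_design("3TU", c(
    InsUp = "ZETA_UP", Marker = "URA3",
    Prom1 = "pTEF_P1", Gene1 = gene1, Term1 = "TLip2_T1",
    Prom2 = "pTEF_P2", Gene2 = gene2, Term2 = "TLip2_T2",
    Prom3 = "pTEF_P3", Gene3 = gene3, Term3 = "TLip2_T3",
    InsDown = "ZETA_DOWN"
  ), vector_id = "GGE029")
}

test_design_1tu <- function() {
  gg_design("1TU", c(
    InsUp = "ZETA_UP", Marker = "URA3", Prom1 = "pTEF_P1",
    Gene1 = "RedStarII_G1", Term1 = "TLip2_EL", InsDown = "ZETA_DOWN"
  ), vector_id = "GGE029")
}

test_design_2tu <- function() {
  gg_design("2TU", c(
    InsUp = "ZETA_UP", Marker = "URA3",
    Prom1 = "pTEF_P1", Gene1 = "RedStarII_G1", Term1 = "TLip2_T1",
    Prom2 = "pTEF_P2", Gene2 = "YFP_G2", Term2 = "TLip2_HL",
    InsDown = "ZETA_DOWN"
  ), vector_id = "GGE029")
}

# draw a random complete 3-TU design from the fixture kit (bricks whose
# letter pair matches the 3-TU grammar; shortcut terminators excluded)
random_design_3tu <- function(kit = test_toolkit()) {
  b <- kit$bricks
  g <- gg_grammar("3TU")
  pick <- function(slot) {
    row <- g[g$slot == slot, ]
    ok <- b$slot == slot & b$left_letter == row$left & b$right_letter == row$right
    ids <- b$id[ok]
    if (length(ids) == 1) ids else sample(ids, 1)
  }
  gg_design("3TU", c(
    InsUp = pick("InsUp"), Marker = pick("Marker"),
    Prom1 = pick("Prom1"), Gene1 = pick("Gene1"), Term1 = pick("Term1"),
    Prom2 = pick("Prom2"), Gene2 = pick("Gene2"), Term2 = pick("Term2"),
    Prom3 = pick("Prom3"), Gene3 = pick("Gene3"), Term3 = pick("Term3"),
    InsDown = pick("InsDown")
  ), vector_id = "GGE029")
}

# independent sliding-window scan for a motif on both strands (oracle for
# find_recognition_sites); returns 0-based positions
oracle_scan <- function(s, motif, circular = FALSE) {
  rc <- yaligg::revcomp(motif)
  n <- nchar(s)
  m <- nchar(motif)
  ext <- if (circular) paste0(s, substr(s, 1, m - 1)) else s
  hits <- list()
  for (i in seq_len(nchar(ext) - m + 1)) {
    w <- substr(ext, i, i + m - 1)
    if (w == motif) hits[[length(hits) + 1]] <- c(i - 1, 1)
    if (w == rc && rc != motif) hits[[length(hits) + 1]] <- c(i - 1, 2)
  }
  if (!length(hits)) {
    return(data.frame(position = integer(), strand = character()))
  }
  h <- do.call(rbind, hits)
  data.frame(position = h[, 1], strand = c("top", "bottom")[h[, 2]])
}

# brute-force count of distinct circular closures (rotations identified) of
# a fragment multiset, by trying every permutation -- oracle for the
# assembler's uniqueness contract; feasible for small pots
oracle_closure_count <- function(left, right) {
  n <- length(left)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  count <- 0
  for (p in perms(seq_len(n)[-1])) {
    ord <- c(1, p)
    ok <- all(right[ord] == left[c(ord[-1], ord[1])])
    if (ok) count <- count + 1
  }
  count
}
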