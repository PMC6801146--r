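#' Predict NotI cassette release
#'
#' Verified assemblies are linearized with NotI to release the expression
#' cassette (integration flanks + marker + transcription units) before
#' yeast transformation. This predicts the digest: fragment sizes, which
#' fragment is the cassette, and whether an internal NotI site splits it.
#' Constructs whose insertion bricks carry NotI flanks (ZETA-style
#' `ZUpNotI ... ZDNotI`) yield exactly two fragments.
#'
#' @param construct A `gg_construct` from [simulate_one_pot()].
#' @return Tibble of class `gg_notI_report`: one row per fragment
#'   (`start`, `end`, `length`, `is_cassette`), fragment lengths summing to
#'   the plasmid size (4 nt per junction counted once). Attribute
#'   `cassette` records the identified coordinates and contained features.
#'   Zero NotI sites raise a cannot-linearize error; a cut strictly inside
#'   the cassette interior triggers a warning.
#' @export
notI_release <- function(construct) {
  plasmid <- construct$plasmid
  stopifnot(plasmid$circular)
  frags <- digest(plasmid, "NotI")
  if (any(is.na(frags$left_overhang))) {
    rlang::abort("cannot linearize: construct has no NotI site",
      class = "yaligg_cannot_linearize")
  }
  feats <- construct$features
  insert <- feats[feats$slot != "Backbone", ]
  n <- length(plasmid)
  # interior of the cassette: between InsUp's end and InsDown's start,
  # where a NotI cut would split the expression cassette
  core <- insert[!insert$slot %in% c("InsUp", "InsDown"), ]
  in_range <- function(p, a, b) {
    if (a <= b) p >= a & p < b else p >= a | p < b  # circular interval
  }
  if (nrow(core)) {
    lo <- min(core$start)
    hi <- max(core$end)
    splitting <- frags$start[in_range(frags$start, lo, hi)]
    for (p in splitting) {
      rlang::warn(sprintf("cassette split by internal NotI cut at position %d", p))
    }
  }
  # the cassette fragment contains every core feature midpoint
  mid <- (core$start + ((core$end - core$start) %/% 2L)) %% n
  contains <- vapply(seq_len(nrow(frags)), function(i) {
    all(in_range(mid, frags$start[i], frags$end[i]))
  }, logical(1))
  out <- tibble::tibble(
    start = frags$start, end = frags$end, length = frags$length,
    is_cassette = contains
  )
  structure(out, class = c("gg_notI_report", class(tibble::tibble())),
    plasmid_length = n,
    cassette = if (any(contains)) {
      list(start = frags$start[contains][1], end = frags$end[contains][1],
        features = insert$slot)
    } else NULL
  )
}

#' Predict colony-PCR amplicons
#'
#' Reports every amplicon defined by an exact-match forward primer site and
#' a downstream exact-match of the reverse primer's reverse complement.
#' Lengths are measured primer start to primer start, inclusive of both
#' primers. Circular templates are scanned across the origin and a product
#' may wrap it. Zero mismatches are allowed; a primer matching more than
#' one site triggers a multi-product warning listing all products.
#'
#' @param template A [dna_seq] or string.
#' @param fwd,rev Primer sequences (>= 15 nt), given 5'->3' as ordered.
#' @return Tibble with columns `fwd_start` (0-based), `rev_end`
#'   (exclusive), `length`; zero rows when either primer has no site.
#' @examples
#' tpl <- dna_seq(paste0("ATGCATGCATGCATGCATGC",
#'                        strrep("A", 40), "TTTTGGGGCCCCAAAATTTT"))
#' colony_pcr(tpl, "ATGCATGCATGCATGCATGC", revcomp("TTTTGGGGCCCCAAAATTTT"))
#' @export
colony_pcr <- function(template, fwd, rev) {
  template <- as_dna_seq(template)
  fwd <- toupper(fwd)
  rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    rlang::abort("primers must be at least 15 nt", class = "yaligg_bad_primer")
  }
  s <- template$seq
  n <- nchar(s)
  f_pos <- motif_starts(s, fwd, template$circular)
  r_pos <- motif_starts(s, revcomp(rev), template$circular)
  if (length(f_pos) > 1L || length(r_pos) > 1L) {
    rlang::warn(sprintf(
      "primer matches multiple sites (forward: %d, reverse: %d); all products reported",
      length(f_pos), length(r_pos)))
  }
  if (length(f_pos) == 0L || length(r_pos) == 0L) {
    return(tibble::tibble(fwd_start = integer(), rev_end = integer(),
      length = integer()))
  }
  out <- tidyr::expand_grid(fwd_start = f_pos, rev_start = r_pos) |>
    dplyr::mutate(rev_end = .data$rev_start + nchar(rev)) |>
    dplyr::mutate(length = .data$rev_end - .data$fwd_start)
  if (template$circular) {
    out$length <- ((out$length - 1L) %% n) + 1L
    out$rev_end <- out$rev_end %% n
  } else {
    out <- dplyr::filter(out, .data$length > 0L,
      .data$rev_start >= .data$fwd_start)
  }
  dplyr::select(dplyr::arrange(out, .data$fwd_start, .data$length),
    "fwd_start", "rev_end", "length")
}

#' Bench protocol for a named assembly stage
#'
#' Reproduces the printed one-pot recipes exactly. All stages use 50 pmol
#' of each DNA molecule, equimolar.
#'
#' * `standard_one_pot`: 5 U BsaI, 200 U T4 ligase, 2 ul ligase buffer,
#'   20 ul final volume; cycling (37 C 5 min / 16 C 2 min) x 60, then 55 C
#'   5 min, 80 C 5 min, hold 15 C.
#' * `preassembly` (4 parts per sub-reaction): 5 U BsaI, 200 U ligase, 1 ul
#'   buffer, 10 ul final; (37 C 3 min / 16 C 2 min) x 30, then 55/80/hold.
#' * `multigene_final`: 20 U BsaI, 400 U ligase, 4 ul buffer, 40 ul final;
#'   (37 C 5 min / 16 C 5 min) x 50, then 55/80/hold.
#'
#' @param stage One of `"standard_one_pot"`, `"preassembly"`,
#'   `"multigene_final"`.
#' @param n_fragments Number of molecules in the pot (>= 2); recorded in
#'   the protocol for the equimolar pipetting table.
#' @return A `gg_protocol` list: numeric fields plus a `programme` tibble
#'   (`step`, `temperature_c`, `duration_min`, `cycles`).
#' @examples
#' make_protocol("standard_one_pot", 13)
#' @export
make_protocol <- function(stage = c("standard_one_pot", "preassembly",
                                    "multigene_final"), n_fragments) {
  stage <- match.arg(stage)
  stopifnot(n_fragments >= 2L)
  spec <- switch(stage,
    standard_one_pot = list(bsai_u = 5, ligase_u = 200, buffer_ul = 2,
      final_ul = 20, cyc = c(37, 5, 16, 2), n_cycles = 60),
    preassembly = list(bsai_u = 5, ligase_u = 200, buffer_ul = 1,
      final_ul = 10, cyc = c(37, 3, 16, 2), n_cycles = 30),
    multigene_final = list(bsai_u = 20, ligase_u = 400, buffer_ul = 4,
      final_ul = 40, cyc = c(37, 5, 16, 5), n_cycles = 50)
  )
  programme <- tibble::tibble(
    step = c("digest", "ligate", "final_ligation", "inactivation", "hold"),
    temperature_c = c(spec$cyc[1], spec$cyc[3], 55, 80, 15),
    duration_min = c(spec$cyc[2], spec$cyc[4], 5, 5, NA),  # hold is open-ended
    cycles = c(spec$n_cycles, spec$n_cycles, 1, 1, 1)
  )
  structure(
    list(
      stage = stage,
      n_fragments = as.integer(n_fragments),
      per_fragment_pmol = 50,
      bsai_units = spec$bsai_u,
      ligase_units = spec$ligase_u,
      buffer_ul = spec$buffer_ul,
      final_volume_ul = spec$final_ul,
      cycles = spec$n_cycles,
      programme = programme
    ),
    class = "gg_protocol"
  )
}

#' @export
print.gg_protocol <- function(x, ...) {
  cat(sprintf(
    "<gg_protocol> %s: %d molecules x %g pmol; BsaI %g U, T4 ligase %g U, buffer %g ul, final %g ul\n",
    x$stage, x$n_fragments, x$per_fragment_pmol, x$bsai_units,
    x$ligase_units, x$buffer_ul, x$final_volume_ul))
  cyc <- x$programme[x$programme$cycles > 1, ]
  cat(sprintf("  [%s] x %d, then %s\n",
    paste(sprintf("%g C %g min", cyc$temperature_c, cyc$duration_min),
      collapse = " / "),
    x$cycles,
    paste(sprintf("%g C %g min",
      x$programme$temperature_c[x$programme$cycles == 1][1:2],
      x$programme$duration_min[x$programme$cycles == 1][1:2]),
      collapse = ", ")))
  invisible(x)
}

#' @rdname tidy.gg_validation
#' @method tidy gg_protocol
#' @export
tidy.gg_protocol <- function(x, ...) x$programme

#' @rdname tidy.gg_validation
#' @method glance gg_protocol
#' @export
glance.gg_protocol <- function(x, ...) {
  tibble::tibble(
    stage = x$stage, n_fragments = x$n_fragments,
    per_fragment_pmol = x$per_fragment_pmol, bsai_units = x$bsai_units,
    ligase_units = x$ligase_units, buffer_ul = x$buffer_ul,
    final_volume_ul = x$final_volume_ul, cycles = x$cycles
  )
}

#' Convert a molar DNA amount to mass
#'
#' Supports the equimolar pipetting table: `ng = pmol x length_bp x c`
#' with `c` the average double-stranded base-pair weight in g/mol/bp
#' (default 650, configurable).
#'
#' @param pmol Amount in picomoles.
#' @param length_bp Fragment length in base pairs.
#' @param bp_weight Grams per mole per base pair.
#' @return Mass in nanograms.
#' @examples
#' pmol_to_mass(1, 1)  # 0.65 ng
#' @export
pmol_to_mass <- function(pmol, length_bp, bp_weight = 650) {
  stopifnot(all(pmol >= 0), all(length_bp >= 0))
  pmol * length_bp * bp_weight * 1e-3
}

#' Integration-rate arithmetic
#'
#' Percent of screened transformants showing the locus-replacement
#' phenotype, formatted as a whole percent under an explicit rounding
#' policy. The policy matters at the margins the published counts sit on:
#' 5/37 gives 14% rounded but 13% truncated, and 11/24 gives 46% rounded
#' but 45% truncated -- so every report states which policy produced it.
#'
#' @param positives Number of phenotype-positive transformants.
#' @param screened Number screened (> 0).
#' @param policy `"round"` (half-up) or `"truncate"`.
#' @return Integer percent.
#' @examples
#' integration_rate(5, 37, "round")     # 14
#' integration_rate(11, 24, "truncate") # 45
#' @export
integration_rate <- function(positives, screened, policy = c("round", "truncate")) {
  policy <- match.arg(policy)
  stopifnot(screened > 0, positives >= 0, positives <= screened)
  pct <- 100 * positives / screened
  as.integer(if (policy == "round") floor(pct + 0.5) else floor(pct))
}
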