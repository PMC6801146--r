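#' Codon table for synonymous substitution
#'
#' The standard genetic code as a lookup used by the domestication editor:
#' codon -> amino acid plus amino acid -> synonymous codon list. Taken from
#' `Biostrings::GENETIC_CODE` when available, with an identical built-in
#' fallback, so translation semantics match the reference implementation
#' used as an oracle in the test-suite.
#'
#' @return List with elements `codon_to_aa` (named character) and
#'   `aa_to_codons` (named list).
#' @export
codon_table <- function() {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    code <- Biostrings::GENETIC_CODE
    codon_to_aa <- stats::setNames(as.character(code), names(code))
  } else {
    bases <- c("T", "C", "A", "G")
    codons <- as.vector(t(outer(
      as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
    codon_to_aa <- stats::setNames(aas, codons)
  }
  list(
    codon_to_aa = codon_to_aa,
    aa_to_codons = split(names(codon_to_aa), codon_to_aa)
  )
}

#' Translate a coding sequence
#'
#' @param cds Character scalar or [dna_seq]; length divisible by 3.
#' @param table Codon table from [codon_table()].
#' @return Amino-acid string (stops as `*`).
#' @export
translate_cds <- function(cds, table = codon_table()) {
  s <- if (inherits(cds, "dna_seq")) cds$seq else toupper(cds)
  stopifnot(nchar(s) %% 3 == 0)
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(table$codon_to_aa[codons], collapse = "")
}

# candidate synonymous replacements for a codon: wobble (third-position)
# changes first, then the rest, each block lexicographic
synonym_candidates <- function(codon, table) {
  syn <- setdiff(table$aa_to_codons[[table$codon_to_aa[[codon]]]], codon)
  if (length(syn) == 0L) return(character())
  third <- syn[substr(syn, 1, 2) == substr(codon, 1, 2)]
  c(sort(third), sort(setdiff(syn, third)))
}

forbidden_hits <- function(s, enzymes) {
  purrr::map(enzymes, function(e) {
    e <- as_enzyme(e)
    h <- find_recognition_sites(dna_seq(s), e)
    if (nrow(h)) h$width <- nchar(e$recognition)
    h
  }) |> dplyr::bind_rows()
}

#' Domesticate a coding sequence
#'
#' Removes every recognition site of the forbidden enzymes (both strands)
#' from a CDS by synonymous single-codon substitution, scanning sites left
#' to right with one edit per site. Candidate codons are tried
#' third-position changes first, then any synonymous codon, lexicographic
#' within each block, and an edit is accepted only if it destroys the site
#' without creating a new forbidden site anywhere (the sequence is
#' re-scanned after every edit). Translation is preserved exactly.
#'
#' @param cds Character scalar or [dna_seq]; length must be divisible by 3.
#'   A missing start codon only triggers a warning.
#' @param forbidden List of enzymes (specs or names); default BsaI.
#' @param table Codon table.
#' @return A [dna_seq] with attribute `edits`: a tibble logging each
#'   substitution (`codon_index`, 1-based; `position`, 0-based nt offset;
#'   `from`, `to`, `site_position`). An unresolvable site (spanning only
#'   codons with no synonyms, e.g. Met/Trp) raises an error with its
#'   coordinates.
#' @examples
#' dom <- domesticate_cds("ATGGGTCTCAAATAA")
#' attr(dom, "edits")
#' @export
domesticate_cds <- function(cds, forbidden = list("BsaI"), table = codon_table()) {
  seq_in <- as_dna_seq(cds)
  s <- seq_in$seq
  if (nchar(s) %% 3 != 0) {
    rlang::abort("CDS length must be divisible by 3", class = "yaligg_bad_cds")
  }
  if (substr(s, 1, 3) != "ATG") {
    rlang::warn("CDS does not start with ATG")
  }
  if (!is.list(forbidden)) forbidden <- as.list(forbidden)
  aa_in <- translate_cds(s, table)
  edits <- list()
  guard <- 0L
  repeat {
    hits <- forbidden_hits(s, forbidden)
    if (nrow(hits) == 0L) break
    guard <- guard + 1L
    if (guard > 10000L) {
      rlang::abort("domestication did not converge", class = "yaligg_unresolvable_site")
    }
    hits <- dplyr::arrange(hits, .data$position)
    site <- hits[1, ]
    first_codon <- site$position %/% 3L
    last_codon <- (site$position + site$width - 1L) %/% 3L
    fixed <- FALSE
    for (ci in first_codon:last_codon) {
      from <- substr(s, ci * 3L + 1L, ci * 3L + 3L)
      for (cand in synonym_candidates(from, table)) {
        trial <- paste0(substr(s, 1L, ci * 3L), cand,
          substr(s, ci * 3L + 4L, nchar(s)))
        trial_hits <- forbidden_hits(trial, forbidden)
        # accept iff strictly fewer sites remain and the targeted site is gone
        still <- any(trial_hits$position == site$position &
          trial_hits$strand == site$strand)
        if (!still && nrow(trial_hits) < nrow(hits)) {
          s <- trial
          edits[[length(edits) + 1L]] <- tibble::tibble(
            codon_index = ci + 1L, position = ci * 3L,
            from = from, to = cand, site_position = site$position
          )
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      rlang::abort(sprintf(
        "unresolvable forbidden site at position %d (codons %d-%d admit no clean synonymous substitution)",
        site$position, first_codon + 1L, last_codon + 1L),
        class = "yaligg_unresolvable_site")
    }
  }
  if (!identical(translate_cds(s, table), aa_in)) {
    rlang::abort("internal error: translation changed during domestication")
  }
  out <- dna_seq(s, circular = FALSE, name = seq_in$name)
  attr(out, "edits") <- if (length(edits)) dplyr::bind_rows(edits) else
    tibble::tibble(codon_index = integer(), position = integer(),
      from = character(), to = character(), site_position = integer())
  out
}

#' Simple melting-temperature estimate
#'
#' Wallace rule: 2 degrees C per A/T plus 4 per G/C. Deterministic and
#' dependency-free; chosen as the default because the annealing regions it
#' sizes (18-30 nt) are squarely in its validity range. The rule is a
#' [run_config()] field so a different estimator can be swapped in.
#'
#' @param seq Character vector of primer/annealing sequences.
#' @return Numeric vector, degrees C.
#' @export
tm_wallace <- function(seq) {
  seq <- toupper(seq)
  at <- stringr::str_count(seq, "[AT]")
  gc <- stringr::str_count(seq, "[GC]")
  2 * at + 4 * gc
}

#' Design adapter primers that add BsaI flanks with slot overhangs
#'
#' Builds the primer pair that turns a plain template into a Golden Gate
#' brick insert: each primer is a 5' tail (BsaI recognition `GGTCTC`, a
#' 1-nt spacer `A` matching the enzyme's 1/5 cut geometry, then the
#' junction overhang) followed by a template-annealing region extended
#' 3'-wards from 18 nt until the estimated melting temperature reaches
#' `tm_target`. BsaI digestion of the simulated amplicon releases exactly
#' `left overhang + template + right overhang`.
#'
#' @param template Linear [dna_seq] or string, >= 40 nt.
#' @param left_letter,right_letter Junction letters for the target slot.
#' @param overhangs Letter table (the grammar's overhang set).
#' @param tm_target Minimum annealing Tm, degrees C (default 55).
#' @param min_anneal Minimum annealing length (default 18 nt).
#' @return A `gg_primer_pair`: tibble with one row per primer (`primer`,
#'   `sequence`, `tail`, `anneal`, `anneal_len`, `tm`), with the simulated
#'   `amplicon` as an attribute. Warns if the template contains an internal
#'   BsaI site (domesticate first).
#' @export
design_adapter_primers <- function(template, left_letter, right_letter,
                                   overhangs = default_overhangs(),
                                   tm_target = 55, min_anneal = 18L) {
  template <- as_dna_seq(template)
  if (template$circular) {
    rlang::abort("template must be linear", class = "yaligg_bad_template")
  }
  n <- nchar(template$seq)
  if (n < 40L) {
    rlang::abort("template shorter than 40 nt", class = "yaligg_bad_template")
  }
  if (nrow(find_recognition_sites(template, "BsaI")) > 0L) {
    rlang::warn("template contains internal BsaI site(s); domesticate before amplification")
  }
  lo <- overhang_seq(left_letter, overhangs)
  ro <- overhang_seq(right_letter, overhangs)
  grow <- function(seed_fun) {
    len <- min_anneal
    while (tm_wallace(seed_fun(len)) < tm_target && len < n) len <- len + 1L
    len
  }
  f_len <- grow(function(l) substr(template$seq, 1, l))
  r_len <- grow(function(l) substr(template$seq, n - l + 1L, n))
  f_anneal <- substr(template$seq, 1, f_len)
  r_anneal <- revcomp(substr(template$seq, n - r_len + 1L, n))
  f_tail <- paste0("GGTCTC", "A", lo)
  r_tail <- paste0("GGTCTC", "A", revcomp(ro))
  amplicon <- paste0(f_tail, template$seq, revcomp(r_tail))
  out <- tibble::tibble(
    primer = c("forward", "reverse"),
    sequence = c(paste0(f_tail, f_anneal), paste0(r_tail, r_anneal)),
    tail = c(f_tail, r_tail),
    anneal = c(f_anneal, r_anneal),
    anneal_len = c(f_len, r_len),
    tm = tm_wallace(c(f_anneal, r_anneal))
  )
  structure(out, class = c("gg_primer_pair", class(tibble::tibble())),
    amplicon = amplicon,
    letters = c(left_letter, right_letter))
}
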