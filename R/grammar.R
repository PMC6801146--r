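#' The A-M junction grammar
#'
#' The assembly standard positions every part between two of thirteen
#' lettered 4-nt junctions arranged on a circle:
#'
#' ```
#' Backbone -A- InsUp -B- Marker -C- Prom1 -D- Gene1 -E- Term1 -F-
#' Prom2 -G- Gene2 -H- Term2 -I- Prom3 -J- Gene3 -K- Term3 -L- InsDown -M-
#' ```
#'
#' Shorter designs reuse the same letters so gene and promoter bricks never
#' change: a 1-TU design closes Term1 with an E-L shortcut terminator and a
#' 2-TU design closes Term2 with an H-L shortcut, giving junction lists of
#' length 7, 10 and 13 for 1, 2 and 3 transcription units.
#'
#' @param topology `"1TU"`, `"2TU"` or `"3TU"`.
#' @return `gg_grammar()`: a tibble with one row per slot (`slot`, `left`,
#'   `right` junction letters, in circle order ending at `Backbone`).
#'   `junctions_for()`: the ordered character vector of junction letters.
#' @examples
#' junctions_for("3TU")
#' gg_grammar("1TU")
#' @export
gg_grammar <- function(topology = c("3TU", "2TU", "1TU")) {
  topology <- match.arg(topology)
  rows <- switch(topology,
    "3TU" = list(
      c("InsUp", "A", "B"), c("Marker", "B", "C"),
      c("Prom1", "C", "D"), c("Gene1", "D", "E"), c("Term1", "E", "F"),
      c("Prom2", "F", "G"), c("Gene2", "G", "H"), c("Term2", "H", "I"),
      c("Prom3", "I", "J"), c("Gene3", "J", "K"), c("Term3", "K", "L"),
      c("InsDown", "L", "M"), c("Backbone", "M", "A")
    ),
    "2TU" = list(
      c("InsUp", "A", "B"), c("Marker", "B", "C"),
      c("Prom1", "C", "D"), c("Gene1", "D", "E"), c("Term1", "E", "F"),
      c("Prom2", "F", "G"), c("Gene2", "G", "H"), c("Term2", "H", "L"),
      c("InsDown", "L", "M"), c("Backbone", "M", "A")
    ),
    "1TU" = list(
      c("InsUp", "A", "B"), c("Marker", "B", "C"),
      c("Prom1", "C", "D"), c("Gene1", "D", "E"), c("Term1", "E", "L"),
      c("InsDown", "L", "M"), c("Backbone", "M", "A")
    )
  )
  out <- tibble::tibble(
    slot = vapply(rows, `[`, "", 1),
    left = vapply(rows, `[`, "", 2),
    right = vapply(rows, `[`, "", 3)
  )
  structure(out, class = c("gg_grammar", class(tibble::tibble())),
    topology = topology)
}

#' @rdname gg_grammar
#' @export
junctions_for <- function(topology = c("3TU", "2TU", "1TU")) {
  g <- gg_grammar(topology)
  g$left
}

#' All slot identifiers of the grammar
#' @return Character vector of the 13 slot ids (3-TU layout).
#' @export
gg_slots <- function() gg_grammar("3TU")$slot

# legal letter pairs per slot across all topologies (shortcut terminators
# make Term1/Term2 two-valued)
legal_letter_pairs <- function(slot) {
  pairs <- list()
  for (t in c("3TU", "2TU", "1TU")) {
    g <- gg_grammar(t)
    row <- g[g$slot == slot, ]
    if (nrow(row) == 1L) pairs[[t]] <- c(row$left, row$right)
  }
  unique(pairs)
}

#' Default 4-nt overhang set
#'
#' The thirteen junction sequences packaged with the toolkit fixture: a
#' repository-defined set that satisfies every constraint checked by
#' [validate_overhang_set()] (length 4, pairwise distinct, no palindromes,
#' no mutual reverse complements). Laboratories using the physical toolkit
#' can substitute their own letter-to-sequence mapping through the manifest.
#'
#' @return Tibble with columns `letter` (A-M) and `sequence`.
#' @export
default_overhangs <- function() {
  tibble::tibble(
    letter = LETTERS[1:13],
    sequence = c(
      "GGAG", "TACT", "AATG", "AGGT", "TTCG", "GCTT", "GGTA",
      "CGCT", "TGCC", "ACTA", "TAGA", "CAGA", "TGTG"
    )
  )
}

#' Validate a junction overhang set
#'
#' A usable Golden Gate overhang set must give every junction a unique
#' sticky end: all sequences of length 4, pairwise distinct, none equal to
#' its own reverse complement (a palindromic overhang ligates to itself in
#' either orientation) and no two sequences mutual reverse complements
#' (which would let two different junctions anneal). Violations are report
#' entries, not errors.
#'
#' @param overhangs Tibble with columns `letter` and `sequence`, or a bare
#'   character vector of sequences.
#' @return A `gg_validation` object; see [tidy.gg_validation()]. Passing
#'   means zero issues.
#' @examples
#' validate_overhang_set(default_overhangs())
#' validate_overhang_set(c("AATT", "GATC"))  # GATC is self-complementary
#' @export
validate_overhang_set <- function(overhangs) {
  if (is.character(overhangs)) {
    overhangs <- tibble::tibble(
      letter = make.unique(rep_len(LETTERS, length(overhangs))[seq_along(overhangs)]),
      sequence = overhangs
    )
  }
  stopifnot(nrow(overhangs) > 0)
  seqs <- toupper(overhangs$sequence)
  lab <- overhangs$letter
  issues <- list()
  push <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }
  bad_len <- which(nchar(seqs) != 4L | stringr::str_detect(seqs, "[^ACGT]"))
  for (i in bad_len) push("length", sprintf("%s (%s) is not a 4-nt A/C/G/T sequence", lab[i], seqs[i]))
  dup <- which(duplicated(seqs))
  for (i in dup) push("duplicate", sprintf("%s (%s) duplicates %s", lab[i], seqs[i],
    lab[match(seqs[i], seqs)]))
  dup_letter <- which(duplicated(lab))
  for (i in dup_letter) push("duplicate_letter", sprintf("letter %s used more than once", lab[i]))
  ok <- nchar(seqs) == 4L & !stringr::str_detect(seqs, "[^ACGT]")
  rc <- ifelse(ok, revcomp(seqs), NA)
  selfc <- which(ok & seqs == rc)
  for (i in selfc) push("self_complementary", sprintf("%s (%s) equals its own reverse complement", lab[i], seqs[i]))
  if (any(ok)) {
    for (i in which(ok)) {
      j <- which(ok & seqs == rc[i])
      j <- j[j > i]
      for (k in j) push("mutual_revcomp", sprintf(
        "%s (%s) and %s (%s) are mutual reverse complements", lab[i], seqs[i], lab[k], seqs[k]))
    }
  }
  new_validation(
    subject = "overhang set",
    issues = if (length(issues)) dplyr::bind_rows(issues) else
      tibble::tibble(check = character(), detail = character())
  )
}

new_validation <- function(subject, issues) {
  structure(
    list(subject = subject, pass = nrow(issues) == 0L, issues = issues),
    class = "gg_validation"
  )
}

#' @export
print.gg_validation <- function(x, ...) {
  cat(sprintf("<gg_validation> %s: %s\n", x$subject,
    if (x$pass) "PASS" else sprintf("FAIL (%d issue%s)", nrow(x$issues),
      if (nrow(x$issues) == 1) "" else "s")))
  if (!x$pass) {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  - [%s] %s\n", x$issues$check[i], x$issues$detail[i]))
    }
  }
  invisible(x)
}

#' Broom-style accessors for validation reports
#'
#' `tidy()` returns the issue table (one row per violation); `glance()` a
#' one-row summary.
#'
#' @param x A `gg_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gg_validation
#' @export
tidy.gg_validation <- function(x, ...) x$issues

#' @rdname tidy.gg_validation
#' @method glance gg_validation
#' @export
glance.gg_validation <- function(x, ...) {
  tibble::tibble(subject = x$subject, pass = x$pass, n_issues = nrow(x$issues))
}
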