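#' DNA sequence objects
#'
#' `dna_seq()` builds the package's minimal double-stranded DNA record: an
#' upper-case A/C/G/T string plus a topology flag. IUPAC ambiguity codes are
#' rejected on ingest because every brick in the Golden Gate standard is a
#' fully specified sequence; a part whose junction bases were ambiguous could
#' not be assigned a unique 4-nt overhang.
#'
#' @param seq Character scalar over A/C/G/T (case-insensitive).
#' @param circular Logical; `TRUE` for plasmids, `FALSE` for linear parts.
#' @param name Free-text molecule name carried into reports and GenBank.
#' @return An object of class `dna_seq`.
#' @examples
#' dna_seq("ATGCATGC", circular = TRUE, name = "demo")
#' @export
dna_seq <- function(seq, circular = FALSE, name = "") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  bad <- stringr::str_locate(s, "[^ACGT]")[1, 1]
  if (!is.na(bad)) {
    rlang::abort(sprintf(
      "ambiguous or invalid base '%s' at position %d (only A/C/G/T allowed)",
      substr(s, bad, bad), bad
    ), class = "yaligg_ambiguous_base")
  }
  if (nchar(s) == 0L) {
    rlang::abort("empty sequence", class = "yaligg_empty_seq")
  }
  structure(
    list(seq = s, circular = isTRUE(circular), name = as.character(name)[1]),
    class = "dna_seq"
  )
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$seq)
  head <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf(
    "<dna_seq> %s: %d bp, %s\n  %s\n",
    if (nzchar(x$name)) x$name else "(unnamed)", n,
    if (x$circular) "circular" else "linear", head
  ))
  invisible(x)
}

#' @export
length.dna_seq <- function(x) nchar(x$seq)

as_dna_seq <- function(x, circular = FALSE, name = "") {
  if (inherits(x, "dna_seq")) x else dna_seq(x, circular = circular, name = name)
}

#' Reverse complement of a DNA string
#'
#' Operates on plain character vectors; an involution by construction.
#'
#' @param x Character vector of A/C/G/T strings (or a [dna_seq]).
#' @return Character vector (or `dna_seq`) of the same length.
#' @examples
#' revcomp("GGTCTC") # "GAGACC"
#' @export
revcomp <- function(x) {
  if (inherits(x, "dna_seq")) {
    return(dna_seq(revcomp(x$seq), circular = x$circular, name = x$name))
  }
  vapply(x, function(s) {
    stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", s))
  }, character(1), USE.NAMES = FALSE)
}

# lexicographically minimal rotation of s, by progressive candidate filtering
min_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  d <- paste0(s, s)
  cand <- seq_len(n)
  k <- 0L
  chunk <- 48L
  while (length(cand) > 1L && k < n) {
    take <- min(chunk, n - k)
    subs <- substring(d, cand + k, cand + k + take - 1L)
    cand <- cand[subs == min(subs)]
    k <- k + take
  }
  substring(d, cand[1], cand[1] + n - 1L)
}

#' Canonical form of a sequence
#'
#' Circular molecules have no natural origin or strand, so equality is tested
#' on a canonical representative: the lexicographically minimal string over
#' all rotations of both strands. Linear sequences are returned unchanged.
#' Two circular molecules are the same physical plasmid iff their canonical
#' forms are identical strings.
#'
#' @param seq A [dna_seq] or character scalar (treated as circular if a
#'   `dna_seq` says so; plain strings need `circular = TRUE`).
#' @param circular Used only when `seq` is a bare string.
#' @return Character scalar.
#' @export
canonical_form <- function(seq, circular = FALSE) {
  if (inherits(seq, "dna_seq")) {
    s <- seq$seq
    circular <- seq$circular
  } else {
    s <- toupper(seq)
  }
  if (!circular) return(s)
  min(min_rotation(s), min_rotation(revcomp(s)))
}

#' Rotate a circular sequence
#'
#' @param seq A circular [dna_seq] or character scalar.
#' @param by Number of bases to rotate leftward (new origin at `by`, 0-based).
#' @return Same type as the input.
#' @export
rotate_seq <- function(seq, by) {
  if (inherits(seq, "dna_seq")) {
    stopifnot(seq$circular)
    return(dna_seq(rotate_seq(seq$seq, by), circular = TRUE, name = seq$name))
  }
  n <- nchar(seq)
  by <- ((by %% n) + n) %% n
  if (by == 0) return(seq)
  paste0(substr(seq, by + 1L, n), substr(seq, 1L, by))
}

#' Random DNA generation
#'
#' Uniform random A/C/G/T string, optionally resampled until it is free of a
#' set of forbidden motifs on both strands (used by the fixture generator to
#' keep stuffers and payloads clear of BsaI/NotI recognition sites).
#'
#' @param n Length in nt.
#' @param avoid Character vector of motifs to exclude (both strands).
#' @param max_iter Resampling cap before giving up.
#' @return Character scalar.
#' @export
random_dna <- function(n, avoid = character(), max_iter = 200L) {
  bases <- c("A", "C", "G", "T")
  s <- paste(sample(bases, n, replace = TRUE), collapse = "")
  if (length(avoid) == 0L) return(s)
  motifs <- unique(c(avoid, revcomp(avoid)))
  for (i in seq_len(max_iter)) {
    hit <- NULL
    for (m in motifs) {
      p <- stringr::str_locate(s, stringr::fixed(m))[1, 1]
      if (!is.na(p)) {
        hit <- c(p, p + nchar(m) - 1L)
        break
      }
    }
    if (is.null(hit)) return(s)
    w <- hit[1]:hit[2]
    repl <- sample(bases, length(w), replace = TRUE)
    s <- paste0(
      substr(s, 1, hit[1] - 1L),
      paste(repl, collapse = ""),
      substr(s, hit[2] + 1L, nchar(s))
    )
  }
  rlang::abort("could not generate motif-free sequence", class = "yaligg_rng_fail")
}

# does s (given topology) contain motif on either strand?
has_motif <- function(s, motif, circular = FALSE) {
  ext <- if (circular && nchar(s) > 1) paste0(s, substr(s, 1, nchar(motif) - 1L)) else s
  stringr::str_detect(ext, stringr::fixed(motif)) ||
    stringr::str_detect(ext, stringr::fixed(revcomp(motif)))
}
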