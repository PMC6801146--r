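#' Restriction enzyme specifications
#'
#' The built-in table covers the two enzymes the assembly standard uses:
#' BsaI, the Type IIS workhorse that cuts downstream of its recognition
#' sequence (GGTCTC N1, leaving 4-nt 5' overhangs), and NotI, the 8-cutter
#' used to release the integration cassette (GC^GGCCGC, cutting within its
#' palindromic site). Additional enzymes can be declared with
#' `enzyme_spec()` and used anywhere a built-in is accepted.
#'
#' @param name Enzyme name; for `gg_enzyme()` one of the built-ins
#'   (case-insensitive).
#' @param recognition Recognition sequence, top strand, length >= 6.
#' @param spacer_len For `downstream_typeIIS`: nt between the recognition
#'   sequence and the top-strand cut (1 for BsaI). `NA` for within-site
#'   cutters.
#' @param overhang_len Length of the 5' overhang left by the cut.
#' @param cut_kind `"downstream_typeIIS"` or `"within_site"`.
#' @return A one-row tibble of class `enzyme_spec`.
#' @examples
#' gg_enzyme("BsaI")
#' enzyme_spec("BsmBI", "CGTCTC", spacer_len = 1, overhang_len = 4,
#'             cut_kind = "downstream_typeIIS")
#' @export
enzyme_spec <- function(name, recognition, spacer_len, overhang_len, cut_kind) {
  cut_kind <- match.arg(cut_kind, c("downstream_typeIIS", "within_site"))
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) >= 6L, overhang_len >= 0L)
  if (cut_kind == "within_site") {
    spacer_len <- NA_integer_
    if ((nchar(recognition) - overhang_len) %% 2L != 0L) {
      rlang::abort("within-site cut must be centred in the recognition sequence")
    }
  } else {
    stopifnot(!is.na(spacer_len), spacer_len >= 0L)
  }
  structure(
    tibble::tibble(
      name = name, recognition = recognition,
      spacer_len = as.integer(spacer_len),
      overhang_len = as.integer(overhang_len), cut_kind = cut_kind
    ),
    class = c("enzyme_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname enzyme_spec
#' @export
enzyme_table <- function() {
  dplyr::bind_rows(
    enzyme_spec("BsaI", "GGTCTC", 1L, 4L, "downstream_typeIIS"),
    enzyme_spec("NotI", "GCGGCCGC", NA, 4L, "within_site")
  )
}

#' @rdname enzyme_spec
#' @export
gg_enzyme <- function(name) {
  tab <- enzyme_table()
  hit <- tab[tolower(tab$name) == tolower(name), ]
  if (nrow(hit) == 0L) {
    rlang::abort(sprintf("unknown enzyme '%s'; use enzyme_spec() to define it", name),
      class = "yaligg_unknown_enzyme")
  }
  structure(hit, class = c("enzyme_spec", class(tibble::tibble())))
}

as_enzyme <- function(x) {
  if (is.character(x)) gg_enzyme(x) else x
}

# all 0-based start offsets of fixed motif in s; circular scans across origin
motif_starts <- function(s, motif, circular) {
  m <- nchar(motif)
  n <- nchar(s)
  ext <- if (circular && n > 1L) paste0(s, substr(s, 1L, m - 1L)) else s
  loc <- stringr::str_locate_all(ext, stringr::fixed(motif))[[1]][, 1]
  pos <- as.integer(loc) - 1L
  pos[pos < n]
}

#' Find restriction recognition sites
#'
#' Scans both strands for exact occurrences of the enzyme's recognition
#' sequence. Positions are 0-based offsets on the top strand: for bottom
#' strand hits, the offset where the reverse complement of the recognition
#' sequence begins. Circular sequences are scanned across the origin and
#' origin-spanning sites are reported once. Palindromic recognition sites
#' (e.g. NotI) are reported once, as top-strand hits.
#'
#' @param seq A [dna_seq] (ambiguous bases are rejected at construction).
#' @param enzyme An [enzyme_spec] or built-in enzyme name.
#' @return Tibble with columns `position` (0-based) and `strand`
#'   (`"top"`/`"bottom"`), sorted by position.
#' @examples
#' find_recognition_sites(dna_seq("GGTCTCAAATT"), "BsaI")
#' @export
find_recognition_sites <- function(seq, enzyme) {
  seq <- as_dna_seq(seq)
  enzyme <- as_enzyme(enzyme)
  motif <- enzyme$recognition
  rc <- revcomp(motif)
  top <- motif_starts(seq$seq, motif, seq$circular)
  if (identical(motif, rc)) {
    bottom <- integer()
  } else {
    bottom <- motif_starts(seq$seq, rc, seq$circular)
  }
  out <- tibble::tibble(
    position = c(top, bottom),
    strand = rep(c("top", "bottom"), c(length(top), length(bottom)))
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

# 0-based top-strand cut offsets + overhang text for each site.
# downstream_typeIIS, top site at p:    top cut at p + reclen + spacer
# downstream_typeIIS, bottom site at q: top cut at q - spacer - overhang_len
# within_site, site at p:               top cut at p + (reclen - overhang)/2
cut_events <- function(seq, enzyme) {
  sites <- find_recognition_sites(seq, enzyme)
  n <- nchar(seq$seq)
  m <- nchar(enzyme$recognition)
  oh <- enzyme$overhang_len
  if (nrow(sites) == 0L) {
    return(tibble::tibble(cut = integer(), overhang = character(),
      site_position = integer(), site_strand = character()))
  }
  cut <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    if (enzyme$cut_kind == "within_site") {
      cut[i] <- p + (m - oh) %/% 2L
    } else if (sites$strand[i] == "top") {
      cut[i] <- p + m + enzyme$spacer_len
    } else {
      cut[i] <- p - enzyme$spacer_len - oh
    }
  }
  if (seq$circular) {
    cut <- ((cut %% n) + n) %% n
  } else if (any(cut < 0L | cut + oh > n)) {
    bad <- which(cut < 0L | cut + oh > n)[1]
    rlang::abort(sprintf(
      "site at position %d cuts outside the linear molecule", sites$position[bad]),
      class = "yaligg_cut_outside")
  }
  ext <- paste0(seq$seq, substr(seq$seq, 1L, oh))
  tibble::tibble(
    cut = cut,
    overhang = substring(ext, cut + 1L, cut + oh),
    site_position = sites$position,
    site_strand = sites$strand
  )
}

#' Simulate a restriction digest with exact cut geometry
#'
#' Cuts the molecule at every recognition site of `enzyme` and returns the
#' resulting fragments. Each fragment is recorded as its top-strand text
#' *including* both 4-nt junction regions, together with `left_overhang` and
#' `right_overhang`: the 5'-protruding single-stranded ends written as
#' top-strand 5'->3' text. Under this convention a fragment's right overhang
#' ligates to the next fragment's left overhang iff the strings are equal
#' (Watson-Crick pairing is implicit). Blunt ends of linear molecules carry
#' empty overhangs.
#'
#' Residues are conserved: the sum of fragment lengths minus
#' `overhang_len` per junction equals the parent length.
#'
#' @param seq A [dna_seq].
#' @param enzyme An [enzyme_spec] or enzyme name.
#' @return A tibble of class `gg_digest` with columns `seq`, `left_overhang`,
#'   `right_overhang`, `start`, `end` (0-based top-strand cut coordinates on
#'   the parent), `length`, `source`. Zero sites return the molecule intact
#'   as one fragment (`NA` coordinates).
#' @examples
#' digest(dna_seq("AAAAGGTCTCAAATTCCCCGG"), "BsaI")
#' @export
digest <- function(seq, enzyme) {
  seq <- as_dna_seq(seq)
  enzyme <- as_enzyme(enzyme)
  oh <- enzyme$overhang_len
  ev <- cut_events(seq, enzyme)
  n <- nchar(seq$seq)
  src <- seq$name
  frag_tbl <- function(seqs, lo, ro, st, en) {
    structure(
      tibble::tibble(
        seq = seqs, left_overhang = lo, right_overhang = ro,
        start = st, end = en, length = nchar(seqs), source = src
      ),
      class = c("gg_digest", class(tibble::tibble())),
      parent_length = n, circular_parent = seq$circular,
      overhang_len = oh
    )
  }
  if (nrow(ev) == 0L) {
    return(frag_tbl(seq$seq, NA_character_, NA_character_, NA_integer_, NA_integer_))
  }
  ev <- ev[!duplicated(ev$cut), , drop = FALSE]
  ev <- ev[order(ev$cut), , drop = FALSE]
  cuts <- ev$cut
  # overlapping cut geometry: two cuts closer than the overhang length would
  # give ends sharing residues
  gaps <- if (seq$circular) {
    diff(c(cuts, cuts[1] + n))
  } else {
    diff(cuts)
  }
  if (length(gaps) > 0 && any(gaps < oh)) {
    i <- which(gaps < oh)[1]
    rlang::abort(sprintf(
      "degenerate cut geometry: cuts at %d and %d are closer than the %d-nt overhang (sites at %s)",
      cuts[i], cuts[(i %% length(cuts)) + 1L], oh,
      paste(ev$site_position, collapse = ", ")),
      class = "yaligg_degenerate_geometry")
  }
  if (seq$circular) {
    ext <- paste0(seq$seq, seq$seq)
    k <- length(cuts)
    nxt <- c(cuts[-1], cuts[1] + n)
    seqs <- substring(ext, cuts + 1L, nxt + oh)
    frag_tbl(seqs, ev$overhang, c(ev$overhang[-1], ev$overhang[1]),
      cuts, nxt %% n)
  } else {
    k <- length(cuts)
    starts <- c(0L, cuts)
    ends <- c(cuts, n)  # top-strand cut coords; right overhang extends past
    seqs <- substring(seq$seq, starts + 1L,
      pmin(c(cuts + oh, n), n))
    lo <- c("", ev$overhang)
    ro <- c(ev$overhang, "")
    frag_tbl(seqs, lo, ro, starts, ends)
  }
}
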