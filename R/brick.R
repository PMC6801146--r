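#' Construct a brick record
#'
#' A brick is a donor plasmid carrying one part: the payload flanked by two
#' outward-facing BsaI recognition sites that cut inward, so that digestion
#' releases exactly `left overhang + payload + right overhang` while both
#' recognition sites stay on the donor backbone. Bricks are rows of a
#' toolkit's brick table; this helper builds one such row, synthesising the
#' donor plasmid when only a payload is supplied.
#'
#' @param id Unique brick identifier.
#' @param category One of promoter, gene, terminator, marker, insertion_up,
#'   insertion_down, destination_vector.
#' @param slot Grammar slot id (see [gg_slots()]); destination vectors use
#'   `"Backbone"`.
#' @param left_letter,right_letter Junction letters flanking the payload.
#' @param payload Part sequence (character), BsaI-free.
#' @param overhangs Letter-to-sequence table, default [default_overhangs()].
#' @param plasmid Optional pre-built circular donor plasmid sequence; if
#'   `NULL`, one is synthesised with a small random stuffer (uses the
#'   current RNG state).
#' @param name,strength,notes Free-text annotations.
#' @param provides Slots satisfied by the brick itself; destination vectors
#'   that preassemble popular parts cover more than `Backbone`.
#' @return One-row tibble.
#' @export
gg_brick <- function(id, category, slot, left_letter, right_letter, payload,
                     overhangs = default_overhangs(), plasmid = NULL,
                     name = id, strength = NA_character_, notes = NA_character_,
                     provides = slot) {
  payload <- toupper(payload)
  if (is.null(plasmid)) {
    plasmid <- brick_plasmid(payload, left_letter, right_letter, overhangs)
  }
  tibble::tibble(
    id = id, category = category, slot = slot,
    left_letter = left_letter, right_letter = right_letter,
    name = name, strength = strength, notes = notes,
    provides = list(provides),
    payload = payload, plasmid = plasmid
  )
}

overhang_seq <- function(letter, overhangs) {
  i <- match(letter, overhangs$letter)
  if (anyNA(i)) {
    rlang::abort(sprintf("unknown junction letter(s): %s",
      paste(letter[is.na(i)], collapse = ", ")), class = "yaligg_unknown_letter")
  }
  overhangs$sequence[i]
}

# the BsaI cassette released on digestion: recognition + 1-nt spacer, then
# the overhang; mirrored on the far side
brick_insert <- function(payload, left_letter, right_letter, overhangs) {
  paste0(
    "GGTCTCA", overhang_seq(left_letter, overhangs),
    payload,
    overhang_seq(right_letter, overhangs), "T", "GAGACC"
  )
}

#' Synthesise a circular donor plasmid around a payload
#'
#' Adds inward-cutting BsaI flanks with the requested junction overhangs and
#' a random BsaI/NotI-free stuffer backbone, then verifies the plasmid has
#' exactly the two intended BsaI recognition sites.
#'
#' @inheritParams gg_brick
#' @param stuffer_len Backbone stuffer length.
#' @return Circular plasmid sequence (character).
#' @export
brick_plasmid <- function(payload, left_letter, right_letter,
                          overhangs = default_overhangs(), stuffer_len = 400L) {
  insert <- brick_insert(payload, left_letter, right_letter, overhangs)
  # payload-internal sites (if any) are the caller's business -- check_brick
  # flags them; the synthesised backbone must not add sites of its own
  want <- 2L + nrow(find_recognition_sites(dna_seq(payload), "BsaI"))
  for (i in 1:50) {
    stuffer <- random_dna(stuffer_len, avoid = c("GGTCTC", "GCGGCCGC"))
    plasmid <- paste0(insert, stuffer)
    hits <- find_recognition_sites(dna_seq(plasmid, circular = TRUE), "BsaI")
    if (nrow(hits) == want) return(plasmid)
  }
  rlang::abort("failed to synthesise a clean donor plasmid", class = "yaligg_rng_fail")
}

# flanking letters of the contiguous arc of grammar slots a preassembled
# destination vector covers (e.g. InsDown+Backbone+InsUp+Marker -> L, C)
vector_letter_pair <- function(provides, topology = "3TU") {
  g <- gg_grammar(topology)
  idx <- sort(match(provides, g$slot))
  if (anyNA(idx)) rlang::abort("unknown slot in provides")
  n <- nrow(g)
  in_set <- seq_len(n) %in% idx
  # rotate so the arc does not wrap, then require contiguity
  if (all(in_set)) rlang::abort("vector cannot provide every slot")
  gap <- which(!in_set)[1]
  ord <- ((seq_len(n) + gap - 1L) %% n) + 1L  # start just after a non-member
  member <- in_set[ord]
  runs <- rle(member)
  if (sum(runs$values) != 1L) rlang::abort("provided slots not contiguous")
  arc <- ord[member]
  c(g$left[arc[1]], g$right[arc[length(arc)]])
}

#' Validate a brick against the grammar
#'
#' Checks that (i) the payload is internally BsaI-free on both strands,
#' (ii) BsaI digestion of the donor plasmid releases exactly one BsaI-free
#' fragment equal to `left overhang + payload + right overhang` for the
#' declared letters, and (iii) the declared letter pair is legal for the
#' declared slot in at least one topology (shortcut terminators E-L and H-L
#' are legal for Term1/Term2).
#'
#' @param brick One-row brick tibble (see [gg_brick()]).
#' @param overhangs Letter-to-sequence table.
#' @return A `gg_validation` object.
#' @export
check_brick <- function(brick, overhangs = default_overhangs()) {
  stopifnot(nrow(brick) == 1L)
  issues <- list()
  push <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }

  pay <- dna_seq(brick$payload, circular = FALSE, name = brick$id)
  internal <- find_recognition_sites(pay, "BsaI")
  if (nrow(internal) > 0L) {
    push("internal_bsai", sprintf(
      "payload contains BsaI recognition site(s) at position(s) %s",
      paste(internal$position, collapse = ", ")))
  }

  exp_lo <- tryCatch(overhang_seq(brick$left_letter, overhangs), error = function(e) NA)
  exp_ro <- tryCatch(overhang_seq(brick$right_letter, overhangs), error = function(e) NA)
  if (is.na(exp_lo) || is.na(exp_ro)) {
    push("letters", sprintf("undeclared junction letter(s) %s/%s",
      brick$left_letter, brick$right_letter))
  } else {
    frags <- tryCatch(
      digest(dna_seq(brick$plasmid, circular = TRUE, name = brick$id), "BsaI"),
      error = function(e) NULL)
    if (is.null(frags) || any(is.na(frags$left_overhang))) {
      push("flank_geometry", "donor plasmid does not digest into fragments with BsaI")
    } else {
      free <- vapply(frags$seq, function(s) !has_motif(s, "GGTCTC"), logical(1))
      if (sum(free) != 1L) {
        push("flank_geometry", sprintf(
          "expected exactly one BsaI-free released fragment, found %d", sum(free)))
      } else {
        rel <- frags[free, ]
        want <- paste0(exp_lo, brick$payload, exp_ro)
        if (!identical(rel$seq, want)) {
          push("release", "released fragment is not left-overhang + payload + right-overhang for the declared letters")
        }
        if (!identical(rel$left_overhang, exp_lo) || !identical(rel$right_overhang, exp_ro)) {
          push("release_overhangs", sprintf(
            "released overhangs %s/%s do not match declared letters %s/%s",
            rel$left_overhang, rel$right_overhang, brick$left_letter, brick$right_letter))
        }
      }
    }
  }

  provides <- if (is.list(brick$provides)) brick$provides[[1]] else brick$slot
  if (!all(provides %in% gg_slots()) || !(brick$slot %in% gg_slots())) {
    push("slot", sprintf("unknown slot '%s'",
      paste(setdiff(c(brick$slot, provides), gg_slots()), collapse = ", ")))
  } else if (identical(brick$category, "destination_vector") && length(provides) > 1L) {
    pair <- tryCatch(vector_letter_pair(provides), error = function(e) NULL)
    if (is.null(pair)) {
      push("slot_letters", "provided slots do not form a contiguous arc of the grammar circle")
    } else if (!identical(c(brick$left_letter, brick$right_letter), pair)) {
      push("slot_letters", sprintf(
        "letter pair %s-%s does not match the %s-%s arc covered by the vector",
        brick$left_letter, brick$right_letter, pair[1], pair[2]))
    }
  } else {
    legal <- legal_letter_pairs(brick$slot)
    pair <- c(brick$left_letter, brick$right_letter)
    if (!any(vapply(legal, identical, logical(1), y = pair))) {
      push("slot_letters", sprintf(
        "letter pair %s-%s is not legal for slot %s (legal: %s)",
        pair[1], pair[2], brick$slot,
        paste(vapply(legal, paste, "", collapse = "-"), collapse = ", ")))
    }
  }

  new_validation(
    subject = sprintf("brick %s", brick$id),
    issues = if (length(issues)) dplyr::bind_rows(issues) else
      tibble::tibble(check = character(), detail = character())
  )
}
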