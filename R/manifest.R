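#' Toolkit objects
#'
#' A toolkit bundles the junction overhang set, the brick table and free
#' metadata (e.g. the physical collection's Addgene range as provenance
#' text). The packaged fixture reproduces the published inventory: 64
#' bricks = 27 promoter + 14 terminator + 6 marker + 10 genome-insertion +
#' 5 gene + 2 destination vectors.
#'
#' @param bricks Brick tibble (rows from [gg_brick()]).
#' @param overhangs Letter/sequence tibble.
#' @param meta Named list of free metadata.
#' @return An object of class `gg_toolkit`.
#' @export
gg_toolkit <- function(bricks, overhangs = default_overhangs(), meta = list()) {
  if (anyDuplicated(bricks$id)) {
    rlang::abort(sprintf("duplicate brick id(s): %s",
      paste(unique(bricks$id[duplicated(bricks$id)]), collapse = ", ")),
      class = "yaligg_duplicate_id")
  }
  structure(list(bricks = bricks, overhangs = overhangs, meta = meta),
    class = "gg_toolkit")
}

#' @export
print.gg_toolkit <- function(x, ...) {
  counts <- manifest_counts(x)
  cat(sprintf("<gg_toolkit> %d bricks (%s)\n", nrow(x$bricks),
    paste(sprintf("%s: %d", counts$category, counts$n), collapse = ", ")))
  invisible(x)
}

#' Category counts of a toolkit or manifest
#'
#' Insertion bricks (up and down flanks) are counted as one
#' `insertion_sequence` category, matching how the published inventory is
#' tallied.
#'
#' @param x A `gg_toolkit` or brick tibble.
#' @return Tibble with `category` and `n`.
#' @export
manifest_counts <- function(x) {
  bricks <- if (inherits(x, "gg_toolkit")) x$bricks else x
  bricks |>
    dplyr::mutate(category = dplyr::if_else(
      .data$category %in% c("insertion_up", "insertion_down"),
      "insertion_sequence", .data$category)) |>
    dplyr::count(.data$category, name = "n")
}

toolkit_brick <- function(toolkit, id) {
  row <- toolkit$bricks[toolkit$bricks$id == id, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("brick '%s' not found in toolkit", id),
      class = "yaligg_missing_brick")
  }
  row
}

#' Read a toolkit manifest
#'
#' The manifest is a YAML document with top-level fields `name`, `meta`
#' (free map), `overhangs` (letter -> 4-nt sequence map) and `bricks`
#' (list of records with `id`, `category`, `slot`, `left_letter`,
#' `right_letter` and optional `name`, `strength`, `notes`, `provides`,
#' `payload`). Payload sequences may be omitted (inventory-only manifests,
#' like the packaged fixture manifest) or given inline.
#'
#' @param path Manifest file path.
#' @return A `gg_toolkit`; inventory-only manifests have `NA` payloads and
#'   plasmids. A manifest with no destination vector is valid but carries a
#'   `no_destination_vector` flag in its metadata.
#' @examples
#' m <- load_manifest(system.file("extdata", "toolkit_manifest.yaml",
#'                    package = "yaligg"))
#' sum(manifest_counts(m)$n)  # 64
#' @export
load_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$bricks)) doc$bricks <- list()
  required <- c("id", "category", "slot", "left_letter", "right_letter")
  categories <- c("promoter", "gene", "terminator", "marker",
    "insertion_up", "insertion_down", "destination_vector")
  rows <- purrr::map(doc$bricks, function(b) {
    missing <- setdiff(required, names(b))
    if (length(missing)) {
      rlang::abort(sprintf("manifest brick record missing field(s): %s",
        paste(missing, collapse = ", ")), class = "yaligg_manifest_schema")
    }
    if (!b$category %in% categories) {
      rlang::abort(sprintf("brick %s: unknown category '%s'", b$id, b$category),
        class = "yaligg_manifest_schema")
    }
    tibble::tibble(
      id = b$id, category = b$category, slot = b$slot,
      left_letter = b$left_letter, right_letter = b$right_letter,
      name = b$name %||% b$id,
      strength = b$strength %||% NA_character_,
      notes = b$notes %||% NA_character_,
      provides = list(b$provides %||% b$slot),
      payload = b$payload %||% NA_character_,
      plasmid = NA_character_
    )
  })
  bricks <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = character(), category = character(), slot = character(),
      left_letter = character(), right_letter = character(), name = character(),
      strength = character(), notes = character(), provides = list(),
      payload = character(), plasmid = character())
  overhangs <- if (!is.null(doc$overhangs)) {
    tibble::tibble(letter = names(doc$overhangs),
      sequence = toupper(unlist(doc$overhangs, use.names = FALSE)))
  } else {
    default_overhangs()
  }
  meta <- doc$meta %||% list()
  if (!is.null(doc$name)) meta$name <- doc$name
  if (!any(bricks$category == "destination_vector")) {
    meta$no_destination_vector <- TRUE
  }
  gg_toolkit(bricks, overhangs, meta)
}

#' Write a toolkit manifest
#'
#' @param toolkit A `gg_toolkit`.
#' @param path Output YAML path.
#' @param sequences Include payload sequences inline (default `FALSE`:
#'   inventory-only manifest).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(toolkit, path, sequences = FALSE) {
  bricks <- purrr::pmap(toolkit$bricks, function(...) {
    b <- list(...)
    rec <- list(
      id = b$id, category = b$category, slot = b$slot,
      left_letter = b$left_letter, right_letter = b$right_letter,
      name = b$name
    )
    if (!is.na(b$strength)) rec$strength <- b$strength
    if (!is.na(b$notes)) rec$notes <- b$notes
    if (!identical(b$provides, b$slot)) rec$provides <- b$provides
    if (sequences && !is.na(b$payload)) rec$payload <- b$payload
    rec
  })
  doc <- list(
    name = toolkit$meta$name %||% "yaligg toolkit",
    meta = toolkit$meta[setdiff(names(toolkit$meta), "name")],
    overhangs = as.list(stats::setNames(toolkit$overhangs$sequence,
      toolkit$overhangs$letter)),
    bricks = bricks
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname tidy.gg_validation
#' @method tidy gg_toolkit
#' @export
tidy.gg_toolkit <- function(x, ...) {
  dplyr::select(x$bricks, -"payload", -"plasmid")
}

#' @rdname tidy.gg_validation
#' @method glance gg_toolkit
#' @export
glance.gg_toolkit <- function(x, ...) {
  counts <- manifest_counts(x)
  wide <- tidyr::pivot_wider(counts, names_from = "category", values_from = "n")
  dplyr::bind_cols(tibble::tibble(n_bricks = nrow(x$bricks)), wide)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
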