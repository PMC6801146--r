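#' Specify an assembly design
#'
#' A design maps every grammar slot of a topology to a brick id, plus the
#' destination vector. Slots the vector itself provides (preassembled
#' vectors) are filled implicitly and must not be given a brick.
#'
#' @param topology `"1TU"`, `"2TU"` or `"3TU"`.
#' @param slots Named character vector/list, slot id -> brick id.
#' @param vector_id Destination vector brick id.
#' @return A tibble of class `gg_design` (columns `slot`, `brick_id`; the
#'   Backbone row holds the vector), with a `topology` attribute.
#' @examples
#' \dontrun{
#' design <- gg_design("1TU", c(InsUp = "ZETA_UP", Marker = "URA3",
#'   Prom1 = "pTEF_P1", Gene1 = "RedStarII_G1", Term1 = "TLip2_EL",
#'   InsDown = "ZETA_DOWN"), vector_id = "GGE029")
#' }
#' @export
gg_design <- function(topology, slots, vector_id) {
  slots <- unlist(slots)
  out <- tibble::tibble(
    slot = c(names(slots), "Backbone"),
    brick_id = c(unname(slots), vector_id)
  )
  structure(out, class = c("gg_design", class(tibble::tibble())),
    topology = topology)
}

design_topology <- function(design) {
  attr(design, "topology") %||% "3TU"
}

#' Validate a design against a toolkit
#'
#' Every grammar slot of the topology must be filled exactly once, either by
#' a design brick or by the destination vector's preassembled arc; all
#' brick ids must exist in the toolkit.
#'
#' @param design A [gg_design()].
#' @param toolkit A `gg_toolkit`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_design <- function(design, toolkit) {
  topo <- design_topology(design)
  g <- gg_grammar(topo)
  for (id in design$brick_id) toolkit_brick(toolkit, id)
  vec_id <- design$brick_id[design$slot == "Backbone"]
  if (length(vec_id) != 1L) {
    rlang::abort("design must contain exactly one Backbone entry",
      class = "yaligg_bad_design")
  }
  vec <- toolkit_brick(toolkit, vec_id)
  provided <- vec$provides[[1]]
  need <- setdiff(g$slot, provided)
  given <- design$slot[design$slot != "Backbone"]
  if (length(setdiff(need, given))) {
    rlang::abort(sprintf("unfilled slot(s): %s",
      paste(setdiff(need, given), collapse = ", ")), class = "yaligg_bad_design")
  }
  extra <- setdiff(given, need)
  if (length(extra)) {
    rlang::abort(sprintf("slot(s) not in the %s grammar or already provided by %s: %s",
      topo, vec_id, paste(extra, collapse = ", ")), class = "yaligg_bad_design")
  }
  if (anyDuplicated(design$slot)) {
    rlang::abort("duplicate slot assignment", class = "yaligg_bad_design")
  }
  invisible(TRUE)
}

#' Number of DNA molecules entering the one-pot reaction
#'
#' Inserts plus the destination vector: 13 for a complete 3-TU design, 10
#' for 2-TU (H-L shortcut terminator), 7 for 1-TU (E-L shortcut), fewer
#' when a preassembled vector provides some slots.
#'
#' @inheritParams validate_design
#' @return Integer count.
#' @export
count_fragments <- function(design, toolkit = NULL) {
  if (!is.null(toolkit)) validate_design(design, toolkit)
  nrow(design)
}

# released (BsaI-free) payload fragment of one brick's donor plasmid
released_fragment <- function(brick) {
  frags <- digest(dna_seq(brick$plasmid, circular = TRUE, name = brick$id), "BsaI")
  if (any(is.na(frags$left_overhang))) {
    rlang::abort(sprintf("brick %s has no BsaI sites", brick$id),
      class = "yaligg_bad_brick")
  }
  free <- vapply(frags$seq, function(s) !has_motif(s, "GGTCTC"), logical(1))
  if (sum(free) != 1L) {
    rlang::abort(sprintf("brick %s releases %d BsaI-free fragments (expected 1)",
      brick$id, sum(free)), class = "yaligg_bad_brick")
  }
  out <- frags[free, ]
  out$source <- brick$id
  out
}

#' Ligate a pot of sticky-ended fragments into a circular product
#'
#' The junction graph connects fragment right overhangs to equal left
#' overhangs (the top-strand text convention makes compatibility a string
#' equality). With a validated overhang set the graph of a complete design
#' has exactly one circular closure using every fragment once; this
#' function finds it, or raises an open-junction error (naming the
#' unsatisfiable overhangs) or an ambiguity error (when redundant overhangs
#' admit more than one closure).
#'
#' @param fragments Tibble with columns `seq`, `left_overhang`,
#'   `right_overhang`, `source` (one row per molecule in the pot).
#' @param overhangs Optional letter table used to translate overhang
#'   sequences back to junction letters in error messages and the junction
#'   record.
#' @return List with `plasmid` (circular [dna_seq] starting at the first
#'   fragment's left junction), `order` (fragment indices in ligation
#'   order), `junctions` (tibble letter/sequence/position).
#' @export
ligate_fragments <- function(fragments, overhangs = default_overhangs()) {
  n <- nrow(fragments)
  stopifnot(n >= 1L)
  letter_of <- function(s) {
    i <- match(s, overhangs$sequence)
    ifelse(is.na(i), s, overhangs$letter[i])
  }
  # adjacency: which fragments can follow fragment i
  succ <- purrr::map(fragments$right_overhang,
    function(ro) which(fragments$left_overhang == ro))
  unmet <- unique(c(
    setdiff(fragments$right_overhang, fragments$left_overhang),
    setdiff(fragments$left_overhang, fragments$right_overhang)))
  if (length(unmet)) {
    rlang::abort(sprintf("open junction(s): unsatisfied overhang(s) %s",
      paste(sort(unique(letter_of(unmet))), collapse = ", ")),
      class = "yaligg_open_junction")
  }
  closures <- enumerate_closures(succ, n)
  if (length(closures) == 0L) {
    # every right overhang has a partner but no single circle uses all
    miss <- unique(letter_of(c(
      setdiff(fragments$right_overhang, fragments$left_overhang),
      setdiff(fragments$left_overhang, fragments$right_overhang))))
    rlang::abort(sprintf(
      "open junction(s): fragments do not close into one circle (unbalanced: %s)",
      if (length(miss)) paste(miss, collapse = ", ") else "cycle split"),
      class = "yaligg_open_junction")
  }
  if (length(closures) > 1L) {
    desc <- vapply(closures, function(ord)
      paste(fragments$source[ord], collapse = "-"), character(1))
    rlang::abort(paste0("ambiguous overhang set: ", length(closures),
      " distinct circular closures:\n  ", paste(desc, collapse = "\n  ")),
      class = "yaligg_ambiguous_closure")
  }
  ord <- closures[[1]]
  oh <- nchar(fragments$left_overhang[1])
  pieces <- fragments$seq[ord]
  plasmid <- pieces[1]
  for (p in pieces[-1]) plasmid <- paste0(plasmid, substring(p, oh + 1L))
  # the final fragment's right overhang closes onto fragment 1's left:
  # drop the duplicated closing overhang
  plasmid <- substr(plasmid, 1L, nchar(plasmid) - oh)
  pos <- cumsum(c(0L, nchar(pieces) - oh))[seq_along(pieces)]
  junctions <- tibble::tibble(
    letter = letter_of(fragments$left_overhang[ord]),
    sequence = fragments$left_overhang[ord],
    position = pos
  )
  list(
    plasmid = dna_seq(plasmid, circular = TRUE),
    order = ord,
    junctions = junctions
  )
}

# depth-first enumeration of all circular closures using every fragment
# exactly once (Hamiltonian cycles of the junction graph, anchored at 1)
enumerate_closures <- function(succ, n) {
  found <- list()
  path <- integer(n)
  used <- logical(n)
  walk <- function(depth, at) {
    path[depth] <<- at
    used[at] <<- TRUE
    if (depth == n) {
      if (1L %in% succ[[at]]) found[[length(found) + 1L]] <<- path
    } else {
      for (nx in succ[[at]]) {
        if (!used[nx]) walk(depth + 1L, nx)
      }
    }
    used[at] <<- FALSE
  }
  walk(1L, 1L)
  found
}

#' Simulate a one-pot Golden Gate reaction
#'
#' Digests every design brick and the destination vector with BsaI, keeps
#' the released BsaI-free payload fragments (the RFP dropout and donor
#' backbones retain the recognition sites and are excluded, mirroring the
#' red/white counterselection), builds the junction graph and returns the
#' unique circular closure as an annotated construct.
#'
#' @inheritParams validate_design
#' @return A `gg_construct`: list with `plasmid` (circular [dna_seq],
#'   origin at the backbone's left junction), `features` (tibble slot,
#'   brick_id, name, category, start, end, strand), `junctions`, and
#'   `canonical` (rotation/strand-invariant sequence string).
#' @export
simulate_one_pot <- function(design, toolkit) {
  validate_design(design, toolkit)
  bricks <- dplyr::bind_rows(purrr::map(design$brick_id,
    function(id) toolkit_brick(toolkit, id)))
  frags <- dplyr::bind_rows(purrr::map(seq_len(nrow(bricks)),
    function(i) released_fragment(bricks[i, ])))
  # anchor the product at the backbone fragment
  back <- match(design$brick_id[design$slot == "Backbone"], frags$source)
  frags <- frags[c(back, setdiff(seq_len(nrow(frags)), back)), ]
  lig <- ligate_fragments(frags, toolkit$overhangs)
  build_construct(lig, frags, design, toolkit)
}

build_construct <- function(lig, frags, design, toolkit) {
  oh <- 4L
  ord <- lig$order
  meta <- tibble::tibble(
    brick_id = frags$source[ord],
    start = lig$junctions$position,
    len = nchar(frags$seq[ord]) - oh
  )
  meta <- meta |>
    dplyr::left_join(
      tibble::tibble(brick_id = design$brick_id, slot = design$slot),
      by = "brick_id") |>
    dplyr::left_join(
      dplyr::select(toolkit$bricks, "id", "name", "category"),
      by = c(brick_id = "id"))
  features <- tibble::tibble(
    slot = meta$slot, brick_id = meta$brick_id, name = meta$name,
    category = meta$category,
    start = meta$start, end = meta$start + meta$len, strand = "+"
  )
  plasmid <- lig$plasmid
  plasmid$name <- paste0("assembly_", design$brick_id[design$slot == "Backbone"])
  if (nrow(find_recognition_sites(plasmid, "BsaI")) > 0L) {
    rlang::abort("internal error: assembled product contains BsaI sites",
      class = "yaligg_dirty_product")
  }
  structure(
    list(plasmid = plasmid, features = features, junctions = lig$junctions,
      canonical = canonical_form(plasmid), design = design),
    class = "gg_construct"
  )
}

#' @export
print.gg_construct <- function(x, ...) {
  cat(sprintf("<gg_construct> %d bp circular, %d features, junctions %s\n",
    length(x$plasmid), nrow(x$features),
    paste(x$junctions$letter, collapse = "")))
  print(x$features, n = Inf)
  invisible(x)
}

#' @rdname tidy.gg_validation
#' @method tidy gg_construct
#' @export
tidy.gg_construct <- function(x, ...) x$features

#' @rdname tidy.gg_validation
#' @method glance gg_construct
#' @export
glance.gg_construct <- function(x, ...) {
  tibble::tibble(
    length_bp = length(x$plasmid),
    n_features = nrow(x$features),
    n_junctions = nrow(x$junctions),
    bsai_sites = nrow(find_recognition_sites(x$plasmid, "BsaI")),
    noti_sites = nrow(find_recognition_sites(x$plasmid, "NotI"))
  )
}

#' Plan the split preassembly route for a 3-TU design
#'
#' For three transcription units the one-pot reaction holds 13 molecules;
#' assembly efficiency is improved by first fusing three groups of four
#' parts each -- (InsUp, Marker, Prom1, Gene1), (Term1, Prom2, Gene2,
#' Term2), (Prom3, Gene3, Term3, InsDown) -- and then combining the three
#' preassemblies with the destination vector in a final multigene reaction.
#'
#' @inheritParams validate_design
#' @return A `gg_preassembly_plan`: tibble (`reaction`, `slot`, `brick_id`)
#'   plus a `final_inputs` attribute listing the three preassemblies and
#'   the vector.
#' @export
plan_preassembly <- function(design, toolkit = NULL) {
  if (!identical(design_topology(design), "3TU")) {
    rlang::abort("the split preassembly is defined only for 3-TU designs",
      class = "yaligg_unsupported_topology")
  }
  if (!is.null(toolkit)) validate_design(design, toolkit)
  groups <- list(
    c("InsUp", "Marker", "Prom1", "Gene1"),
    c("Term1", "Prom2", "Gene2", "Term2"),
    c("Prom3", "Gene3", "Term3", "InsDown")
  )
  lookup <- stats::setNames(design$brick_id, design$slot)
  missing <- setdiff(unlist(groups), design$slot)
  if (length(missing)) {
    rlang::abort(sprintf(
      "preassembly requires slot(s) %s in the design (vector-provided slots cannot be split)",
      paste(missing, collapse = ", ")), class = "yaligg_bad_design")
  }
  plan <- purrr::imap(groups, function(slots, i) {
    tibble::tibble(reaction = i, slot = slots, brick_id = unname(lookup[slots]))
  }) |> dplyr::bind_rows()
  structure(plan, class = c("gg_preassembly_plan", class(tibble::tibble())),
    final_inputs = c(sprintf("preassembly_%d", 1:3),
      unname(lookup["Backbone"])))
}

# fuse one preassembly group into a single linear fragment; keeps the
# per-brick sub-feature offsets so the final product can be annotated
fuse_group <- function(plan, reaction, toolkit) {
  ids <- plan$brick_id[plan$reaction == reaction]
  frs <- dplyr::bind_rows(purrr::map(ids,
    function(id) released_fragment(toolkit_brick(toolkit, id))))
  oh <- 4L
  # chain by overhang equality starting from the fragment whose left
  # overhang no group member produces
  start <- which(!(frs$left_overhang %in% frs$right_overhang))
  if (length(start) != 1L) {
    rlang::abort("preassembly group does not chain linearly",
      class = "yaligg_open_junction")
  }
  ord <- start
  while (length(ord) < nrow(frs)) {
    nxt <- which(frs$left_overhang == frs$right_overhang[ord[length(ord)]])
    if (length(nxt) != 1L) {
      rlang::abort("preassembly group does not chain linearly",
        class = "yaligg_open_junction")
    }
    ord <- c(ord, nxt)
  }
  seqs <- frs$seq[ord]
  fused <- seqs[1]
  for (p in seqs[-1]) fused <- paste0(fused, substring(p, oh + 1L))
  rel <- cumsum(c(0L, nchar(seqs) - oh))[seq_along(seqs)]
  list(
    fragment = tibble::tibble(
      seq = fused,
      left_overhang = frs$left_overhang[ord[1]],
      right_overhang = frs$right_overhang[ord[length(ord)]],
      start = NA_integer_, end = NA_integer_, length = nchar(fused),
      source = paste0("preassembly_", reaction)
    ),
    sub_features = tibble::tibble(
      brick_id = frs$source[ord],
      rel_start = rel,
      len = nchar(frs$seq[ord]) - oh
    )
  )
}

#' Simulate the preassembly-then-multigene route
#'
#' Runs the three sub-reactions of [plan_preassembly()], then the final
#' multigene reaction with the destination vector. The product is
#' canonically identical to [simulate_one_pot()] on the same design.
#'
#' @inheritParams validate_design
#' @return A `gg_construct` (features annotated per original brick).
#' @export
simulate_preassembly <- function(design, toolkit) {
  validate_design(design, toolkit)
  plan <- plan_preassembly(design, toolkit)
  groups <- purrr::map(1:3, fuse_group, plan = plan, toolkit = toolkit)
  vec <- toolkit_brick(toolkit, design$brick_id[design$slot == "Backbone"])
  vec_frag <- released_fragment(vec)
  pot <- dplyr::bind_rows(vec_frag, purrr::map(groups, "fragment"))
  lig <- ligate_fragments(pot, toolkit$overhangs)
  # expand each pot fragment back to per-brick features
  sub <- c(
    list(tibble::tibble(brick_id = vec$id, rel_start = 0L,
      len = nchar(vec_frag$seq) - 4L)),
    purrr::map(groups, "sub_features")
  )
  feats <- purrr::map2(lig$order, lig$junctions$position, function(i, at) {
    dplyr::mutate(sub[[i]], start = at + .data$rel_start)
  }) |> dplyr::bind_rows()
  meta <- feats |>
    dplyr::left_join(tibble::tibble(brick_id = design$brick_id, slot = design$slot),
      by = "brick_id") |>
    dplyr::left_join(dplyr::select(toolkit$bricks, "id", "name", "category"),
      by = c(brick_id = "id"))
  features <- tibble::tibble(
    slot = meta$slot, brick_id = meta$brick_id, name = meta$name,
    category = meta$category, start = meta$start, end = meta$start + meta$len,
    strand = "+"
  )
  plasmid <- lig$plasmid
  plasmid$name <- paste0("assembly_", vec$id)
  junctions <- tibble::tibble(
    letter = overhang_letter(features_junction_seqs(plasmid, features),
      toolkit$overhangs),
    sequence = features_junction_seqs(plasmid, features),
    position = features$start
  )
  structure(
    list(plasmid = plasmid, features = features, junctions = junctions,
      canonical = canonical_form(plasmid), design = design),
    class = "gg_construct"
  )
}

features_junction_seqs <- function(plasmid, features) {
  ext <- paste0(plasmid$seq, substr(plasmid$seq, 1, 4))
  substring(ext, features$start + 1L, features$start + 4L)
}

overhang_letter <- function(seqs, overhangs) {
  i <- match(seqs, overhangs$sequence)
  ifelse(is.na(i), seqs, overhangs$letter[i])
}

#' Enumerate a combinatorial design space
#'
#' Combinatorial pooling is expressed as per-slot option lists; the design
#' space is their Cartesian product, enumerated deterministically
#' (slots in grammar order, option ids sorted, last slot varying fastest)
#' or sampled with a seed.
#'
#' @param options Named list: slot id -> character vector of brick ids.
#' @param topology Design topology.
#' @param vector_id Destination vector id used for every design.
#' @param sample_k If non-`NULL`, return `sample_k` designs drawn without
#'   replacement (seeded).
#' @param seed RNG seed for sampling.
#' @return Tibble with one column per slot plus `vector_id`; attribute
#'   `n_designs` holds the total count (also returned for sampled grids).
#' @examples
#' opts <- list(Prom1 = c("a", "b", "c"), Gene1 = "g", Term1 = "t",
#'              InsUp = "u", InsDown = "d", Marker = "m")
#' attr(enumerate_designs(opts, "1TU", "V"), "n_designs")  # 3
#' @export
enumerate_designs <- function(options, topology = "3TU", vector_id,
                              sample_k = NULL, seed = 1L) {
  g <- gg_grammar(topology)
  slots <- intersect(g$slot, names(options))
  missing <- setdiff(setdiff(g$slot, "Backbone"), names(options))
  if (length(missing)) {
    rlang::abort(sprintf("no options for slot(s): %s", paste(missing, collapse = ", ")),
      class = "yaligg_bad_design")
  }
  if (any(lengths(options) == 0L)) {
    rlang::abort(sprintf("empty option list for slot(s): %s",
      paste(names(options)[lengths(options) == 0L], collapse = ", ")),
      class = "yaligg_bad_design")
  }
  opts <- purrr::map(options[slots], ~ sort(as.character(.x)))
  total <- prod(lengths(opts))
  if (is.null(sample_k)) {
    grid <- rev(expand.grid(rev(opts), stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE))
    out <- tibble::as_tibble(grid)
  } else {
    stopifnot(sample_k <= total)
    idx <- withr::with_seed(seed, sort(sample.int(total, sample_k)))
    # decode mixed-radix indices (0-based) into option choices
    radix <- lengths(opts)
    out <- purrr::map(idx - 1L, function(k) {
      digit <- integer(length(radix))
      for (j in rev(seq_along(radix))) {
        digit[j] <- k %% radix[j]
        k <- k %/% radix[j]
      }
      tibble::as_tibble(stats::setNames(
        purrr::map2(opts, digit, ~ .x[.y + 1L]), slots))
    }) |> dplyr::bind_rows()
  }
  out$vector_id <- vector_id
  structure(out, n_designs = total, topology = topology)
}

#' Turn one enumerated row into a design
#'
#' @param row One row of the tibble returned by [enumerate_designs()].
#' @param topology Design topology (defaults to the enumeration's).
#' @return A [gg_design()].
#' @export
design_from_row <- function(row, topology = attr(row, "topology") %||% "3TU") {
  slots <- as.list(row[setdiff(names(row), "vector_id")])
  gg_design(topology, unlist(slots), row$vector_id)
}
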