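#' Read and write FASTA
#'
#' Thin wrappers over Biostrings; topology is not part of FASTA, so
#' `circular` applies to every record read.
#'
#' @param path File path.
#' @param circular Topology assigned to the records read.
#' @return `read_fasta()`: list of [dna_seq]. `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path, circular = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  purrr::map2(as.character(set), names(set),
    function(s, n) dna_seq(s, circular = circular, name = n))
}

#' @rdname read_fasta
#' @param seqs A [dna_seq] or list of them.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(x) x$seq, ""))
  names(set) <- vapply(seqs, function(x) {
    if (nzchar(x$name)) x$name else "unnamed"
  }, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Minimal GenBank flat-file writer
#'
#' Writes a LOCUS/FEATURES/ORIGIN record with `misc_feature` annotations.
#' Coordinates are converted from the package's 0-based half-open internal
#' convention to GenBank's 1-based inclusive spans; features crossing the
#' origin of circular molecules use `join()` notation. The LOCUS date is a
#' constant so identical inputs give byte-identical files.
#'
#' @param seq A [dna_seq] (or `gg_construct`, whose features are used).
#' @param path Output path.
#' @param features Optional tibble with `start`, `end` (0-based half-open),
#'   and annotation columns (`name`/`slot`/`category` become qualifiers).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path, features = NULL) {
  if (inherits(seq, "gg_construct")) {
    if (is.null(features)) features <- seq$features
    seq <- seq$plasmid
  }
  n <- nchar(seq$seq)
  name <- if (nzchar(seq$name)) gsub("\\s+", "_", seq$name) else "unnamed"
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2019",
    name, n, if (seq$circular) "circular" else "linear"))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features))) {
      a <- features$start[i] + 1L
      b <- features$end[i]
      if (b == 0L) b <- n
      loc <- if (a <= b) sprintf("%d..%d", a, b) else
        sprintf("join(%d..%d,1..%d)", a, n, b)
      lines <- c(lines, sprintf("     misc_feature    %s", loc))
      for (q in intersect(c("name", "slot", "category", "letter"), names(features))) {
        v <- features[[q]][i]
        if (!is.na(v)) {
          lines <- c(lines, sprintf("                     /%s=\"%s\"",
            if (q == "name") "label" else q, v))
        }
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(seq$seq)
  starts <- seq(1L, n, 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Minimal GenBank flat-file reader
#'
#' Parses records written by [write_genbank()] (and plain single-record
#' GenBank files with `misc_feature` annotations). The LOCUS `circular`
#' token sets the topology; coordinates are converted back to 0-based
#' half-open.
#'
#' @param path GenBank file path.
#' @return List with `seq` (a [dna_seq]) and `features` (tibble `start`,
#'   `end`, `name`, `slot`, `category`, `letter`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  if (is.na(locus)) rlang::abort("not a GenBank file: no LOCUS line")
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  name <- toks[1]
  circular <- any(tolower(toks) == "circular")
  ori <- which(grepl("^ORIGIN", lines))[1]
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  s <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(s)

  feats <- list()
  fstart <- which(grepl("^FEATURES", lines))[1]
  cur <- NULL
  if (!is.na(fstart)) {
    for (ln in lines[(fstart + 1L):(ori - 1L)]) {
      if (grepl("^\\s{5}\\S", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        loc <- parts[2]
        if (grepl("^join", loc)) {
          m <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
          a <- m[1]; b <- m[4]
        } else {
          m <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
          a <- m[1]; b <- m[2]
        }
        cur <- list(type = parts[1], start = a - 1L, end = if (b == n) 0L else b,
          name = NA_character_, slot = NA_character_,
          category = NA_character_, letter = NA_character_)
        # 0-based half-open; end == parent length is stored as 0 only for
        # origin-wrapping bookkeeping symmetry with write_genbank
        if (b <= n && a <= b) cur$end <- b
      } else if (!is.null(cur) && grepl("/", ln)) {
        q <- sub("^\\s*/", "", trimws(ln))
        key <- sub("=.*$", "", q)
        val <- gsub("\"", "", sub("^[^=]*=", "", q))
        if (key == "label") key <- "name"
        if (key %in% c("name", "slot", "category", "letter")) cur[[key]] <- val
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  features <- if (length(feats)) {
    dplyr::bind_rows(purrr::map(feats, tibble::as_tibble))
  } else {
    tibble::tibble(type = character(), start = integer(), end = integer(),
      name = character(), slot = character(), category = character(),
      letter = character())
  }
  list(seq = dna_seq(s, circular = circular, name = name), features = features)
}
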