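#' Read a protein FASTA file
#'
#' Parses an amino-acid FASTA file into a tibble, one row per record. The
#' record id is the header token up to the first whitespace; the remainder is
#' kept as `description`. An `organism=<key>` token in the description (the
#' convention used by [write_fasta()] and the simulator) is parsed into the
#' `organism_key` column, `NA` when absent. Sequences are case-normalized to
#' upper and validated against the 20 standard residues plus the ambiguity
#' codes X, B, Z and the rare residues U, O.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `organism_key`,
#'   `sequence`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 organism=tax1", "ACDE", "FGHK"), f)
#' read_fasta(f)
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) abort(sprintf("FASTA file is empty: %s", path))
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort("Malformed FASTA: sequence data before the first '>' header.")
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) abort("Malformed FASTA: empty record id in a header.")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- vapply(split(lines[!is_header], rec_idx[!is_header]),
                 paste0, character(1), collapse = "")
  # records with a header but no sequence lines
  missing <- setdiff(seq_along(ids), as.integer(names(seqs)))
  if (length(missing) > 0L) {
    abort(sprintf("FASTA record(s) with no sequence: %s",
                  paste(ids[missing], collapse = ", ")))
  }
  seqs <- unname(toupper(seqs[order(as.integer(names(seqs)))]))
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "Illegal residue character '%s' in record '%s' at position %d.",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  org <- stringr::str_match(desc, "(?:^|\\s)organism=(\\S+)")[, 2L]
  tibble(id = ids, description = desc, organism_key = org, sequence = seqs)
}

#' Write protein sequences to FASTA
#'
#' The header is `>id organism=<organism_key>` when `organism_key` is present
#' (so organism provenance survives a round-trip through [read_fasta()]),
#' otherwise `>id description`.
#'
#' @param sequences Tibble with columns `id`, `sequence`, and optionally
#'   `organism_key` and `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  org <- if ("organism_key" %in% names(sequences)) sequences$organism_key else
    rep(NA_character_, nrow(sequences))
  desc <- if ("description" %in% names(sequences)) sequences$description else
    rep("", nrow(sequences))
  header <- ifelse(!is.na(org) & org != "",
                   paste0(">", sequences$id, " organism=", org),
                   ifelse(desc != "", paste0(">", sequences$id, " ", desc),
                          paste0(">", sequences$id)))
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    starts <- seq(1L, nchar(s), by = width)
    vapply(starts, function(i) substr(s, i, min(i + width - 1L, nchar(s))),
           character(1))
  }
  body <- purrr::map2(header, toupper(sequences$sequence),
                      function(h, s) c(h, wrap(s)))
  readr::write_lines(unlist(body), path)
  invisible(path)
}
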