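#' Read a CD-HIT cluster file
#'
#' Parses the `.clstr` dialect written by CD-HIT: `>Cluster N` headers
#' followed by member lines of the form
#' `0\t382aa, >SEQID... *` (representative) or
#' `1\t350aa, >SEQID... at 95.5%` (member aligned to the representative).
#'
#' @param path Path to a `.clstr` file.
#' @return A tibble with columns `id` (sequence id), `cluster` (integer
#'   cluster index from the file) and `representative` (logical). Every id
#'   belongs to exactly one cluster; every cluster has exactly one
#'   representative.
#' @examples
#' f <- tempfile(fileext = ".clstr")
#' writeLines(c(">Cluster 0",
#'              "0\t4aa, >p1... *",
#'              "1\t4aa, >p2... at 75.00%"), f)
#' read_clstr(f)
#' @export
read_clstr <- function(path) {
  if (!file.exists(path)) abort(sprintf(".clstr file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) abort(sprintf(".clstr file is empty: %s", path))
  is_header <- grepl("^>Cluster\\s+\\d+", lines)
  if (!is_header[1L]) {
    abort(sprintf("Malformed .clstr: member line before any '>Cluster' header (line %d).",
                  1L))
  }
  cluster_of_line <- cumsum(is_header)
  cluster_ids <- as.integer(sub("^>Cluster\\s+(\\d+).*$", "\\1", lines[is_header]))
  member_lines <- lines[!is_header]
  member_lineno <- which(!is_header)
  m <- stringr::str_match(member_lines, ">\\s*(.+?)\\.\\.\\.")
  if (anyNA(m[, 2L])) {
    bad <- member_lineno[which(is.na(m[, 2L]))[1L]]
    abort(sprintf("Malformed .clstr member line %d: cannot find '>id...' token.", bad))
  }
  out <- tibble(
    id = m[, 2L],
    cluster = cluster_ids[cluster_of_line[!is_header]],
    representative = grepl("\\*\\s*$", member_lines)
  )
  empty <- setdiff(cluster_ids, out$cluster)
  if (length(empty) > 0L) {
    abort(sprintf("Cluster(s) with zero members: %s",
                  paste(empty, collapse = ", ")))
  }
  if (anyDuplicated(out$id)) {
    dup <- unique(out$id[duplicated(out$id)])
    abort(sprintf("Sequence id(s) listed in more than one cluster: %s",
                  paste(dup, collapse = ", ")))
  }
  n_rep <- tapply(out$representative, out$cluster, sum)
  if (any(n_rep != 1L)) {
    abort(sprintf("Cluster(s) without exactly one representative: %s",
                  paste(names(n_rep)[n_rep != 1L], collapse = ", ")))
  }
  out
}
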