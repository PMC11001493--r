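#' Read / write organism growth-temperature annotations
#'
#' The annotation table is a two-column tab-separated file,
#' `organism_key<TAB>growth_temperature_celsius`, with a header row. Growth
#' temperatures must be finite and within the plausibility window
#' \[-20, 150\] degrees C (hydrothermal-vent archaea top out near 120).
#'
#' @param path File path.
#' @return `read_annotations()`: a tibble with columns `organism_key`
#'   (character) and `growth_temperature` (double, degrees C).
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    organism_key = readr::col_character(),
    growth_temperature = readr::col_double()
  ))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param annotations Tibble with `organism_key` and `growth_temperature`.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_tsv(annotations[c("organism_key", "growth_temperature")], path)
  invisible(path)
}

validate_annotations <- function(ann) {
  stopifnot(all(c("organism_key", "growth_temperature") %in% names(ann)))
  t <- ann$growth_temperature
  if (any(!is.finite(t))) {
    abort("Non-finite growth temperature(s) in annotation table.")
  }
  if (any(t < -20 | t > 150)) {
    bad <- ann$organism_key[t < -20 | t > 150]
    abort(sprintf(
      "Growth temperature outside the plausible range [-20, 150] C for: %s",
      paste(head(bad, 5), collapse = ", ")))
  }
  as_tibble(ann)
}

#' Write / read a prediction table
#'
#' Serializes a prediction-profile tibble (see [predict_profiles()]) as TSV:
#' one row per query with columns `sequence_id`, one probability and one
#' binary-call column per threshold in ascending temperature order
#' (`prob_<T>`, `call_<T>`), then `left_label`, `right_label` and `clash`
#' (literal `true`/`false`). Probabilities are printed with a fixed number of
#' decimals (default 4); the table round-trips through [read_predictions()]
#' losslessly up to that printed precision.
#'
#' @param profiles Profile tibble from [predict_profiles()] (or one with the
#'   same columns and a `thresholds` attribute).
#' @param path Output path.
#' @param digits Decimal places for probabilities (default 4).
#' @return `path` invisibly; `read_predictions()` returns the profile tibble
#'   with the `thresholds` attribute restored.
#' @export
write_predictions <- function(profiles, path, digits = 4) {
  thresholds <- attr(profiles, "thresholds")
  if (is.null(thresholds)) {
    thresholds <- thresholds_from_columns(profiles)
  }
  check_ascending(thresholds)
  pc <- prob_col(thresholds)
  cc <- call_col(thresholds)
  need <- c("sequence_id", pc, cc, "left_label", "right_label", "clash")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0L) {
    abort(sprintf(
      "Profiles do not share the expected threshold set; missing column(s): %s",
      paste(miss, collapse = ", ")))
  }
  extra <- setdiff(grep("^(prob|call)_", names(profiles), value = TRUE), c(pc, cc))
  if (length(extra) > 0L) {
    abort(sprintf("Mixed threshold sets: unexpected column(s) %s",
                  paste(extra, collapse = ", ")))
  }
  out <- profiles[need]
  for (p in pc) out[[p]] <- sprintf(paste0("%.", digits, "f"), profiles[[p]])
  out$clash <- ifelse(profiles$clash, "true", "false")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    sequence_id = readr::col_character(),
    left_label = readr::col_character(),
    right_label = readr::col_character(),
    clash = readr::col_character()
  ))
  thresholds <- thresholds_from_columns(tab)
  tab$clash <- tab$clash == "true"
  for (cc in call_col(thresholds)) tab[[cc]] <- as.integer(tab[[cc]])
  structure(as_tibble(tab), thresholds = thresholds)
}

thresholds_from_columns <- function(tab) {
  pc <- grep("^prob_", names(tab), value = TRUE)
  if (length(pc) == 0L) abort("No prob_<T> columns found.")
  sort(as.numeric(sub("^prob_", "", pc)))
}

#' Write / read a dataset split manifest
#'
#' The manifest records, per sequence: the assigned subset (train /
#' validation / test), its cluster id, the organism growth temperature and
#' the per-threshold binary stability labels (`label_<T>` columns).
#'
#' @param manifest Tibble as produced by [cluster_disjoint_split()] joined
#'   with labels (see [run_build_dataset()]).
#' @param path File path (TSV).
#' @return The manifest tibble (read) or `path` invisibly (write).
#' @export
write_split_manifest <- function(manifest, path) {
  stopifnot(all(c("sequence_id", "subset", "cluster") %in% names(manifest)))
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    sequence_id = readr::col_character(),
    subset = readr::col_character(),
    cluster = readr::col_integer(),
    organism_key = readr::col_character()
  ))
}

#' Write / read a mean-embedding cache
#'
#' Mean embeddings are cached as TSV: `sequence_id` followed by D feature
#' columns printed with 17 significant digits, which round-trips IEEE doubles
#' exactly. A JSON sidecar (`<path>.json`) records the embedder fingerprint
#' (embedder key, dimension, seed) so stale caches are detectable.
#'
#' @param embeddings Tibble with `sequence_id` and an `embedding` list-column.
#' @param path Cache path (TSV).
#' @param fingerprint Optional named list identifying the embedder
#'   (e.g. `list(embedder = "mock-hash", D = 128, seed = 1)`).
#' @return `path` invisibly; `read_embeddings()` returns the tibble with the
#'   fingerprint (if any) as attribute `fingerprint`.
#' @export
write_embeddings <- function(embeddings, path, fingerprint = NULL) {
  m <- embedding_matrix(embeddings)
  lines <- c(
    paste(c("sequence_id", paste0("e", seq_len(ncol(m)))), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(embeddings$sequence_id[i], sprintf("%.17g", m[i, ])),
            collapse = "\t")
    }, character(1))
  )
  readr::write_lines(lines, path)
  if (!is.null(fingerprint)) {
    fingerprint$content_hash <- rlang::hash(m)
    jsonlite::write_json(fingerprint, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  # parsed with base R's strtod (correctly rounded), so "%.17g" output
  # round-trips doubles bit-exactly
  lines <- readr::read_lines(path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  out <- tibble(
    sequence_id = vapply(parts, `[[`, character(1), 1L),
    embedding = lapply(parts, function(p) as.double(p[-1L]))
  )
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "fingerprint") <- jsonlite::read_json(sidecar)
  }
  out
}
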