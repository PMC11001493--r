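# Multi-threshold consistency layer: binarization, left/right temperature-
# range labels, clash detection, and range naming.

#' Temperature ranges tiled by a threshold grid
#'
#' An ascending grid T1 < ... < Tn tiles the temperature axis into n + 1
#' half-open ranges: (-Inf, T1), [T1, T2), ..., [Tn, Inf), rendered as
#' `"<T1"`, `"[T1,T2)"`, ..., `"Tn+"`.
#'
#' @param thresholds Strictly ascending thresholds (degrees C).
#' @return Tibble with `index` (0-based: index i has lower bound Ti, index 0
#'   is the sub-T1 range), `lower`, `upper` and `name`.
#' @examples
#' temperature_ranges(threshold_grid())
#' @export
temperature_ranges <- function(thresholds = threshold_grid()) {
  check_ascending(thresholds)
  n <- length(thresholds)
  f <- format(thresholds, trim = TRUE)
  tibble(
    index = 0:n,
    lower = c(-Inf, thresholds),
    upper = c(thresholds, Inf),
    name = c(paste0("<", f[1L]),
             if (n > 1L) sprintf("[%s,%s)", f[-n], f[-1L]),
             paste0(f[n], "+"))
  )
}

#' Binarize predicted probabilities
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param cutoff Decision cutoff in (0, 1); the call is 1 when
#'   `p >= cutoff` (boundary inclusive). Default 0.5.
#' @return Integer vector of 0/1 calls.
#' @export
binarize <- function(probabilities, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1).")
  if (any(!is.finite(probabilities) | probabilities < 0 | probabilities > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  as.integer(probabilities >= cutoff)
}

#' Left-hand / right-hand labels and clash flag
#'
#' Scans the ordered per-threshold binary calls from both ends. The
#' left-hand label is the range of the last positive call in the *leading*
#' run of 1s (the scan stops at the first 0); the right-hand label is the
#' range of the highest positive call anywhere. When all calls are 0 both
#' labels are the first range (below the lowest threshold). Because
#' independent per-threshold classifiers can disagree non-monotonically, the
#' two labels can differ; that disagreement is the clash flag. For monotone
#' non-increasing call vectors left and right coincide and name the highest
#' temperature range at which the protein is predicted to still be stable.
#'
#' @param calls Integer 0/1 vector, one call per threshold.
#' @param thresholds Ascending thresholds, same length as `calls`.
#' @return A list with `left`, `right` (one-row range tibbles as in
#'   [temperature_ranges()]), `left_label`, `right_label` (names) and
#'   `clash` (logical). The left range index never exceeds the right one.
#' @examples
#' left_right_labels(c(1, 1, 1, 0, 0, 0), threshold_grid())
#' left_right_labels(c(0, 0, 1, 0, 0, 0), threshold_grid())  # clash
#' @export
left_right_labels <- function(calls, thresholds = threshold_grid()) {
  check_ascending(thresholds)
  if (length(calls) != length(thresholds)) {
    abort(sprintf("Got %d calls for %d thresholds.",
                  length(calls), length(thresholds)))
  }
  if (!all(calls %in% c(0L, 1L))) abort("Calls must be 0/1.")
  ranges <- temperature_ranges(thresholds)
  ones <- which(calls == 1L)
  j <- if (length(ones) == 0L || ones[1L] != 1L) 0L else {
    # length of the maximal leading run of 1s
    gap <- which(diff(ones) > 1L)
    if (length(gap) == 0L) length(ones) else gap[1L]
  }
  m <- if (length(ones) == 0L) 0L else max(ones)
  list(
    left = ranges[j + 1L, ],
    right = ranges[m + 1L, ],
    left_label = ranges$name[j + 1L],
    right_label = ranges$name[m + 1L],
    clash = j != m
  )
}

#' Count clash-free call vectors
#'
#' Of the 2^n possible 0/1 call vectors over n thresholds, exactly the
#' monotone non-increasing ones (a leading run of 1s, possibly empty) are
#' clash-free — n + 1 vectors. Exhaustive enumeration utility used to
#' validate the label logic.
#'
#' @param n_thresholds Number of thresholds (>= 1).
#' @return A list with `total` (2^n), `clash_free` (count), and the
#'   clash-free vectors as rows of `vectors`.
#' @export
enumerate_consistency <- function(n_thresholds) {
  stopifnot(n_thresholds >= 1)
  grid <- as.matrix(expand.grid(rep(list(0:1), n_thresholds)))
  dimnames(grid) <- NULL
  thresholds <- seq(40, by = 5, length.out = n_thresholds)
  free <- apply(grid, 1L, function(v) {
    !left_right_labels(as.integer(v), thresholds)$clash
  })
  list(total = nrow(grid), clash_free = sum(free),
       vectors = grid[free, , drop = FALSE])
}

#' Prediction profiles from threshold ensembles
#'
#' Runs every ensemble over the query embeddings and condenses the ordered
#' per-threshold probabilities into binary calls, left/right temperature-
#' range labels and the clash flag.
#'
#' @param ensembles List of `thermo_ensemble`s in strictly ascending
#'   threshold order (duplicates rejected), e.g. from [train_ensembles()] or
#'   [load_ensemble_set()].
#' @param data Query embeddings: tibble with `sequence_id` + `embedding`
#'   list-column, or an N x D matrix with rownames.
#' @param cutoff Binarization cutoff (default 0.5).
#' @return Profile tibble: `sequence_id`, `prob_<T>` and `call_<T>` per
#'   threshold (ascending), `left_label`, `right_label`, `clash` (logical);
#'   attribute `thresholds`.
#' @export
predict_profiles <- function(ensembles, data, cutoff = 0.5) {
  thresholds <- vapply(ensembles, function(e) e$threshold, numeric(1))
  if (anyDuplicated(thresholds) || is.unsorted(thresholds, strictly = TRUE)) {
    abort(sprintf("Ensembles must be sorted by strictly ascending threshold (got: %s).",
                  paste(thresholds, collapse = ", ")))
  }
  X <- if (is.matrix(data)) data else embedding_matrix(data)
  ids <- if (is.matrix(data)) {
    rownames(data) %||% sprintf("query%04d", seq_len(nrow(data)))
  } else data$sequence_id
  probs <- vapply(ensembles, function(e) ensemble_predict(e, X),
                  numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  calls <- matrix(binarize(as.vector(probs), cutoff), nrow = nrow(probs))
  lab <- lapply(seq_len(nrow(calls)), function(i) {
    left_right_labels(calls[i, ], thresholds)
  })
  out <- tibble(sequence_id = ids)
  for (k in seq_along(thresholds)) out[[prob_col(thresholds[k])]] <- probs[, k]
  for (k in seq_along(thresholds)) out[[call_col(thresholds[k])]] <- calls[, k]
  out$left_label <- vapply(lab, `[[`, character(1), "left_label")
  out$right_label <- vapply(lab, `[[`, character(1), "right_label")
  out$clash <- vapply(lab, `[[`, logical(1), "clash")
  structure(out, thresholds = thresholds)
}

#' Prediction profile for a single query vector
#'
#' Single-query convenience wrapper around [predict_profiles()].
#'
#' @inheritParams predict_profiles
#' @param x Length-D numeric vector.
#' @return One-row profile tibble (see [predict_profiles()]).
#' @export
profile_from_ensembles <- function(ensembles, x, cutoff = 0.5) {
  m <- matrix(x, nrow = 1L)
  predict_profiles(ensembles, m, cutoff = cutoff)
}
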