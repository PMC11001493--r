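#' Per-threshold binary stability labels from a growth temperature
#'
#' A protein inherits its host organism's optimal growth temperature (OGT) as
#' a stability lower bound: for each threshold T the label is 1 when
#' OGT >= T ("stable at T and above") and 0 otherwise. Labels are therefore
#' monotone non-increasing along the ascending threshold grid by
#' construction.
#'
#' @param growth_temperature OGT in degrees C (single finite number).
#' @param thresholds Strictly ascending numeric thresholds in degrees C.
#' @return Named integer vector of 0/1 labels, names `label_<T>`.
#' @examples
#' assign_threshold_labels(52, threshold_grid())
#' @export
assign_threshold_labels <- function(growth_temperature,
                                    thresholds = threshold_grid()) {
  check_number(growth_temperature, "growth_temperature")
  check_ascending(thresholds)
  setNames(as.integer(growth_temperature >= thresholds), label_col(thresholds))
}

#' Add per-threshold label columns to a dataset
#'
#' Tidy-verb counterpart of [assign_threshold_labels()]: appends one
#' `label_<T>` column per threshold, derived from the `growth_temperature`
#' column.
#'
#' @param data Tibble with a `growth_temperature` column.
#' @inheritParams assign_threshold_labels
#' @return `data` with `label_<T>` columns appended.
#' @export
add_threshold_labels <- function(data, thresholds = threshold_grid()) {
  check_ascending(thresholds)
  if (!"growth_temperature" %in% names(data)) {
    abort("`data` must have a `growth_temperature` column.")
  }
  if (any(!is.finite(data$growth_temperature))) {
    abort("Non-finite growth temperature(s) in `data`.")
  }
  for (t in thresholds) {
    data[[label_col(t)]] <- as.integer(data$growth_temperature >= t)
  }
  data
}

#' Cluster-disjoint train/validation/test split
#'
#' Assigns whole sequence-identity clusters to subsets so that no two
#' sequences from the same cluster ever land in different subsets,
#' preventing homology leakage between training and evaluation. Cluster ids
#' are shuffled with the given seed, then each cluster is assigned greedily
#' to the subset with the largest remaining deficit relative to its target
#' share of the total sequence count.
#'
#' @param data Tibble of examples with a `sequence_id` column.
#' @param clusters Cluster table (tibble with `id`, `cluster`), e.g. from
#'   [read_clstr()] or [greedy_cluster()].
#' @param fractions Numeric length-3 vector `(train, validation, test)`
#'   summing to 1. Default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   split.
#' @return `data` with `subset` (factor train/validation/test) and `cluster`
#'   columns appended; attribute `provenance` holds the cluster-id sets per
#'   subset and the realized fractions.
#' @export
cluster_disjoint_split <- function(data, clusters,
                                   fractions = c(0.70, 0.15, 0.15),
                                   seed = 1L) {
  stopifnot("sequence_id" %in% names(data))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0)) {
    abort(sprintf("`fractions` must be 3 non-negative numbers summing to 1 (got %s).",
                  paste(format(fractions), collapse = ", ")))
  }
  missing <- setdiff(data$sequence_id, clusters$id)
  if (length(missing) > 0L) {
    abort(sprintf("Example(s) missing from the cluster table: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else ""))
  }
  subset_names <- c("train", "validation", "test")
  cl <- clusters$cluster[match(data$sequence_id, clusters$id)]
  sizes <- table(cl)
  ids <- names(sizes)
  order_ids <- with_seed(seed, sample(ids))
  total <- nrow(data)
  target <- fractions * total
  got <- c(0, 0, 0)
  assign <- setNames(character(length(order_ids)), order_ids)
  for (cid in order_ids) {
    deficit <- target - got
    k <- which.max(deficit)
    assign[cid] <- subset_names[k]
    got[k] <- got[k] + sizes[[cid]]
  }
  subset <- factor(assign[as.character(cl)], levels = subset_names)
  realized <- as.vector(table(subset)) / total
  if (any(fractions > 0 & realized == 0)) {
    warn(paste(
      "Some subsets received no sequences: too few clusters to honour the",
      "requested fractions (clusters are assigned atomically)."))
  }
  out <- data
  out$subset <- subset
  out$cluster <- as.integer(as.character(cl))
  attr(out, "provenance") <- list(
    seed = seed,
    fractions = setNames(fractions, subset_names),
    realized_fractions = setNames(realized, subset_names),
    clusters = split(as.integer(order_ids), assign[order_ids])
  )
  out
}

#' Class-balanced subsample at one threshold
#'
#' Randomly samples, without replacement, exactly `n/2` positive and `n/2`
#' negative examples at the given temperature threshold — the construction
#' used to report metrics on a balanced evaluation subset when the full test
#' set is heavily imbalanced.
#'
#' @param data Tibble with `sequence_id` and either a `label_<T>` column or a
#'   `growth_temperature` column to derive it from.
#' @param threshold Temperature threshold in degrees C.
#' @param n Total subsample size (even).
#' @param seed Integer seed.
#' @return Tibble of `n` rows, `n/2` per class, in stable (positive-first)
#'   order.
#' @export
balanced_subsample <- function(data, threshold, n, seed = 1L) {
  if (n %% 2L != 0L) abort("`n` must be even for an exactly balanced sample.")
  lc <- label_col(threshold)
  y <- if (lc %in% names(data)) data[[lc]] else
    as.integer(data$growth_temperature >= threshold)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) < n / 2 || length(neg) < n / 2) {
    abort(sprintf(
      "Cannot draw %d per class at threshold %s C: available class 1 = %d, class 0 = %d.",
      n / 2, format(threshold), length(pos), length(neg)))
  }
  idx <- with_seed(seed, c(sample(pos, n / 2), sample(neg, n / 2)))
  data[idx, , drop = FALSE]
}

#' Greedy k-mer sequence clustering
#'
#' A self-contained stand-in for an external identity clusterer so the
#' pipeline runs without CD-HIT installed. Records are sorted by descending
#' length; each record joins the first existing cluster whose representative
#' shares at least `identity_threshold` identity under ungapped k-mer
#' containment (k = 5; identity = fraction of the shorter sequence's distinct
#' 5-mers found in the longer one's), otherwise it founds a new cluster and
#' becomes its representative.
#'
#' @param sequences Tibble with `id` and `sequence`.
#' @param identity_threshold Fraction in (0, 1); 0.3 mirrors a 30 percent
#'   identity clustering.
#' @param k k-mer length (default 5).
#' @return Cluster table tibble (`id`, `cluster`, `representative`), same
#'   schema as [read_clstr()].
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.3, k = 5L) {
  if (nrow(sequences) == 0L) abort("Cannot cluster an empty record list.")
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    abort("`identity_threshold` must be strictly between 0 and 1.")
  }
  ord <- order(-nchar(sequences$sequence), sequences$id)
  ids <- sequences$id[ord]
  seqs <- toupper(sequences$sequence[ord])
  kmer_sets <- lapply(seqs, kmer_set, k = k)
  rep_idx <- integer(0)       # index (into ord) of each cluster representative
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (c in seq_along(rep_idx)) {
      if (kmer_identity(kmer_sets[[i]], kmer_sets[[rep_idx[c]]]) >=
          identity_threshold) {
        assignment[i] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
    }
  }
  tibble(
    id = ids,
    cluster = assignment - 1L,
    representative = seq_along(ids) %in% rep_idx
  )[order(match(ids, sequences$id)), ]
}

kmer_set <- function(s, k = 5L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), k:n))
}

# Identity = shared distinct k-mers as a fraction of the smaller set.
kmer_identity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  shared <- length(intersect(a, b))
  shared / min(length(a), length(b))
}
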