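# Binary-classification metric panel, computed from first principles.

#' Confusion matrix counts
#'
#' @param labels,calls Equal-length 0/1 vectors; TP counts label 1 called 1.
#' @return A list of class `confusion` with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls) || length(labels) < 1L) {
    abort("`labels` and `calls` must have equal length >= 1.")
  }
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (!all(labels %in% 0:1) || !all(calls %in% 0:1)) {
    abort("`labels` and `calls` must be 0/1.")
  }
  structure(list(
    tp = sum(labels == 1L & calls == 1L),
    fp = sum(labels == 0L & calls == 1L),
    tn = sum(labels == 0L & calls == 0L),
    fn = sum(labels == 1L & calls == 0L)
  ), class = "confusion")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention MCC = 0 whenever any of the four marginal factors is zero
#' (e.g. a single-class prediction, common in early training epochs).
#'
#' @param cm A `confusion` object (or list with `tp`, `fp`, `tn`, `fn`).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  tp <- as.double(cm$tp); fp <- as.double(cm$fp)
  tn <- as.double(cm$tn); fn <- as.double(cm$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' ROC AUC by the rank statistic
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with ties counted one half — the Mann-Whitney
#' formulation, exact under ties.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("ROC AUC needs both classes present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC by step summation
#'
#' Area under the precision-recall curve via the average-precision style
#' step sum `sum_i (R_i - R_{i-1}) * P_i` over descending distinct score
#' cut-points (not trapezoids; the two differ and this is the convention
#' used throughout the package).
#'
#' @inheritParams roc_auc
#' @return PR AUC in (0, 1].
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) abort("PR AUC needs at least one positive.")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  # evaluate only at the last index of each distinct score (tie groups act
  # as one cut-point)
  last <- which(s != c(s[-1L], NA) | cum_n == length(y))
  prec <- cum_tp[last] / cum_n[last]
  rec <- cum_tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Full metric panel for one classifier on one evaluation set
#'
#' Computes the confusion matrix at `cutoff` and the derived panel: MCC
#' (primary), accuracy, precision, recall (sensitivity), specificity, F1,
#' plus threshold-free ROC AUC and PR AUC from the scores. Precision,
#' recall and F1 fall back to 0 when their denominators vanish.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted probabilities.
#' @param cutoff Binarization cutoff (default 0.5).
#' @return One-row tibble: `n`, `tp`, `fp`, `tn`, `fn`, `mcc`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`, `roc_auc`, `pr_auc`.
#' @export
metric_panel <- function(labels, scores, cutoff = 0.5) {
  calls <- binarize(scores, cutoff)
  cm <- confusion(labels, calls)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  tibble(
    n = tp + fp + tn + fn, tp = tp, fp = fp, tn = tn, fn = fn,
    mcc = mcc(cm),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = prec, recall = rec, specificity = spec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    roc_auc = roc_auc(labels, scores),
    pr_auc = pr_auc(labels, scores)
  )
}

#' Two-component PCA of mean embeddings
#'
#' Quality-control projection of mean embedding vectors onto the top two
#' principal components of the mean-centred sample covariance (no scaling),
#' e.g. to check visually that embeddings separate by growth temperature.
#'
#' @param x N x D matrix (N >= 3, D >= 2) or tibble with an `embedding`
#'   list-column.
#' @return An object of class `thermo_pca`: `scores` (tibble `PC1`, `PC2`,
#'   plus `sequence_id` when available) and `explained` (two variance
#'   fractions, descending).
#' @export
pca2 <- function(x) {
  ids <- NULL
  if (!is.matrix(x)) {
    ids <- x$sequence_id
    x <- embedding_matrix(x)
  }
  if (nrow(x) < 3L) abort("PCA needs at least 3 observations.")
  if (ncol(x) < 2L) abort("PCA needs at least 2 features.")
  total_var <- sum(apply(x, 2L, stats::var))
  if (total_var == 0) abort("PCA is undefined for rank-0 (constant) data.")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  scores <- tibble(PC1 = pc$x[, 1L], PC2 = pc$x[, 2L])
  if (!is.null(ids)) scores <- tibble(sequence_id = ids, scores)
  structure(list(
    scores = scores,
    explained = pc$sdev[1:2]^2 / total_var,
    rotation = pc$rotation
  ), class = "thermo_pca")
}

#' @export
print.thermo_pca <- function(x, ...) {
  cat(sprintf("<thermo_pca> %d points; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}

#' Evaluate ensembles on a labelled subset
#'
#' Runs each threshold ensemble over the examples and reports the full
#' metric panel per threshold — the package's evaluation-report table.
#'
#' @param ensembles Named list of `thermo_ensemble`s (ascending thresholds).
#' @param data Labelled examples (embedding list-column plus labels or
#'   `growth_temperature`).
#' @param cutoff Binarization cutoff.
#' @return Tibble, one row per threshold, with the [metric_panel()] columns.
#' @export
evaluate_ensembles <- function(ensembles, data, cutoff = 0.5) {
  X <- embedding_matrix(data)
  purrr::map_dfr(ensembles, function(e) {
    lc <- label_col(e$threshold)
    y <- if (lc %in% names(data)) as.integer(data[[lc]]) else
      as.integer(data$growth_temperature >= e$threshold)
    scores <- ensemble_predict(e, X)
    dplyr::bind_cols(tibble(threshold = e$threshold),
                     metric_panel(y, scores, cutoff))
  })
}
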