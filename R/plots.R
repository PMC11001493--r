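# ggplot2 views of fitted objects and reports.

#' @describeIn train_classifier Training curve: per-epoch loss and
#'   validation MCC, selected epoch marked.
#' @param object A `thermo_fit`.
#' @method autoplot thermo_fit
#' @export
autoplot.thermo_fit <- function(object, ...) {
  log <- tidyr::pivot_longer(object$log, c("loss", "val_mcc"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$model$meta$selected_epoch,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Threshold %s C classifier (seed %d)",
                      format(object$model$meta$threshold),
                      object$model$meta$seed),
      x = "epoch", y = NULL)
}

#' @describeIn pca2 Scatter of the two-component projection; pass
#'   `colour_by` (a vector aligned with the rows, e.g. growth temperatures)
#'   to colour the points.
#' @param object A `thermo_pca`.
#' @param colour_by Optional vector (e.g. OGT) to colour points by.
#' @param ... Unused.
#' @method autoplot thermo_pca
#' @export
autoplot.thermo_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_point(alpha = 0.6)
  } else {
    df$colour_by <- colour_by
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     colour = .data$colour_by)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1L]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2L]))
}

#' Per-threshold probability curves for prediction profiles
#'
#' Line plot of ensemble probabilities across the threshold grid, one line
#' per query, clash status distinguished — a quick visual of how coherent
#' the multi-threshold predictions are.
#'
#' @param profiles Profile tibble from [predict_profiles()].
#' @param max_queries Cap on the number of queries drawn (default 50).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, max_queries = 50) {
  thresholds <- attr(profiles, "thresholds") %||%
    thresholds_from_columns(profiles)
  keep <- head(seq_len(nrow(profiles)), max_queries)
  long <- tidyr::pivot_longer(
    profiles[keep, c("sequence_id", prob_col(thresholds), "clash")],
    dplyr::all_of(prob_col(thresholds)),
    names_to = "threshold", values_to = "probability")
  long$threshold <- as.numeric(sub("^prob_", "", long$threshold))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$probability,
    group = .data$sequence_id, colour = .data$clash)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "temperature threshold (C)",
                  y = "ensemble probability", colour = "clash")
}
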