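#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 1e-4 and
#' weight decay 1e-4, mini-batches of 24 drawn with a class-weighted random
#' sampler (with replacement), up to 30 epochs, and per-epoch model
#' selection by validation MCC. A seed is mandatory: there is no unseeded
#' training.
#'
#' @param seed Integer seed (required).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty folded into the Adam gradient.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs; the selected model is the
#'   per-epoch snapshot with the highest validation MCC (ties go to the
#'   earliest epoch).
#' @param weighted_sampler Draw batches with inverse-class-frequency weights
#'   (`TRUE`, default) or uniformly (`FALSE`); both sample with replacement.
#' @param cutoff Probability cutoff for validation binary calls.
#' @return A list of class `train_config`.
#' @export
train_config <- function(seed, learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 24L, max_epochs = 30L,
                         weighted_sampler = TRUE, cutoff = 0.5) {
  if (missing(seed)) abort("`seed` is required: no unseeded training.")
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, cutoff > 0, cutoff < 1)
  structure(list(
    seed = as.integer(seed), learning_rate = learning_rate,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    weighted_sampler = isTRUE(weighted_sampler), cutoff = cutoff
  ), class = "train_config")
}

#' Inverse-class-frequency sampling weights
#'
#' Each example's weight is the reciprocal of its class count, so sampling
#' with replacement under these weights yields an expected 1:1 class balance
#' regardless of the dataset's imbalance.
#'
#' @param labels Vector of 0/1 labels with both classes present.
#' @return Numeric weights, one per example.
#' @examples
#' sampler_weights(c(1, 0, 0, 0))
#' @export
sampler_weights <- function(labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort(sprintf("Both classes must be present (got %d positives, %d negatives).",
                  n1, n0))
  }
  ifelse(labels == 1L, 1 / n1, 1 / n0)
}

extract_xy <- function(data, threshold, what) {
  X <- embedding_matrix(data)
  lc <- label_col(threshold)
  y <- if (lc %in% names(data)) as.integer(data[[lc]]) else {
    if (!"growth_temperature" %in% names(data)) {
      abort(sprintf("`%s` needs a `%s` or `growth_temperature` column.",
                    what, lc))
    }
    as.integer(data$growth_temperature >= threshold)
  }
  if (length(unique(y)) < 2L) {
    abort(sprintf(
      "Single-class %s set at threshold %s C (%d positives / %d negatives).",
      what, format(threshold), sum(y == 1L), sum(y == 0L)))
  }
  list(X = X, y = y)
}

#' Train one per-threshold binary classifier
#'
#' Trains the multilayer perceptron with mini-batch Adam on class-weighted
#' random batches, evaluates MCC on the whole (unweighted) validation set
#' after every epoch, and returns the weight snapshot from the epoch with
#' the highest validation MCC (earliest epoch on ties). Fully
#' seed-deterministic under single-threaded execution.
#'
#' @param train,val Tibbles of labelled examples: an `embedding` list-column
#'   plus either a `label_<threshold>` column or `growth_temperature` to
#'   derive it. Both classes must be present in each.
#' @param threshold Temperature threshold in degrees C this classifier
#'   answers for.
#' @param spec An [mlp_spec()]; defaults to the reference architecture with
#'   `input_dim` taken from the data.
#' @param config A [train_config()].
#' @return An object of class `thermo_fit`: the selected `thermo_mlp` model
#'   (`$model`), the per-epoch training log (`$log`: epoch, loss, val_mcc)
#'   and the configuration. [tidy()] returns the log; [glance()] the
#'   one-row summary.
#' @export
train_classifier <- function(train, val, threshold,
                             spec = NULL, config = train_config(seed = 1L)) {
  tr <- extract_xy(train, threshold, "train")
  va <- extract_xy(val, threshold, "validation")
  if (is.null(spec)) spec <- mlp_spec(input_dim = ncol(tr$X))
  if (ncol(tr$X) != spec$input_dim || ncol(va$X) != spec$input_dim) {
    abort(sprintf("Embedding dimension (%d) does not match spec input_dim (%d).",
                  ncol(tr$X), spec$input_dim))
  }
  model <- init_mlp(spec, seed = config$seed)
  weights <- model$weights
  n_layers <- length(weights)
  N <- nrow(tr$X)
  n_batches <- ceiling(N / config$batch_size)
  w <- if (config$weighted_sampler) sampler_weights(tr$y) else NULL

  adam <- lapply(weights, function(l) list(
    W = list(m = l$W * 0, v = l$W * 0),
    b = list(m = l$b * 0, v = l$b * 0)
  ))
  step <- 0L
  best <- list(mcc = -Inf, epoch = NA_integer_, weights = NULL)
  log <- vector("list", config$max_epochs)

  with_seed(derive_seed(config$seed, 23), {
    for (epoch in seq_len(config$max_epochs)) {
      epoch_loss <- 0
      for (b in seq_len(n_batches)) {
        idx <- sample.int(N, config$batch_size, replace = TRUE, prob = w)
        Xb <- tr$X[idx, , drop = FALSE]
        yb <- tr$y[idx]
        acts <- mlp_forward_full(weights, Xb)
        p <- drop(acts[[n_layers + 1L]])
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
        if (!is.finite(loss)) {
          abort(sprintf(
            "Non-finite training loss at epoch %d, batch %d (lr = %g); aborting.",
            epoch, b, config$learning_rate))
        }
        epoch_loss <- epoch_loss + loss
        step <- step + 1L
        # Backprop: logistic output + binary cross-entropy.
        delta <- matrix((p - yb) / config$batch_size, ncol = 1L)
        for (l in rev(seq_len(n_layers))) {
          A_prev <- acts[[l]]
          gW <- crossprod(A_prev, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(weights[[l]]$W)) * (acts[[l]] > 0)
          }
          sW <- adam_step(weights[[l]]$W, gW, adam[[l]]$W,
                          config$learning_rate, config$weight_decay, step)
          sb <- adam_step(weights[[l]]$b, gb, adam[[l]]$b,
                          config$learning_rate, config$weight_decay, step)
          weights[[l]]$W <- sW$theta; adam[[l]]$W <- sW$state
          weights[[l]]$b <- sb$theta; adam[[l]]$b <- sb$state
        }
      }
      val_p <- drop(mlp_forward_full(weights, va$X)[[n_layers + 1L]])
      val_mcc <- mcc(confusion(va$y, as.integer(val_p >= config$cutoff)))
      if (val_mcc > best$mcc) {
        best <- list(mcc = val_mcc, epoch = epoch, weights = weights)
      }
      log[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss / n_batches,
                             val_mcc = val_mcc)
    }
  })

  meta <- list(threshold = threshold, seed = config$seed,
               selected_epoch = best$epoch, val_mcc = best$mcc,
               init = model$meta$init)
  structure(list(
    model = new_thermo_mlp(best$weights, spec, meta),
    log = bind_rows(log),
    config = config
  ), class = "thermo_fit")
}

#' @export
predict.thermo_fit <- function(object, x, ...) predict(object$model, x, ...)

#' @export
print.thermo_fit <- function(x, ...) {
  print(x$model)
  invisible(x)
}

#' @rdname train_classifier
#' @param x A `thermo_fit`.
#' @param ... Unused.
#' @method tidy thermo_fit
#' @export
tidy.thermo_fit <- function(x, ...) x$log

#' @rdname train_classifier
#' @method glance thermo_fit
#' @export
glance.thermo_fit <- function(x, ...) {
  tibble(
    threshold = x$model$meta$threshold,
    seed = x$model$meta$seed,
    selected_epoch = x$model$meta$selected_epoch,
    val_mcc = x$model$meta$val_mcc,
    epochs = nrow(x$log),
    final_loss = x$log$loss[nrow(x$log)]
  )
}

new_thermo_ensemble <- function(threshold, members, member_seeds) {
  if (length(members) == 0L) abort("Ensemble must have at least one member.")
  structure(list(threshold = threshold, members = members,
                 member_seeds = as.integer(member_seeds)),
            class = "thermo_ensemble")
}

#' Train a five-member threshold ensemble
#'
#' Members share the architecture, data and threshold and differ only by
#' training seed; at inference their predicted probabilities are averaged.
#'
#' @inheritParams train_classifier
#' @param n_members Number of members (5 in the reference configuration).
#' @param seed Base seed from which the member seeds are derived.
#' @param ... Further arguments passed to [train_config()] (e.g.
#'   `max_epochs`).
#' @return A `thermo_ensemble`: members (selected models), member seeds and
#'   training logs.
#' @export
train_ensemble <- function(train, val, threshold, n_members = 5L,
                           spec = NULL, seed = 1L, ...) {
  member_seeds <- with_seed(derive_seed(seed, round(threshold * 10)),
                            sample.int(1e8, n_members))
  fits <- lapply(member_seeds, function(s) {
    train_classifier(train, val, threshold, spec = spec,
                     config = train_config(seed = s, ...))
  })
  ens <- new_thermo_ensemble(threshold, lapply(fits, `[[`, "model"),
                             member_seeds)
  ens$logs <- lapply(fits, `[[`, "log")
  ens
}

#' Averaged ensemble prediction
#'
#' @param ensemble A `thermo_ensemble`.
#' @param x Input vector / matrix / tibble (see [predict.thermo_mlp()]).
#' @return Arithmetic mean of the member probabilities, one per input row.
#' @export
ensemble_predict <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "thermo_ensemble"))
  preds <- vapply(ensemble$members, function(m) predict(m, x),
                  numeric(nrow(as_input_matrix(x, ensemble$members[[1L]]$spec$input_dim))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  unname(rowMeans(preds))
}

#' @export
predict.thermo_ensemble <- function(object, x, ...) ensemble_predict(object, x)

#' @export
print.thermo_ensemble <- function(x, ...) {
  cat(sprintf("<thermo_ensemble> threshold %s C, %d member(s)\n",
              format(x$threshold), length(x$members)))
  invisible(x)
}

#' @rdname train_ensemble
#' @method tidy thermo_ensemble
#' @export
tidy.thermo_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]$meta
    tibble(threshold = x$threshold, member = i, seed = m$seed,
           selected_epoch = m$selected_epoch, val_mcc = m$val_mcc)
  })
}

#' Train ensembles for every threshold
#'
#' Convenience driver over a split dataset: for each threshold, trains an
#' `n_members`-strong ensemble on the train subset with per-epoch selection
#' on the validation subset.
#'
#' @param data Split tibble with `subset`, `embedding` and label (or
#'   `growth_temperature`) columns, as from [cluster_disjoint_split()].
#' @param thresholds Ascending thresholds (default the 40-65 grid).
#' @inheritParams train_ensemble
#' @return Named list of `thermo_ensemble`s (`T40`, `T45`, ...), ascending.
#' @export
train_ensembles <- function(data, thresholds = threshold_grid(),
                            n_members = 5L, spec = NULL, seed = 1L, ...) {
  check_ascending(thresholds)
  stopifnot("subset" %in% names(data))
  train <- data[data$subset == "train", ]
  val <- data[data$subset == "validation", ]
  ens <- lapply(thresholds, function(t) {
    train_ensemble(train, val, t, n_members = n_members, spec = spec,
                   seed = seed, ...)
  })
  names(ens) <- paste0("T", format(thresholds, trim = TRUE))
  ens
}
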