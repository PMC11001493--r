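#' Classifier architecture specification
#'
#' The reference architecture is a multilayer perceptron with two fully
#' connected hidden layers of sizes 256 and 128, rectified-linear hidden
#' activations and a logistic (sigmoid) output unit producing the
#' probability that a protein is stable at the classifier's temperature
#' threshold and above.
#'
#' @param input_dim Embedding dimension fed to the first layer (1024 for
#'   ProtT5-class mean embeddings; dataset-level parameter).
#' @param hidden Integer vector of hidden-layer sizes (default `c(256, 128)`).
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim = 1024L, hidden = c(256L, 128L)) {
  stopifnot(input_dim >= 1, length(hidden) >= 1, all(hidden >= 1))
  structure(list(
    input_dim = as.integer(input_dim),
    hidden = as.integer(hidden),
    output = 1L,
    activation = "relu",
    output_activation = "sigmoid"
  ), class = "mlp_spec")
}

new_thermo_mlp <- function(weights, spec, meta = list()) {
  structure(list(weights = weights, spec = spec, meta = meta),
            class = "thermo_mlp")
}

#' Initialize a multilayer perceptron
#'
#' Weights and biases of each linear layer are drawn from the seeded uniform
#' fan-in scheme U(-1/sqrt(fan_in), 1/sqrt(fan_in)); the scheme is recorded
#' in the model metadata for reproducibility.
#'
#' @param spec An [mlp_spec()].
#' @param seed Integer seed.
#' @return A `thermo_mlp` model.
#' @export
init_mlp <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mlp_spec"))
  dims <- layer_dims(spec$input_dim, spec$hidden)
  weights <- with_seed(seed, {
    lapply(seq_len(nrow(dims)), function(l) {
      fan_in <- dims[l, 1L]
      bound <- 1 / sqrt(fan_in)
      list(
        W = matrix(runif(fan_in * dims[l, 2L], -bound, bound),
                   nrow = fan_in),
        b = runif(dims[l, 2L], -bound, bound)
      )
    })
  })
  new_thermo_mlp(weights, spec,
                 meta = list(seed = as.integer(seed),
                             init = "uniform fan-in U(-1/sqrt(fan_in), 1/sqrt(fan_in))"))
}

# Forward pass returning all layer activations (for backprop).
mlp_forward_full <- function(weights, X) {
  n_layers <- length(weights)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(n_layers)) {
    Z <- H %*% weights[[l]]$W
    Z <- sweep(Z, 2L, weights[[l]]$b, "+")
    H <- if (l < n_layers) pmax(Z, 0) else plogis_mat(Z)
    acts[[l + 1L]] <- H
  }
  acts
}

plogis_mat <- function(z) 1 / (1 + exp(-z))

#' Forward pass: predicted stability probability
#'
#' @param object A `thermo_mlp` model.
#' @param x A length-D vector, an N x D matrix of row-vector inputs, or a
#'   tibble with an `embedding` list-column.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), one per input row;
#'   deterministic given the weights.
#' @export
predict.thermo_mlp <- function(object, x, ...) {
  X <- as_input_matrix(x, object$spec$input_dim)
  acts <- mlp_forward_full(object$weights, X)
  p <- drop(acts[[length(acts)]])
  unname(p)
}

#' @export
print.thermo_mlp <- function(x, ...) {
  cat(sprintf("<thermo_mlp> %d-%s-1 (relu/sigmoid)%s\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = "-"),
              if (!is.null(x$meta$threshold))
                sprintf(", threshold %s C", format(x$meta$threshold)) else ""))
  if (!is.null(x$meta$selected_epoch)) {
    cat(sprintf("  selected epoch %d, validation MCC %.4f\n",
                x$meta$selected_epoch, x$meta$val_mcc))
  }
  invisible(x)
}

# One Adam step with L2 weight decay folded into the gradient (the
# coupled-decay convention of classic Adam, not decoupled AdamW).
adam_step <- function(theta, grad, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- grad + wd * theta
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}
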