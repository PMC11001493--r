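# Small in-code fixtures shared across test files.

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A small labelled dataset with embedding list-column, via the simulator.
small_labeled <- function(n = 300, D = 32, beta = 3, sigma = 1, seed = 1,
                          thresholds = c(50)) {
  sim <- simulate_dataset(n_organisms = n, D = D, beta = beta, sigma = sigma,
                          seed = seed, length_range = c(30, 60))
  add_threshold_labels(sim$data, thresholds)
}

# Rig an ensemble whose members always output fixed probabilities: a
# one-member "constant" network built by zeroing weights and setting the
# output bias to the logit of the target probability.
rigged_ensemble <- function(threshold, p, input_dim = 4) {
  spec <- mlp_spec(input_dim = input_dim, hidden = c(2, 2))
  model <- init_mlp(spec, seed = 1)
  for (l in seq_along(model$weights)) {
    model$weights[[l]]$W[] <- 0
    model$weights[[l]]$b[] <- 0
  }
  model$weights[[length(model$weights)]]$b[] <- log(p / (1 - p))
  model$meta$threshold <- threshold
  thermopred:::new_thermo_ensemble(threshold, list(model), 1L)
}

rigged_ensemble_set <- function(probs, thresholds = threshold_grid(),
                                input_dim = 4) {
  ens <- purrr::map2(thresholds, probs, rigged_ensemble,
                     input_dim = input_dim)
  names(ens) <- paste0("T", thresholds)
  ens
}
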