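# MLP forward pass, sampler weights, training loop, ensembles.

test_that("forward pass matches closed forms and a hand-computed toy network", {
  spec <- mlp_spec(input_dim = 3, hidden = c(4, 2))
  model <- init_mlp(spec, seed = 1)
  for (l in seq_along(model$weights)) {
    model$weights[[l]]$W[] <- 0
    model$weights[[l]]$b[] <- 0
  }
  expect_equal(predict(model, c(1, 2, 3)), 0.5)  # logistic of 0

  # 2 -> 2 -> 1 network, pencil-and-paper arithmetic:
  # z1 = relu([1,2] %*% [[1,-1],[0.5,2]] + [0.5,-1]) = [2.5, 2]
  # z2 = 2.5*1 + 2*(-2) + 0.5 = -1;  p = 1/(1+e) = 0.2689414
  toy <- init_mlp(mlp_spec(input_dim = 2, hidden = 2), seed = 1)
  toy$weights[[1]]$W <- rbind(c(1, -1), c(0.5, 2))
  toy$weights[[1]]$b <- c(0.5, -1)
  toy$weights[[2]]$W <- rbind(1, -2)
  toy$weights[[2]]$b <- 0.5
  expect_equal(predict(toy, c(1, 2)), 1 / (1 + exp(1)), tolerance = 1e-12)

  # output is monotone in the final-layer logit
  probs <- vapply(c(0.5, 2, 5, 20), function(s) {
    t2 <- toy
    t2$weights[[2]]$W <- t2$weights[[2]]$W * s
    t2$weights[[2]]$b <- t2$weights[[2]]$b * s
    predict(t2, c(1, 2))
  }, numeric(1))
  expect_true(all(diff(probs) < 0))  # logit is negative, scaling drives p -> 0

  expect_error(predict(toy, c(1, 2, 3)), "dimension mismatch")
})

test_that("sampler weights are reciprocal class counts and balance sampling", {
  labels <- c(rep(0, 900), rep(1, 100))
  w <- sampler_weights(labels)
  expect_equal(unique(w[labels == 1]) / unique(w[labels == 0]), 9)
  expect_equal(length(unique(sampler_weights(rep(c(0, 1), 50)))), 1L)
  expect_error(sampler_weights(rep(1, 10)), "Both classes")

  set.seed(77)
  draw <- sample(labels, 10000, replace = TRUE, prob = w)
  expect_lt(abs(mean(draw) - 0.5), 0.02)
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- small_labeled(n = 150, D = 8, seed = 2)
  cfg <- train_config(seed = 21, max_epochs = 4)
  f1 <- train_classifier(d[1:100, ], d[101:150, ], 50, config = cfg)
  f2 <- train_classifier(d[1:100, ], d[101:150, ], 50, config = cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$model$meta$selected_epoch, f2$model$meta$selected_epoch)
  expect_identical(f1$log, f2$log)
})

test_that("training rejects single-class inputs and unseeded configs", {
  d <- small_labeled(n = 100, D = 8, seed = 2)
  hot <- d[d$label_50 == 1, ]
  expect_error(train_classifier(hot, d, 50,
                                config = train_config(seed = 1, max_epochs = 2)),
               "Single-class train")
  expect_error(train_classifier(d, hot, 50,
                                config = train_config(seed = 1, max_epochs = 2)),
               "Single-class validation")
  expect_error(train_config(), "seed")
})

test_that("strong signal is learned to high validation MCC; selection is a maximum", {
  sim <- simulate_dataset(n_organisms = 2500, D = 32, beta = 3, sigma = 1,
                          seed = 6, length_range = c(30, 60))
  d <- add_threshold_labels(sim$data, 50)
  fit <- train_classifier(d[1:2000, ], d[2001:2500, ], 50,
                          config = train_config(seed = 13))
  expect_gte(fit$model$meta$val_mcc, 0.95)
  expect_gte(fit$model$meta$val_mcc, fit$log$val_mcc[1])
  expect_equal(fit$model$meta$val_mcc, max(fit$log$val_mcc))
  expect_true(all(is.finite(fit$log$loss)))

  # monotone response: mean predicted probability non-decreasing in OGT
  p <- predict(fit, d)
  bins <- cut(d$growth_temperature, breaks = seq(0, 100, by = 10))
  mp <- tapply(p, bins, mean)
  expect_gte(stats::cor(seq_along(mp), mp, method = "spearman"), 0.95)

  # tidy/glance accessors expose the training log
  expect_equal(nrow(tidy(fit)), 30L)
  expect_equal(glance(fit)$selected_epoch, fit$model$meta$selected_epoch)
})

test_that("zero-signal data trains to chance-level validation MCC", {
  sim <- simulate_dataset(n_organisms = 600, D = 16, beta = 0, sigma = 1,
                          seed = 14, length_range = c(30, 60))
  d <- add_threshold_labels(sim$data, 50)
  fit <- train_classifier(d[1:400, ], d[401:600, ], 50,
                          config = train_config(seed = 3, max_epochs = 10))
  expect_lt(abs(fit$model$meta$val_mcc), 0.15)
})

test_that("held-out recovery holds across seeds on strongly separable data", {
  sim <- simulate_dataset(n_organisms = 1400, D = 32, beta = 3, sigma = 1,
                          seed = 15, length_range = c(30, 60))
  d <- add_threshold_labels(sim$data, 50)
  test <- d[1201:1400, ]
  mccs <- vapply(1:5, function(s) {
    fit <- train_classifier(d[1:1000, ], d[1001:1200, ], 50,
                            config = train_config(seed = s, max_epochs = 12))
    mcc(confusion(test$label_50, binarize(predict(fit, test))))
  }, numeric(1))
  expect_gte(mean(mccs), 0.9)
})

test_that("ensemble prediction is the member mean and is order-invariant", {
  members <- lapply(c(0.2, 0.4, 0.6, 0.8, 1 - 1e-9), function(p) {
    rigged_ensemble(50, p)$members[[1]]
  })
  ens <- thermopred:::new_thermo_ensemble(50, members, 1:5)
  x <- rnorm(4)
  expect_equal(ensemble_predict(ens, x), 0.6, tolerance = 1e-9)

  shuf <- thermopred:::new_thermo_ensemble(50, members[c(3, 1, 5, 2, 4)], 1:5)
  expect_equal(ensemble_predict(shuf, x), ensemble_predict(ens, x))

  one <- thermopred:::new_thermo_ensemble(50, members[2], 1L)
  expect_equal(ensemble_predict(one, x), predict(members[[2]], x))
  expect_error(thermopred:::new_thermo_ensemble(50, list(), integer(0)),
               "at least one")
})

test_that("train_ensemble produces distinct members that average sensibly", {
  d <- small_labeled(n = 200, D = 8, seed = 4)
  d$subset <- rep(c("train", "validation"), c(140, 60))
  ens <- train_ensembles(d, thresholds = 50, n_members = 2, seed = 9,
                         max_epochs = 3)[[1]]
  expect_length(ens$members, 2L)
  expect_false(identical(ens$members[[1]]$weights, ens$members[[2]]$weights))
  x <- d$embedding[[1]]
  expect_equal(ensemble_predict(ens, x),
               mean(c(predict(ens$members[[1]], x),
                      predict(ens$members[[2]], x))))
  expect_equal(nrow(tidy(ens)), 2L)
})
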