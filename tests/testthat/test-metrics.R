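# Metric panel against brute-force oracles; PCA QC.

test_that("confusion counts match the counting-loop oracle", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm$tp, 2L); expect_equal(cm$tn, 1L)
  expect_equal(cm$fp, 0L); expect_equal(cm$fn, 0L)

  cm0 <- confusion(c(1, 1, 0), c(0, 0, 0))
  expect_equal(cm0$tp, 0L); expect_equal(cm0$fp, 0L)

  set.seed(55)
  labels <- rbinom(1000, 1, 0.3)
  calls <- rbinom(1000, 1, 0.5)
  expect_equal(unclass(confusion(labels, calls)),
               oracle_confusion(labels, calls))
  expect_error(confusion(c(1, 0), 1), "equal length")
})

test_that("MCC matches the direct formula, with the zero-margin convention", {
  expect_equal(mcc(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1.0)
  expect_equal(mcc(list(tp = 10, fn = 0, tn = 0, fp = 5)), 0)  # one-class calls
  expect_equal(mcc(list(tp = 45, fn = 5, tn = 40, fp = 10)),
               0.7035, tolerance = 1e-4)
  expect_equal(mcc(list(tp = 45, fn = 5, tn = 40, fp = 10)),
               oracle_mcc(45, 10, 40, 5), tolerance = 1e-12)

  # invariance under simultaneous label/call flip
  set.seed(66)
  for (i in 1:20) {
    labels <- rbinom(200, 1, 0.4); calls <- rbinom(200, 1, 0.5)
    expect_equal(mcc(confusion(labels, calls)),
                 mcc(confusion(1 - labels, 1 - calls)), tolerance = 1e-12)
  }
})

test_that("ROC AUC is the rank statistic with ties at one half", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.3, 0.4, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  # complement identity for tie-free scores
  set.seed(77)
  labels <- rbinom(100, 1, 0.5)
  scores <- runif(100)
  expect_equal(roc_auc(labels, scores) + roc_auc(labels, -scores), 1,
               tolerance = 1e-12)
})

test_that("PR AUC: perfect ranking, prevalence limit, grid-oracle agreement", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "positive")

  # random scores: PR AUC approaches the prevalence
  set.seed(88)
  labels <- rbinom(10000, 1, 0.3)
  scores <- runif(10000)
  expect_lt(abs(pr_auc(labels, scores) - 0.3), 0.05)
})

test_that("full metric panel matches independent oracles on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(20:1000, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # some tie-heavy
    panel <- metric_panel(labels, scores)
    oc <- oracle_confusion(labels, as.integer(scores >= 0.5))
    expect_equal(panel$tp, oc$tp); expect_equal(panel$fn, oc$fn)
    expect_equal(panel$mcc, oracle_mcc(oc$tp, oc$fp, oc$tn, oc$fn),
                 tolerance = 1e-10)
    expect_equal(panel$accuracy, (oc$tp + oc$tn) / n, tolerance = 1e-10)
    prec <- if (oc$tp + oc$fp == 0) 0 else oc$tp / (oc$tp + oc$fp)
    rec <- if (oc$tp + oc$fn == 0) 0 else oc$tp / (oc$tp + oc$fn)
    expect_equal(panel$precision, prec, tolerance = 1e-10)
    expect_equal(panel$recall, rec, tolerance = 1e-10)
    expect_equal(panel$specificity, oc$tn / (oc$tn + oc$fp), tolerance = 1e-10)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(panel$f1, f1, tolerance = 1e-10)
    expect_equal(panel$roc_auc, oracle_roc_auc(labels, scores),
                 tolerance = 1e-10)
    expect_equal(panel$pr_auc, oracle_pr_auc(labels, scores),
                 tolerance = 1e-10)
  }
})

test_that("ROC AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(101)
  for (i in 1:10) {
    labels <- rbinom(300, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(300), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-10)
  }
})

test_that("two-component PCA captures collinear and isotropic structure", {
  set.seed(111)
  # points on one line in 10-D
  t <- rnorm(50)
  dir <- rnorm(10)
  line <- outer(t, dir) + 1e-8 * matrix(rnorm(500), 50)
  p <- pca2(line)
  expect_gt(p$explained[1], 0.999)

  # isotropic cloud: each of the top-2 fractions near 2/D overall
  D <- 20
  cloud <- matrix(rnorm(3000 * D), ncol = D)
  p2 <- pca2(cloud)
  expect_lt(abs(sum(p2$explained) - 2 / D), 0.02)
  expect_gte(p2$explained[1], p2$explained[2])

  expect_error(pca2(matrix(1, 5, 3)), "rank-0|constant")
  expect_error(pca2(matrix(rnorm(4), 2, 2)), "at least 3")
})

test_that("evaluate_ensembles reproduces the metric panel per threshold", {
  d <- small_labeled(n = 200, D = 4, seed = 12,
                     thresholds = threshold_grid())
  ens <- rigged_ensemble_set(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  rep <- evaluate_ensembles(ens, d)
  expect_equal(rep$threshold, threshold_grid())
  # rigged constant probabilities: calls are all-1 or all-0 per threshold
  expect_equal(rep$mcc, rep(0, 6))
  one <- metric_panel(d$label_40, rep(0.9, 200))
  expect_equal(rep$accuracy[1], one$accuracy)
})
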