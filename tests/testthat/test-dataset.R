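# Labelling, cluster-disjoint splitting, balancing, greedy clustering.

test_that("threshold labels follow the OGT >= T rule and are monotone", {
  grid <- threshold_grid()
  expect_equal(unname(assign_threshold_labels(65, grid)), rep(1L, 6))
  expect_equal(unname(assign_threshold_labels(52, grid)),
               c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(unname(assign_threshold_labels(39.999, grid)), rep(0L, 6))
  expect_equal(unname(assign_threshold_labels(40, grid))[1], 1L)  # boundary
  expect_error(assign_threshold_labels(NaN, grid), "finite")

  # monotonicity property over random OGTs
  set.seed(42)
  for (t in runif(200, -10, 120)) {
    lab <- assign_threshold_labels(t, grid)
    expect_true(all(diff(lab) <= 0))
  }
})

test_that("add_threshold_labels matches the scalar rule column-wise", {
  d <- tibble::tibble(sequence_id = letters[1:4],
                      growth_temperature = c(10, 47.5, 62, 99))
  d2 <- add_threshold_labels(d, threshold_grid())
  for (i in seq_len(nrow(d))) {
    expect_equal(
      unlist(d2[i, paste0("label_", threshold_grid())], use.names = FALSE),
      unname(assign_threshold_labels(d$growth_temperature[i], threshold_grid())))
  }
})

test_that("cluster-disjoint split keeps clusters atomic and conserves examples", {
  # 10 singleton clusters at (0.8, 0.1, 0.1)
  d <- tibble::tibble(sequence_id = paste0("s", 1:10))
  cl <- tibble::tibble(id = d$sequence_id, cluster = 0:9,
                       representative = TRUE)
  sp <- cluster_disjoint_split(d, cl, fractions = c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(as.vector(table(sp$subset)), c(8, 1, 1))
  expect_setequal(sp$sequence_id, d$sequence_id)

  # one giant cluster: everything lands in one subset, with a warning
  cl1 <- tibble::tibble(id = d$sequence_id, cluster = 0L,
                        representative = c(TRUE, rep(FALSE, 9)))
  expect_warning(sp1 <- cluster_disjoint_split(d, cl1, seed = 1),
                 "atomically")
  expect_equal(length(unique(sp1$subset)), 1L)
})

test_that("split is deterministic and errors on ids missing from clusters", {
  d <- tibble::tibble(sequence_id = paste0("s", 1:30))
  cl <- tibble::tibble(id = d$sequence_id, cluster = rep(0:9, 3),
                       representative = rep(c(TRUE, FALSE, FALSE), each = 10))
  a <- cluster_disjoint_split(d, cl, seed = 11)
  b <- cluster_disjoint_split(d, cl, seed = 11)
  expect_identical(a$subset, b$subset)
  expect_error(
    cluster_disjoint_split(tibble::tibble(sequence_id = "ghost"), cl, seed = 1),
    "ghost")
  expect_error(cluster_disjoint_split(d, cl, fractions = c(0.5, 0.3, 0.3)),
               "summing|sum")
})

test_that("subset cluster-id sets are pairwise disjoint over random instances", {
  set.seed(202)
  for (rep in 1:100) {
    n_cl <- sample(5:25, 1)
    sizes <- sample(1:8, n_cl, replace = TRUE)
    cl <- tibble::tibble(
      id = paste0("r", rep, "_", seq_len(sum(sizes))),
      cluster = rep(seq_len(n_cl) - 1L, sizes),
      representative = unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1)))))
    d <- tibble::tibble(sequence_id = cl$id)
    sp <- suppressWarnings(cluster_disjoint_split(d, cl, seed = rep))
    by_subset <- split(sp$cluster, sp$subset, drop = TRUE)
    pairs <- utils::combn(length(by_subset), 2)
    for (j in seq_len(ncol(pairs))) {
      expect_length(intersect(by_subset[[pairs[1, j]]],
                              by_subset[[pairs[2, j]]]), 0)
    }
    expect_setequal(unlist(by_subset), unique(cl$cluster))
    expect_equal(nrow(sp), nrow(d))
  }
})

test_that("realized fractions approach targets with many singleton clusters", {
  d <- tibble::tibble(sequence_id = paste0("s", 1:1000))
  cl <- tibble::tibble(id = d$sequence_id, cluster = 0:999,
                       representative = TRUE)
  sp <- cluster_disjoint_split(d, cl, seed = 3)
  realized <- as.vector(table(sp$subset)) / 1000
  expect_true(all(abs(realized - c(0.70, 0.15, 0.15)) <= 0.02))
})

test_that("balanced subsample gives exact parity, determinism, and clear errors", {
  d <- small_labeled(n = 400, D = 4, seed = 9)
  sub <- balanced_subsample(d, 50, 200, seed = 5)
  expect_equal(sum(sub$label_50 == 1), 100)
  expect_equal(sum(sub$label_50 == 0), 100)
  sub2 <- balanced_subsample(d, 50, 200, seed = 5)
  expect_identical(sort(sub$sequence_id), sort(sub2$sequence_id))

  skew <- d[c(which(d$label_50 == 0)[1:100], which(d$label_50 == 1)[1:3]), ]
  expect_error(balanced_subsample(skew, 50, 10, seed = 1), "class 1 = 3")
  expect_error(balanced_subsample(d, 50, 7, seed = 1), "even")
})

test_that("greedy clustering groups identical sequences and splits disjoint ones", {
  same <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep(strrep("ACDEFGHIKL", 4), 3))
  cl <- greedy_cluster(same)
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(sum(cl$representative), 1L)

  disjoint <- tibble::tibble(
    id = c("x", "y"),
    sequence = c(strrep("AC", 20), strrep("MK", 20)))
  cl2 <- greedy_cluster(disjoint)
  expect_equal(length(unique(cl2$cluster)), 2L)
  expect_error(greedy_cluster(same[0, ]), "empty")
})

test_that("greedy clustering co-clusters exact copies, agreeing with a k-mer oracle", {
  set.seed(31)
  base <- replicate(20, paste(sample(c("A","C","D","E","F","G","H","I","K","L"),
                                     60, TRUE), collapse = ""))
  seqs <- tibble::tibble(
    id = c(paste0("orig", 1:20), paste0("copy", 1:5)),
    sequence = c(base, base[1:5]))
  cl <- greedy_cluster(seqs, identity_threshold = 0.3)
  for (i in 1:5) {
    expect_equal(cl$cluster[cl$id == paste0("copy", i)],
                 cl$cluster[cl$id == paste0("orig", i)])
    expect_equal(oracle_kmer_identity(base[i], base[i]), 1)
  }
  # oracle agreement on the pairwise identity driving the decisions
  expect_equal(thermopred:::kmer_identity(thermopred:::kmer_set(base[1]),
                                          thermopred:::kmer_set(base[2])),
               oracle_kmer_identity(base[1], base[2]))
})
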