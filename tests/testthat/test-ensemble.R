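# Splitting, base-classifier training, weighting and weighted voting.

test_that("outer split respects the 3:1 ratio and stratification", {
  td <- tiny_dataset(seed = 21L, n_per_class = c(42L, 38L), regions = 6L,
                     timepoints = 30L)
  ds <- td$dataset
  parts <- split_outer(ds, split_spec(), seed = 5L)
  expect_length(parts$test, 20)      # round(42/4) + round(38/4)
  expect_length(parts$trainval, 60)
  expect_setequal(c(parts$trainval, parts$test), seq_len(80))
  expect_length(intersect(parts$trainval, parts$test), 0)
  for (p in parts) expect_setequal(unique(ds$labels[p]), c(-1L, 1L))
})

test_that("outer split partitions exhaustively across many seeds", {
  td <- tiny_dataset(seed = 3L, n_per_class = c(10L, 9L), regions = 5L,
                     timepoints = 20L)
  for (s in 1:100) {
    parts <- split_outer(td$dataset, split_spec(), seed = s)
    expect_setequal(c(parts$trainval, parts$test), seq_len(19))
    expect_length(intersect(parts$trainval, parts$test), 0)
  }
})

test_that("boundary split with 2 subjects per class keeps parts non-empty", {
  td <- tiny_dataset(seed = 4L, n_per_class = c(2L, 2L), regions = 5L,
                     timepoints = 20L)
  parts <- split_outer(td$dataset, split_spec(), seed = 1L)
  expect_length(parts$test, 2)
  expect_length(parts$trainval, 2)
  for (p in parts) expect_setequal(unique(td$dataset$labels[p]), c(-1L, 1L))
})

test_that("classifier draws give distinct in-pool features and valid splits", {
  td <- tiny_dataset(seed = 10L)
  ds <- td$dataset
  pool <- seq_len(ncol(ds$features))
  draw <- draw_classifier_data(seq_len(24), ds$labels, pool, m = 6L,
                               seed = 11L)
  expect_length(draw$features, 6)
  expect_length(unique(draw$features), 6)
  expect_true(all(draw$features %in% pool))
  expect_length(intersect(draw$train, draw$validation), 0)
  expect_setequal(c(draw$train, draw$validation), seq_len(24))
  # m = |pool| returns the whole pool
  full <- draw_classifier_data(seq_len(24), ds$labels, pool,
                               m = length(pool), seed = 2L)
  expect_setequal(full$features, pool)
  expect_error(
    draw_classifier_data(seq_len(24), ds$labels, pool, m = 29L, seed = 1L),
    class = "ewrsvmc_pool_exhausted")
})

test_that("uniform feature sampling covers a small pool over many draws", {
  td <- tiny_dataset(seed = 2L)
  ds <- td$dataset
  seen <- integer(0)
  for (s in 1:200) {
    draw <- draw_classifier_data(seq_len(24), ds$labels, 1:10, m = 3L,
                                 seed = s)
    seen <- union(seen, draw$features)
  }
  expect_setequal(seen, 1:10)  # P(miss) < 1e-6 under uniformity
})

test_that("member weight equals validation accuracy and is recomputable", {
  td <- tiny_dataset(seed = 12L)
  ds <- td$dataset
  draw <- draw_classifier_data(seq_len(24), ds$labels,
                               seq_len(ncol(ds$features)), m = 5L, seed = 3L)
  mb <- train_base_classifier(ds, draw$train, draw$validation, draw$features)
  expect_true(mb$weight >= 0 && mb$weight <= 1)
  pred <- sapply(draw$validation, function(i)
    ifelse(ewrsvmc:::decision_values(
      mb, ds$features[i, mb$features, drop = FALSE]) > 0,
      mb$positive_decision_label, -mb$positive_decision_label))
  expect_equal(mb$weight, mean(pred == ds$labels[draw$validation]))
})

test_that("separable blobs give training accuracy 1 under a hard margin", {
  # two well-separated Gaussian blobs in feature space
  set.seed(6)
  X <- rbind(matrix(rnorm(40, -0.5, 0.05), 20, 2),
             matrix(rnorm(40, 0.5, 0.05), 20, 2))
  X <- cbind(X, matrix(rnorm(80, 0, 0.1), 40, 2))  # pad to d = 4
  ds <- structure(list(features = X, labels = rep(c(-1L, 1L), each = 20),
                       subject_ids = sprintf("s%02d", 1:40),
                       pair_map = pair_index_map(4)), class = "fc_dataset")
  mb <- train_base_classifier(ds, train = c(1:15, 21:35),
                              validation = c(16:20, 36:40), features = 1:2)
  pred <- sapply(c(1:15, 21:35), function(i)
    ifelse(ewrsvmc:::decision_values(
      mb, X[i, 1:2, drop = FALSE]) > 0,
      mb$positive_decision_label, -mb$positive_decision_label))
  expect_equal(mean(pred == ds$labels[c(1:15, 21:35)]), 1)
  expect_equal(mb$weight, 1)
})

test_that("single-class training part raises a degenerate-training error", {
  td <- tiny_dataset(seed = 13L)
  ds <- td$dataset
  pos <- which(ds$labels == 1L)
  expect_error(
    train_base_classifier(ds, train = pos[1:6], validation = pos[7:9],
                          features = 1:4),
    class = "ewrsvmc_degenerate_training")
})

test_that("build_ensemble produces n reproducible members from the pool", {
  td <- tiny_dataset(seed = 14L)
  ds <- td$dataset
  pool <- seq_len(ncol(ds$features))
  e1 <- build_ensemble(ds, seq_len(24), pool, n = 15L, m = 5L, seed = 99L)
  expect_length(e1$members, 15)
  for (mb in e1$members) {
    expect_true(all(mb$features %in% pool))
    expect_length(intersect(mb$train, mb$validation), 0)
    w <- mb$weight
    expect_true(w >= 0 && w <= 1)
  }
  e2 <- build_ensemble(ds, seq_len(24), pool, n = 15L, m = 5L, seed = 99L)
  expect_identical(lapply(e1$members, `[[`, "features"),
                   lapply(e2$members, `[[`, "features"))
  expect_identical(ensemble_weights(e1), ensemble_weights(e2))
  expect_identical(predict_batch(e1, ds$features),
                   predict_batch(e2, ds$features))
  # n = 1 degenerates to a single weighted SVM
  e_single <- build_ensemble(ds, seq_len(24), pool, n = 1L, m = 5L, seed = 7L)
  expect_length(e_single$members, 1)
})

test_that("weighted vote matches brute-force per-label weight summation", {
  # deterministic textbook case: 0.9 + 0.9 for +1 beats 0.7 for -1
  ens <- fixed_vote_ensemble(votes = c(1L, 1L, -1L),
                             weights = c(0.9, 0.9, 0.7))
  expect_identical(predict_sample(ens, rep(0, 4)), 1L)
  vw <- vote_weights(ens, matrix(0, 1, 4))
  expect_equal(unname(vw[1, ]), c(1.8, 0.7))

  # 50 random small ensembles vs the brute-force oracle
  for (s in 1:50) {
    set.seed(s)
    nm <- sample(2:9, 1)
    weights <- round(runif(nm), 2)
    ens <- random_pattern_ensemble(nm, weights, seed = s + 1000)
    X <- matrix(runif(10 * 4, -3, 3), 10, 4)
    got <- predict_batch(ens, X)
    votes <- sapply(seq_len(nrow(X)), function(i)
      sapply(ens$members, function(mb)
        ewrsvmc:::member_predict(mb, X[i, , drop = FALSE])))
    want <- apply(votes, 2, brute_vote, weights = weights)
    expect_identical(got, as.integer(want))
  }
})

test_that("vote ties resolve by top-weight member, then +1", {
  # tie 0.8 vs 0.8: single heaviest member (weight 0.8 appears twice but
  # votes disagree) -> +1
  ens <- fixed_vote_ensemble(votes = c(1L, -1L), weights = c(0.8, 0.8))
  expect_identical(predict_sample(ens, rep(0, 4)), 1L)
  # tie in sums but a unique heaviest member decides
  ens2 <- fixed_vote_ensemble(votes = c(-1L, 1L, 1L),
                              weights = c(0.8, 0.5, 0.3))
  expect_identical(predict_sample(ens2, rep(0, 4)), -1L)
})

test_that("equal weights reduce the vote to unweighted majority", {
  for (s in 1:10) {
    set.seed(s)
    nm <- sample(c(3L, 5L, 7L), 1)  # odd: no ties
    ens <- random_pattern_ensemble(nm, rep(0.6, nm), seed = s + 55)
    X <- matrix(runif(8 * 4, -3, 3), 8, 4)
    votes <- sapply(seq_len(nrow(X)), function(i)
      sapply(ens$members, function(mb)
        ewrsvmc:::member_predict(mb, X[i, , drop = FALSE])))
    majority <- ifelse(colSums(votes == 1L) > nm / 2, 1L, -1L)
    expect_identical(predict_batch(ens, X), as.integer(majority))
  }
})

test_that("prediction is invariant to member order", {
  td <- tiny_dataset(seed = 16L)
  ds <- td$dataset
  ens <- build_ensemble(ds, seq_len(24), seq_len(28), n = 12L, m = 5L,
                        seed = 31L)
  perm <- ens
  set.seed(2)
  perm$members <- perm$members[sample(12)]
  expect_identical(predict_batch(ens, ds$features),
                   predict_batch(perm, ds$features))
})

test_that("predict_batch maps rows like predict_sample and checks dims", {
  td <- tiny_dataset(seed = 17L)
  ds <- td$dataset
  ens <- build_ensemble(ds, seq_len(24), seq_len(28), n = 8L, m = 5L,
                        seed = 13L)
  X <- ds$features[1:5, ]
  batch <- predict_batch(ens, X)
  expect_identical(batch, vapply(1:5, function(i)
    predict_sample(ens, X[i, ]), integer(1)))
  expect_identical(predict_batch(ens, X[0, , drop = FALSE]), integer(0))
  expect_identical(predict_batch(ens, X[1, , drop = FALSE]),
                   predict_sample(ens, X[1, ]))
  expect_error(predict_batch(ens, X[, 1:10]), "dimension mismatch")
})

test_that("member decision values agree with e1071's own predictions", {
  td <- tiny_dataset(seed = 18L)
  ds <- td$dataset
  draw <- draw_classifier_data(seq_len(24), ds$labels, seq_len(28), m = 6L,
                               seed = 3L)
  fit <- e1071::svm(x = ds$features[draw$train, draw$features, drop = FALSE],
                    y = factor(ds$labels[draw$train], levels = c(-1L, 1L)),
                    scale = FALSE, kernel = "radial", gamma = 1 / 18,
                    cost = 1e6)
  mb <- train_base_classifier(ds, draw$train, draw$validation, draw$features)
  ours <- ewrsvmc:::member_predict(mb, ds$features)
  theirs <- as.integer(as.character(
    predict(fit, ds$features[, draw$features, drop = FALSE])))
  expect_identical(ours, theirs)
})
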