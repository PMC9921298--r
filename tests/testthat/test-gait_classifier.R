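test_that("kNN labelling is a deterministic majority vote with index tie-break", {
  expect_equal(knn_label(c(0.3, 0.1, 0.8), c("PRE_NP", "PRE_NP", "POST_P"), 1), "PRE_NP")
  expect_equal(knn_label(c(0.3, 0.1, 0.2), c("PRE_NP", "POST_P", "POST_P"), 3), "POST_P")
  # exact distance tie: lower train index wins
  expect_equal(knn_label(c(0.5, 0.5, 0.9), c("POST_P", "PRE_NP", "PRE_NP"), 1), "POST_P")
  expect_equal(knn_label(c(0.5, 0.5, 0.9), c("PRE_NP", "POST_P", "POST_P"), 1), "PRE_NP")
  expect_error(knn_label(numeric(), character(), 1), "empty")
  expect_error(knn_label(c(1, 2), c("a", "b"), 2), "odd")
  expect_error(knn_label(c(1, 2), c("a", "b"), 5), "<=")
})

test_that("the nearest-centroid-distance rule agrees with kNN on separated classes", {
  expect_equal(centroid_label(c(0.1, 0.2, 0.8, 0.9), rep(c("PRE_NP", "POST_P"), each = 2)),
               "PRE_NP")
  sets <- two_class_sets(n = 30, delta = 6, noise = 0.3, seed = 28)
  res <- cross_validate(sets$pre, sets$post, rule = "nearest-centroid-distance",
                        seed = 17)
  expect_gte(res$accuracy_mean[["PRE_NP"]], 0.99)
  expect_gte(res$accuracy_mean[["POST_P"]], 0.99)
  fr <- classify_condition(sets$post, sets$pre, sets$post,
                           rule = "nearest-centroid-distance")
  expect_gte(fr[["POST_P"]], 0.99)
})

test_that("fold plans are stratified, balanced, and seed-reproducible", {
  plan <- make_folds(100, seed = 17)
  expect_equal(tabulate(plan$assignment, 5), rep(20L, 5))
  plan2 <- make_folds(103, seed = 17)
  expect_true(all(tabulate(plan2$assignment, 5) %in% c(20L, 21L)))
  expect_equal(sum(tabulate(plan2$assignment, 5)), 103L)
  expect_identical(make_folds(100, seed = 3)$assignment,
                   make_folds(100, seed = 3)$assignment)
  expect_false(identical(make_folds(100, seed = 3)$assignment,
                         make_folds(100, seed = 4)$assignment))
  expect_error(make_folds(4), "at least 5")
})

test_that("F1 matches its definition including the degenerate cases", {
  truth <- rep(c("PRE_NP", "POST_P"), each = 10)
  expect_equal(f1_score(truth, truth), 1)
  # all-positive prediction on balanced classes: precision 1/2, recall 1 -> 2/3
  expect_equal(f1_score(truth, rep("POST_P", 20)), 2 / 3)
  # no correct positives
  pred <- ifelse(truth == "POST_P", "PRE_NP", "POST_P")
  expect_equal(f1_score(truth, pred), 0)
  expect_error(f1_score(rep("PRE_NP", 5), rep("PRE_NP", 5)), "recall undefined")
})

test_that("cross-validation separates well-separated classes and not duplicates", {
  sets <- two_class_sets(n = 40, delta = 6, noise = 0.3, seed = 21)
  res <- cross_validate(sets$pre, sets$post, metric = "euclidean", seed = 17)
  expect_gte(res$accuracy_mean[["PRE_NP"]], 0.99)
  expect_gte(res$accuracy_mean[["POST_P"]], 0.99)
  expect_gte(res$f1, 0.99)

  # the same strides duplicated into both classes: warning and chance-level
  dup <- stride_set(sets$pre$values, condition = "POST_P")
  expect_warning(res_dup <- cross_validate(sets$pre, dup, seed = 17),
                 "not distinguishable")
  expect_lt(abs(res_dup$pooled_accuracy - 0.5), 0.2)
})

test_that("class sizes are equalized by truncating the larger class", {
  sets <- two_class_sets(n = 30, delta = 6, seed = 22)
  small_post <- stride_set(sets$post$values[1:17, ], condition = "POST_P")
  res <- cross_validate(sets$pre, small_post, seed = 17)
  expect_equal(res$n_per_class, 17L)
})

test_that("label-swap symmetry is exact", {
  sets <- two_class_sets(n = 25, delta = 1.2, noise = 0.8, seed = 23)
  a <- cross_validate(sets$pre, sets$post, seed = 17)
  swapped_pre <- stride_set(sets$post$values, condition = "PRE_NP")
  swapped_post <- stride_set(sets$pre$values, condition = "POST_P")
  b <- cross_validate(swapped_pre, swapped_post, seed = 17)
  expect_identical(a$accuracy_mean[["PRE_NP"]], b$accuracy_mean[["POST_P"]])
  expect_identical(a$accuracy_mean[["POST_P"]], b$accuracy_mean[["PRE_NP"]])

  tgt <- as_stride_set(sets$pre$values[1:10, ] + 0.3, "MID_P")
  fa <- classify_condition(tgt, sets$pre, sets$post)
  fb <- classify_condition(tgt, swapped_pre, swapped_post)
  expect_identical(fa[["PRE_NP"]], fb[["POST_P"]])
})

test_that("kNN decisions are invariant under monotone distance transforms", {
  sets <- two_class_sets(n = 15, delta = 1, noise = 1, seed = 24)
  train <- rbind(sets$pre$values, sets$post$values)
  labels <- rep(c("PRE_NP", "POST_P"), each = 15)
  dm <- pairwise_distances(sets$pre$values[1:8, ] + 0.5, train,
                           metric = "euclidean", train_labels = labels)
  base <- apply(dm$values, 1, knn_label, train_labels = labels, k = 3)
  for (f in list(sqrt, function(d) 2 * d + 1, function(d) d^2)) {
    expect_identical(apply(f(dm$values), 1, knn_label, train_labels = labels, k = 3),
                     base)
  }
})

test_that("1-NN resubstitution is perfect when strides are distinct", {
  sets <- two_class_sets(n = 12, delta = 0.5, noise = 1, seed = 25)
  train <- rbind(sets$pre$values, sets$post$values)
  labels <- rep(c("PRE_NP", "POST_P"), each = 12)
  dm <- pairwise_distances(train, train, metric = "euclidean", train_labels = labels)
  pred <- apply(dm$values, 1, knn_label, train_labels = labels, k = 1)
  expect_identical(pred, labels)
})

test_that("classified fractions sum to exactly one", {
  sets <- two_class_sets(n = 20, delta = 1, noise = 1, seed = 26)
  tgt <- as_stride_set(sets$pre$values[1:13, ] + 0.7, "MID_P")
  fr <- classify_condition(tgt, sets$pre, sets$post)
  expect_identical(fr[["PRE_NP"]] + fr[["POST_P"]], 1)
  # target identical to the post training set, k = 1: zero self-distance
  tgt_post <- as_stride_set(sets$post$values, "POST_NP")
  fr2 <- classify_condition(tgt_post, sets$pre, sets$post)
  expect_identical(fr2[["POST_P"]], 1)
})

test_that("variance summary reproduces known dispersion ratios", {
  # published mean per-timepoint dispersion pairs and their printed ratios
  expect_equal(round(f_ratio(0.4180, 0.4920), 4), 1.1770)
  expect_equal(round(f_ratio(0.0367, 0.0353), 4), 1.0397)

  sets <- two_class_sets(n = 20, seed = 27)
  vs <- variance_summary(sets$pre, sets$pre)
  expect_identical(vs$f_value, 1)
  vs2 <- variance_summary(sets$pre, sets$post)
  expect_gte(vs2$f_value, 1)
  # swapping the conditions leaves the ratio unchanged
  expect_identical(variance_summary(sets$post, sets$pre)$f_value, vs2$f_value)
  # per-timepoint SD definition (n - 1 denominator), averaged over timepoints
  expect_equal(vs2$mean_sd_pre, mean(apply(sets$pre$values, 2, sd)))
  expect_error(variance_summary(as_stride_set(sets$pre$values[1, , drop = FALSE]),
                                sets$post), "at least 2")
})
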