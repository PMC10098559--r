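test_that("binarization uses a strict threshold", {
  expect_equal(binarize(rep(0.7, 4), 0.5)$bits, rep(1L, 4))
  m <- binarize(rep(0.3, 4), 0.5)
  expect_equal(m$n_selected, 0L)
  expect_equal(binarize(c(0.2, 0.9, 0.5), 0.5)$bits, c(0L, 1L, 0L))
  expect_error(binarize(c(0.2, NA)), "non-finite")
})

test_that("holdout splits are stratified, deterministic, and validated", {
  ft <- make_sep_table(n_per = 10)            # 20 trials, 10 per class
  spec <- cost_spec(split_seed = 99)
  sp <- make_split(ft, spec)
  expect_length(sp$test_indices, 4)
  expect_equal(as.vector(table(ft$labels[sp$test_indices])), c(2L, 2L))
  expect_setequal(c(sp$train_indices, sp$test_indices), 1:20)
  expect_identical(make_split(ft, spec), sp)

  # 60 trials, 4 balanced classes -> 12 test, 3 per class
  ft4 <- nirselect:::with_seed(1, nirselect:::new_feature_table(
    matrix(rnorm(60 * 3), 60, 3), rep(c("w", "x", "y", "z"), each = 15),
    sprintf("C%d", 1:3), rep("mean", 3)))
  sp4 <- make_split(ft4, spec)
  expect_length(sp4$test_indices, 12)
  expect_true(all(table(ft4$labels[sp4$test_indices]) == 3))

  tiny <- nirselect:::new_feature_table(matrix(rnorm(6), 3, 2),
                                        c("a", "a", "b"), c("C1", "C2"),
                                        rep("mean", 2))
  expect_error(make_split(tiny, spec), "at least 2 trials")
})

test_that("k-NN agrees with brute-force distance enumeration on a toy set", {
  # 6 training points, 2 features, one borderline test point
  train <- matrix(c(0, 0,  1, 0,  0, 1,  4, 4,  5, 4,  4, 5),
                  ncol = 2, byrow = TRUE)
  y <- c("a", "a", "a", "b", "b", "b")
  test <- matrix(c(2.4, 2.4), ncol = 2)
  # independent oracle: enumerate all distances, majority of 3 nearest
  d <- sqrt(rowSums((train - matrix(test, 6, 2, byrow = TRUE))^2))
  oracle <- names(sort(table(y[order(d)[1:3]]), decreasing = TRUE))[1]
  expect_equal(unname(nirselect:::knn_predict(train, y, test, 3)), oracle)

  # k = 1 with a duplicated training point returns that label
  expect_equal(unname(nirselect:::knn_predict(train, y, train[4, , drop = FALSE], 1)),
               "b")
  expect_error(nirselect:::knn_predict(train, y, test, 7), "exceeds")
})

test_that("k-NN matches FNN on tie-free random data", {
  skip_if_not_installed("FNN")
  set.seed(31)
  train <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), 20)
  test <- matrix(rnorm(15 * 6), 15, 6)
  ours <- nirselect:::knn_predict(train, y, test, 5)
  ref <- as.character(FNN::knn(train, test, factor(y), k = 5))
  expect_equal(unname(ours), ref)
})

test_that("separable classes give perfect holdout accuracy for any informative mask", {
  ft <- make_sep_table(n_per = 10, d = 4, gap = 10, sd = 0.1)
  spec <- cost_spec(split_seed = 7)
  sp <- make_split(ft, spec)
  for (bits in list(c(1, 0, 0, 0), c(0, 0, 1, 1), rep(1, 4)))
    expect_equal(knn_accuracy(ft, nirselect:::new_mask(bits), sp, k = 5), 1)
})

test_that("wrapper cost follows the accuracy/size tradeoff formula", {
  ft <- make_sep_table(n_per = 10, d = 4)
  spec <- cost_spec(split_seed = 7)
  sp <- make_split(ft, spec)
  # perfect accuracy with all features: J = 0.99*0 + 0.01*1
  res <- evaluate_cost(rep(1, 4), ft, sp, spec)
  expect_equal(res$J, 0.01)
  expect_equal(res$accuracy, 1)
  # empty mask: policy cost
  res0 <- evaluate_cost(rep(0, 4), ft, sp, spec)
  expect_equal(res0$J, 1.0)
  expect_equal(res0$n_selected, 0L)
  # J strictly increases with subset size at fixed (perfect) accuracy
  js <- vapply(1:4, function(k)
    evaluate_cost(nirselect:::new_mask(c(rep(1, k), rep(0, 4 - k))),
                  ft, sp, spec)$J, 0)
  expect_true(all(diff(js) > 0))
})

test_that("an 11/12-correct holdout reproduces the printed-accuracy arithmetic", {
  # 60 trials, holdout 0.2 -> 12 test trials; force exactly one test error,
  # accuracy 11/12 = 0.9167 as printed for the full-feature column
  ft <- make_sep_table(seed = 5, n_per = 30, d = 2, gap = 10, sd = 0.1)
  spec <- cost_spec(split_seed = 13)
  sp <- make_split(ft, spec)
  victim <- sp$test_indices[ft$labels[sp$test_indices] == "a"][1]
  ft$values[victim, ] <- 10      # moved into class b territory
  res <- evaluate_cost(rep(1, 2), ft, sp, spec)
  expect_equal(res$accuracy, 11 / 12)
  expect_equal(res$J, 0.99 * (1 - 11 / 12) + 0.01, tolerance = 1e-12)
  expect_equal(round(res$J, 4), 0.0925)
})

test_that("evaluate_cost is pure: repeated calls agree bit-for-bit", {
  ft <- make_d8_table(2)
  spec <- cost_spec(split_seed = 3)
  sp <- make_split(ft, spec)
  pos <- nirselect:::with_seed(1, runif(8))
  r1 <- evaluate_cost(pos, ft, sp, spec)
  r2 <- evaluate_cost(pos, ft, sp, spec)
  expect_identical(r1, r2)
})

test_that("exhaustive oracle enumerates all masks and applies the tie rules", {
  ft3 <- nirselect:::with_seed(4, {
    lab <- rep(c("a", "b"), each = 10)
    sep <- ifelse(lab == "a", -3, 3) + rnorm(20, sd = 0.2)
    nirselect:::new_feature_table(cbind(sep, rnorm(20), rnorm(20)), lab,
                                  sprintf("C%d", 1:3), rep("mean", 3))
  })
  spec <- cost_spec(split_seed = 21)
  sp <- make_split(ft3, spec)
  or <- exhaustive_oracle(ft3, sp, spec)
  expect_equal(or$n_evaluated, 7)
  expect_equal(or$best_mask$bits, c(1L, 0L, 0L))   # the separating feature

  # duplicated separating feature: equal J, equal size -> lexicographically
  # smaller bit vector wins ([0,1,0] sorts before [1,0,0])
  ftdup <- ft3
  ftdup$values[, 2] <- ftdup$values[, 1]
  ordup <- exhaustive_oracle(ftdup, sp, spec)
  expect_equal(ordup$best_mask$bits, c(0L, 1L, 0L))

  big <- make_sep_table(n_per = 10, d = 13)
  expect_error(exhaustive_oracle(big, make_split(big, spec), spec), "d_max")
})
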