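#' Wrapper cost specification
#'
#' Parameters of the wrapper objective J = alpha * (1 - accuracy) +
#' beta * n_selected / D, scored by a k-nearest-neighbor classifier on one
#' fixed stratified holdout split. Defaults: alpha 0.99, beta 0.01, k = 5
#' neighbors, 0.2 holdout fraction, binarization threshold 0.5, and worst
#' cost 1 for an empty mask.
#'
#' @param alpha Accuracy weight.
#' @param beta Subset-size weight.
#' @param k Neighbor count.
#' @param holdout_fraction Test share of trials.
#' @param split_seed Optional seed pinning the holdout split; when `NULL` the
#'   optimizer derives one from its run seed.
#' @param binarize_threshold Position-to-bit threshold in (0, 1).
#' @param empty_mask_cost Cost assigned to an empty feature subset.
#' @param standardize Z-score features using training-set statistics before
#'   the k-NN distance (off by default; raw features match the usual wrapper
#'   toolbox behavior).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(alpha = 0.99, beta = 0.01, k = 5, holdout_fraction = 0.2,
                      split_seed = NULL, binarize_threshold = 0.5,
                      empty_mask_cost = 1, standardize = FALSE) {
  if (k < 1) stop_param("k must be >= 1")
  if (!(holdout_fraction > 0 && holdout_fraction < 1))
    stop_param("holdout_fraction must lie in (0, 1)")
  if (!(binarize_threshold > 0 && binarize_threshold < 1))
    stop_param("binarize_threshold must lie in (0, 1)")
  structure(list(alpha = alpha, beta = beta, k = as.integer(k),
                 holdout_fraction = holdout_fraction,
                 split_seed = if (is.null(split_seed)) NULL else as.integer(split_seed),
                 binarize_threshold = binarize_threshold,
                 empty_mask_cost = empty_mask_cost,
                 standardize = isTRUE(standardize)),
            class = "cost_spec")
}

#' Binarize a continuous search position into a feature mask
#'
#' Bit d is 1 iff `position[d] > threshold` (strict, so a value exactly at the
#' threshold is excluded). Empty masks are permitted here and penalized in
#' [evaluate_cost()].
#'
#' @param position Numeric vector in `[0, 1]^D`.
#' @param threshold Scalar threshold.
#' @return A `feature_mask`: list with integer `bits` and `n_selected`.
#' @export
binarize <- function(position, threshold = 0.5) {
  if (any(!is.finite(position))) stop_param("non-finite position")
  new_mask(as.integer(position > threshold))
}

new_mask <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  structure(list(bits = bits, n_selected = sum(bits)), class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d features selected\n",
              x$n_selected, length(x$bits)))
  invisible(x)
}

#' Stratified holdout split
#'
#' Draws a seeded, class-stratified train/test partition of the trials. The
#' test set holds `round(holdout_fraction * n_c)` trials of each class, so
#' class proportions are preserved up to rounding. The same `(table, spec)`
#' always yields the same split.
#'
#' @param table A `feature_table`.
#' @param spec A [cost_spec()]; `spec$split_seed` must be set (optimizer runs
#'   derive it from the run seed).
#' @return A `split_fixture`: list with `train_indices`, `test_indices`.
#' @export
make_split <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "cost_spec"))
  seed <- spec$split_seed
  if (is.null(seed)) stop_param("spec$split_seed is not set")
  labs <- table$labels
  classes <- sort(unique(labs))
  counts <- table(labs)
  if (any(counts < 2)) stop_param("every class needs at least 2 trials")
  test <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labs == cl)
      n_test <- round_half_up(spec$holdout_fraction * length(idx))
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      test <- c(test, sort(sample(idx, n_test)))
    }
  })
  test <- sort(test)
  structure(list(train_indices = setdiff(seq_along(labs), test),
                 test_indices = test),
            class = "split_fixture")
}

# Deterministic k-NN with documented tie rules: neighbors ordered by distance
# with ties broken by training-trial index; vote ties broken by the smallest
# class label (alphabetical). Bit-exact reproducibility is part of the cost
# contract.
knn_predict <- function(train_x, train_y, test_x, k) {
  if (k > nrow(train_x)) stop_param("k exceeds training-set size")
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  classes <- sort(unique(train_y))
  apply(d2, 1, function(row) {
    nn <- order(row, seq_along(row))[seq_len(k)]
    votes <- table(factor(train_y[nn], levels = classes))
    classes[which.max(votes)]
  })
}

#' Holdout k-NN accuracy of a feature subset
#'
#' Euclidean-distance majority vote over the `k` nearest training trials,
#' restricted to the masked feature columns.
#'
#' @param table A `feature_table`.
#' @param mask A `feature_mask` (non-empty).
#' @param split A `split_fixture` from [make_split()].
#' @param k Neighbor count.
#' @param standardize Z-score columns on training statistics first.
#' @return Fraction of test trials classified correctly, in `[0, 1]`.
#' @export
knn_accuracy <- function(table, mask, split, k = 5, standardize = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(mask, "feature_mask"),
            inherits(split, "split_fixture"))
  if (mask$n_selected == 0) stop_param("empty mask has no k-NN accuracy")
  cols <- which(mask$bits == 1L)
  tr <- table$values[split$train_indices, cols, drop = FALSE]
  te <- table$values[split$test_indices, cols, drop = FALSE]
  if (standardize) {
    mu <- colMeans(tr)
    sd_ <- apply(tr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    tr <- sweep(sweep(tr, 2, mu), 2, sd_, "/")
    te <- sweep(sweep(te, 2, mu), 2, sd_, "/")
  }
  pred <- knn_predict(tr, table$labels[split$train_indices], te, k)
  mean(pred == table$labels[split$test_indices])
}

#' Evaluate the wrapper cost of a position or mask
#'
#' J = alpha * (1 - accuracy) + beta * n_selected / D for non-empty masks;
#' empty masks score `spec$empty_mask_cost`. A pure function of its inputs:
#' repeated calls agree bit-for-bit.
#'
#' @param x A `feature_mask`, or a numeric position vector which is first
#'   passed through [binarize()] at `spec$binarize_threshold`.
#' @param table A `feature_table`.
#' @param split A `split_fixture`.
#' @param spec A [cost_spec()].
#' @return List with `J`, `accuracy` (NA for the empty mask), `n_selected`.
#' @export
evaluate_cost <- function(x, table, split, spec = cost_spec()) {
  mask <- if (inherits(x, "feature_mask")) x else
    binarize(x, spec$binarize_threshold)
  d <- ncol(table$values)
  if (length(mask$bits) != d) stop_param("mask length != feature count")
  if (mask$n_selected == 0)
    return(list(J = spec$empty_mask_cost, accuracy = NA_real_,
                n_selected = 0L))
  acc <- knn_accuracy(table, mask, split, k = spec$k,
                      standardize = spec$standardize)
  list(J = spec$alpha * (1 - acc) + spec$beta * mask$n_selected / d,
       accuracy = acc, n_selected = mask$n_selected)
}

#' Exhaustive subset oracle
#'
#' Enumerates every non-empty mask over D features (refusing D beyond
#' `d_max`), evaluates the wrapper cost for each, and returns the minimum.
#' Ties are broken by fewer selected features, then by lexicographically
#' smaller bit vector. Ground truth for optimizer testing.
#'
#' @param table A `feature_table` with at most `d_max` columns.
#' @param split A `split_fixture`.
#' @param spec A [cost_spec()].
#' @param d_max Combinatorial guard (default 12).
#' @return List with `best_mask`, `best_J`, and `n_evaluated`.
#' @export
exhaustive_oracle <- function(table, split, spec = cost_spec(), d_max = 12) {
  d <- ncol(table$values)
  if (d > d_max) stop_param("refusing exhaustive enumeration for D = ", d,
                            " > d_max = ", d_max)
  n_masks <- 2^d - 1
  best <- NULL
  for (m in seq_len(n_masks)) {
    bits <- as.integer(bitwAnd(bitwShiftR(m, 0:(d - 1)), 1L))
    mask <- new_mask(bits)
    res <- evaluate_cost(mask, table, split, spec)
    key <- list(J = res$J, n = mask$n_selected,
                lex = paste(bits, collapse = ""))
    if (is.null(best) || res$J < best$J - 1e-15 ||
        (abs(res$J - best$J) <= 1e-15 &&
         (mask$n_selected < best$n ||
          (mask$n_selected == best$n && key$lex < best$lex)))) {
      best <- list(J = res$J, n = mask$n_selected, lex = key$lex, mask = mask)
    }
  }
  list(best_mask = best$mask, best_J = best$J, n_evaluated = n_masks)
}
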