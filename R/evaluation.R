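#' Repeated optimizer runs with summary statistics
#'
#' Runs the configured algorithm `n_runs` times with seeds
#' `config$seed + 1 ... config$seed + n_runs` and summarizes per-run holdout
#' accuracy (in percent) and selected-feature count as plain means and sample
#' (n-1) standard deviations. All per-run results are kept so every reported
#' mean +/- sd is exactly recomputable.
#'
#' @param table A `feature_table`.
#' @param config A [search_config()]; its `seed` is the base seed.
#' @param spec A [cost_spec()].
#' @param n_runs Number of repeats (>= 2).
#' @return A `repeated_run_summary`: list with `algorithm`, `n_runs`,
#'   `acc_mean`, `acc_sd`, `fvs_mean`, `fvs_sd`, `wall_time_mean`, `runs`.
#' @export
repeat_runs <- function(table, config, spec = cost_spec(), n_runs = 10) {
  stopifnot(inherits(config, "search_config"))
  if (n_runs < 2) stop_param("n_runs must be >= 2")
  runs <- vector("list", n_runs)
  times <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r
    times[r] <- system.time(
      runs[[r]] <- run_optimizer(table, cfg, spec)
    )[["elapsed"]]
  }
  acc <- vapply(runs, function(x) 100 * x$best_accuracy, 0)
  fvs <- vapply(runs, function(x) as.numeric(x$n_selected), 0)
  structure(list(algorithm = config$algorithm, n_runs = n_runs,
                 acc_mean = mean(acc), acc_sd = stats::sd(acc),
                 fvs_mean = mean(fvs), fvs_sd = stats::sd(fvs),
                 wall_time_mean = mean(times), runs = runs),
            class = "repeated_run_summary")
}

#' @export
print.repeated_run_summary <- function(x, ...) {
  cat(sprintf("<repeated_run_summary> %s (%d runs): Acc %.1f +/- %.1f %%, F.V.S. %.1f +/- %.1f\n",
              x$algorithm, x$n_runs, x$acc_mean, x$acc_sd, x$fvs_mean,
              x$fvs_sd))
  invisible(x)
}

#' Full-feature baseline accuracy
#'
#' Holdout k-NN accuracy (in percent) using every feature (the all-ones
#' mask) on the split defined by `spec`. The comparison point for all
#' selected subsets.
#'
#' @param table A `feature_table`.
#' @param spec A [cost_spec()] with `split_seed` set.
#' @return Accuracy in percent.
#' @export
full_feature_baseline <- function(table, spec = cost_spec(split_seed = 1)) {
  split <- make_split(table, spec)
  mask <- new_mask(rep(1L, ncol(table$values)))
  100 * knn_accuracy(table, mask, split, k = spec$k,
                     standardize = spec$standardize)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p value (a pooled-variance option is provided).
#' Degenerate case: both samples constant with equal means gives t = 0,
#' p = 1; constant with different means gives infinite t, p = 0.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param pooled Use the pooled-variance (Student) test instead.
#' @return List with `t`, `p`, `df`.
#' @export
welch_ttest <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop_param("each sample needs >= 2 values")
  if (any(!is.finite(c(a, b)))) stop_param("non-finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Compare algorithms on one feature table
#'
#' Repeat-runs every requested algorithm, computes the full-feature baseline
#' on each run's own split machinery, and Welch-tests every algorithm pair on
#' the per-run accuracies.
#'
#' @param table A `feature_table`.
#' @param algorithms Character vector of algorithm names (default all seven).
#' @param spec A [cost_spec()].
#' @param n_runs Repeats per algorithm.
#' @param T,N Iteration and population size.
#' @param base_seed Base seed; run r of every algorithm uses
#'   `base_seed + r`.
#' @return A `comparison_report`: list with `summaries`,
#'   `full_feature_accuracy`, `pairwise_tests`.
#' @export
compare_algorithms <- function(table, algorithms = ALGORITHMS,
                               spec = cost_spec(), n_runs = 10, T = 100,
                               N = 10, base_seed = 1L) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  summaries <- lapply(algorithms, function(alg)
    repeat_runs(table, search_config(alg, T = T, N = N, seed = base_seed),
                spec, n_runs))
  names(summaries) <- algorithms
  base_spec <- spec
  if (is.null(base_spec$split_seed))
    base_spec$split_seed <- derive_seed(base_seed + 1L, 77L)
  baseline <- full_feature_baseline(table, base_spec)
  tests <- NULL
  if (length(algorithms) > 1) {
    pairs <- utils::combn(algorithms, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      acc_a <- vapply(summaries[[a]]$runs, function(x) 100 * x$best_accuracy, 0)
      acc_b <- vapply(summaries[[b]]$runs, function(x) 100 * x$best_accuracy, 0)
      wt <- welch_ttest(acc_a, acc_b)
      data.frame(algorithm_a = a, algorithm_b = b, t = wt$t, p = wt$p)
    }))
  }
  build_report(summaries, baseline, tests)
}

#' Assemble a comparison report
#'
#' Table-shaped summary: one row per algorithm with feature-vector size
#' (F.V.S.) and accuracy as mean +/- sd, plus the full-feature baseline and
#' optional pairwise significance tests.
#'
#' @param summaries Named list of `repeated_run_summary` objects.
#' @param full_feature_accuracy Baseline accuracy in percent.
#' @param pairwise_tests Optional data.frame of pairwise Welch tests.
#' @return A `comparison_report`.
#' @export
build_report <- function(summaries, full_feature_accuracy,
                         pairwise_tests = NULL) {
  stopifnot(length(summaries) >= 1)
  if (!is.null(pairwise_tests))
    stopifnot(all(pairwise_tests$p >= 0 & pairwise_tests$p <= 1))
  structure(list(summaries = summaries,
                 full_feature_accuracy = full_feature_accuracy,
                 pairwise_tests = pairwise_tests),
            class = "comparison_report")
}

#' @rdname build_report
#' @param report A `comparison_report`.
#' @return `report_table()`: data.frame with one row per algorithm.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  df <- do.call(rbind, lapply(report$summaries, function(s)
    data.frame(algorithm = s$algorithm, n_runs = s$n_runs,
               fvs_mean = s$fvs_mean, fvs_sd = s$fvs_sd,
               acc_mean = s$acc_mean, acc_sd = s$acc_sd,
               wall_time_mean = s$wall_time_mean)))
  rownames(df) <- NULL
  df
}

#' @export
print.comparison_report <- function(x, ...) {
  df <- report_table(x)
  cat("Algorithm comparison (mean +/- sd over runs):\n")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-4s F.V.S. %6.1f +/- %5.1f   Acc %5.1f +/- %4.1f %%\n",
                df$algorithm[i], df$fvs_mean[i], df$fvs_sd[i],
                df$acc_mean[i], df$acc_sd[i]))
  cat(sprintf("  full features: Acc %5.2f %%\n", x$full_feature_accuracy))
  invisible(x)
}

#' Serialize / restore a comparison report as JSON
#'
#' Keeps per-run masks (as 0/1 strings), costs, accuracies, and curves, so
#' the summary statistics can be recomputed exactly from the file.
#'
#' @param report A `comparison_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  ser_run <- function(r) list(
    algorithm = r$algorithm, seed = r$seed,
    mask = paste(r$best_mask$bits, collapse = ""),
    best_cost = r$best_cost, best_accuracy = r$best_accuracy,
    n_selected = r$n_selected, curve = r$curve, evaluations = r$evaluations)
  out <- list(
    full_feature_accuracy = report$full_feature_accuracy,
    summaries = lapply(report$summaries, function(s) list(
      algorithm = s$algorithm, n_runs = s$n_runs, acc_mean = s$acc_mean,
      acc_sd = s$acc_sd, fvs_mean = s$fvs_mean, fvs_sd = s$fvs_sd,
      wall_time_mean = s$wall_time_mean, runs = lapply(s$runs, ser_run))),
    pairwise_tests = report$pairwise_tests)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  des_run <- function(r) structure(list(
    algorithm = r$algorithm, seed = r$seed,
    best_mask = new_mask(as.integer(strsplit(r$mask, "")[[1]])),
    best_cost = r$best_cost, best_accuracy = r$best_accuracy,
    n_selected = r$n_selected, curve = unlist(r$curve),
    evaluations = r$evaluations), class = "run_result")
  summaries <- lapply(raw$summaries, function(s) structure(list(
    algorithm = s$algorithm, n_runs = s$n_runs, acc_mean = s$acc_mean,
    acc_sd = s$acc_sd, fvs_mean = s$fvs_mean, fvs_sd = s$fvs_sd,
    wall_time_mean = s$wall_time_mean,
    runs = lapply(s$runs, des_run)), class = "repeated_run_summary"))
  names(summaries) <- vapply(summaries, `[[`, "", "algorithm")
  tests <- raw$pairwise_tests
  if (!is.null(tests) && length(tests))
    tests <- do.call(rbind, lapply(tests, as.data.frame))
  else tests <- NULL
  build_report(summaries, raw$full_feature_accuracy, tests)
}

#' Fraction of selected features lying on given channels
#'
#' Enrichment diagnostic for synthetic ground truth: of all features selected
#' across a summary's runs, the fraction belonging to the listed channels
#' (e.g. the generator's informative channels). Under chance selection this
#' equals the channel base rate.
#'
#' @param summary A `repeated_run_summary`.
#' @param table The `feature_table` the runs were made on.
#' @param channels Character vector of channel labels.
#' @return Fraction in `[0, 1]`.
#' @export
selected_channel_fraction <- function(summary, table, channels) {
  in_ch <- table$channels %in% channels
  sel <- vapply(summary$runs, function(r) sum(r$best_mask$bits[in_ch]), 0)
  tot <- vapply(summary$runs, function(r) r$best_mask$n_selected, 0)
  sum(sel) / sum(tot)
}
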