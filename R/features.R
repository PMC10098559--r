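STAT_NAMES <- c("mean", "peak", "slope", "skewness", "kurtosis")

#' Five temporal statistics of a windowed signal
#'
#' The classic fNIRS temporal feature set: signal mean, peak (maximum), slope
#' of a least-squares line fit (per second, with the time axis in seconds),
#' skewness, and kurtosis. Skewness and kurtosis are population-moment ratios
#' (divide by N, σ in the denominator), and kurtosis is the raw fourth
#' standardized moment — a Gaussian signal has kurtosis 3, not 0.
#'
#' @param x Numeric vector, the windowed ΔHbO signal (length >= 3).
#' @param fs Sampling rate in Hz; fixes the slope's time units.
#' @return Named numeric vector `mean`, `peak`, `slope`, `skewness`,
#'   `kurtosis`.
#' @examples
#' channel_statistics(c(1, 2, 3), fs = 1)
#' @export
channel_statistics <- function(x, fs) {
  if (length(x) < 3) stop_param("need at least 3 samples")
  if (any(!is.finite(x))) stop_param("non-finite values in signal")
  if (fs <= 0) stop_param("fs must be positive")
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  sigma <- sqrt(mean(xc^2))
  if (sigma == 0)
    stop_param("constant signal: skewness and kurtosis are undefined ",
               "(degenerate moment, sigma = 0)")
  t_sec <- (seq_len(n) - 1) / fs
  tc <- t_sec - mean(t_sec)
  c(mean = mu,
    peak = max(x),
    slope = sum(tc * xc) / sum(tc^2),
    skewness = mean(xc^3) / sigma^3,
    kurtosis = mean(xc^4) / sigma^4)
}

#' Extract the trial-by-feature table
#'
#' Applies [channel_statistics()] to every (trial, channel) slice of an
#' epoched tensor and assembles the trials x (channels * 5) matrix. Columns
#' are channel-major: the five statistics of channel 1, then channel 2, and
#' so on, named `<channel>.<statistic>`.
#'
#' @param trials A `trial_tensor` from [epoch()].
#' @return A `feature_table`: list with `values` (trials x D matrix),
#'   `labels`, `channels`, `statistics` (per-column channel / statistic
#'   names).
#' @export
extract_features <- function(trials) {
  stopifnot(inherits(trials, "trial_tensor"))
  d <- dim(trials$data)
  if (d[1] == 0) stop_param("empty trial tensor")
  n_tr <- d[1]; n_ch <- d[2]
  ch_labels <- trials$channel_labels %||% sprintf("CH%02d", seq_len(n_ch))
  vals <- matrix(NA_real_, nrow = n_tr, ncol = n_ch * 5L)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      s <- tryCatch(channel_statistics(trials$data[tr, ch, ], trials$fs),
                    error = function(e)
                      stop_param("trial ", tr, ", channel ", ch, ": ",
                                 conditionMessage(e)))
      vals[tr, (ch - 1) * 5 + 1:5] <- s
    }
  }
  new_feature_table(vals,
                    labels = trials$labels,
                    channels = rep(ch_labels, each = 5),
                    statistics = rep(STAT_NAMES, n_ch))
}

new_feature_table <- function(values, labels, channels, statistics) {
  stopifnot(is.matrix(values), nrow(values) == length(labels),
            ncol(values) == length(channels),
            length(channels) == length(statistics))
  if (any(!is.finite(values))) stop_param("non-finite feature values")
  colnames(values) <- paste(channels, statistics, sep = ".")
  structure(list(values = values, labels = as.character(labels),
                 channels = as.character(channels),
                 statistics = as.character(statistics)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d features (%d channels x 5), classes: %s\n",
              nrow(x$values), ncol(x$values), ncol(x$values) / 5,
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Serialize a feature table as delimited text
#'
#' Two header rows (channel, statistic), then one row per trial: class label
#' followed by the feature values. Round-trips losslessly.
#'
#' @param table A `feature_table`.
#' @param path Output file path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("channel", table$channels), collapse = "\t"), con)
  writeLines(paste(c("statistic", table$statistics), collapse = "\t"), con)
  for (i in seq_len(nrow(table$values)))
    writeLines(paste(c(table$labels[i],
                       sprintf("%.17g", table$values[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop_param("malformed feature table file")
  split_tab <- function(s) strsplit(s, "\t", fixed = TRUE)[[1]]
  channels <- split_tab(lines[1])[-1]
  statistics <- split_tab(lines[2])[-1]
  body <- lapply(lines[-(1:2)], split_tab)
  labels <- vapply(body, `[`, "", 1)
  vals <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  new_feature_table(vals, labels, channels, statistics)
}
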