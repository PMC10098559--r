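# Fixtures are generated in code, seeded, at test time.

# D = 8 wrapper-cost landscape with one perfectly separating feature and
# seven pure-noise features; 25 trials per class so the 10-trial holdout
# cannot be separated by a noise feature by luck.
make_d8_table <- function(seed = 7, n_per = 25) {
  nirselect:::with_seed(seed, {
    lab <- rep(c("a", "b"), each = n_per)
    sep <- ifelse(lab == "a", -2, 2) + stats::rnorm(2 * n_per, sd = 0.3)
    vals <- cbind(sep, matrix(stats::rnorm(2 * n_per * 7), 2 * n_per, 7))
    nirselect:::new_feature_table(vals, lab, sprintf("C%d", 1:8),
                                  rep("mean", 8))
  })
}

# Well-separated two-class Gaussian table (every feature informative).
make_sep_table <- function(seed = 1, n_per = 10, d = 4, gap = 10, sd = 0.1) {
  nirselect:::with_seed(seed, {
    lab <- rep(c("a", "b"), each = n_per)
    mu <- ifelse(lab == "a", 0, gap)
    vals <- matrix(stats::rnorm(2 * n_per * d, sd = sd), 2 * n_per, d) + mu
    nirselect:::new_feature_table(vals, lab, sprintf("C%d", 1:d),
                                  rep("mean", d))
  })
}

# Pure-noise table: no feature carries class information.
make_noise_table <- function(seed = 1, n_per = 10, d = 6) {
  nirselect:::with_seed(seed, {
    lab <- rep(c("a", "b"), each = n_per)
    vals <- matrix(stats::rnorm(2 * n_per * d), 2 * n_per, d)
    nirselect:::new_feature_table(vals, lab, sprintf("C%d", 1:d),
                                  rep("mean", d))
  })
}

# Small noiseless session: deterministic activation only, generous rests so
# consecutive responses never overlap (closed-form oracle applies).
noiseless_activation <- function(seed = 1, amplitude = 1,
                                 informative = list(task = 1:2)) {
  activation_spec(informative_channels = informative, amplitude = amplitude,
                  noise = list(drift_per_min = 0, mayer_amp = 0, resp_amp = 0,
                               cardiac_amp = 0, white_sd = 0),
                  seed = seed)
}

quick_paradigm <- function(n_channels = 4, n_trials_per_class = 3,
                           pre_rest_s = 20, post_rest_s = 20, ...) {
  paradigm_config(n_channels = n_channels,
                  n_trials_per_class = n_trials_per_class,
                  pre_rest_s = pre_rest_s, post_rest_s = post_rest_s, ...)
}

# Independent O(n^2) direct convolution, the oracle for FFT-based responses.
conv_direct <- function(x, h) {
  n <- length(x) + length(h) - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- max(1, i - length(h) + 1):min(i, length(x))
    out[i] <- sum(x[k] * h[i - k + 1])
  }
  out
}
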