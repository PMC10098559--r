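#' Band-limiting filter specification
#'
#' Cascade of a Butterworth low-pass and a Butterworth high-pass, the standard
#' conditioning for slow hemodynamic signals: the low-pass (default 0.1 Hz)
#' suppresses cardiac (~1 Hz), respiratory (~0.25 Hz) and Mayer-wave
#' components, the high-pass (default 0.01 Hz) removes baseline drift. Both
#' filters default to 3rd order. With `zero_phase = TRUE` (default) each
#' filter is applied forward and backward, so no phase distortion shifts the
#' task window, at the price of doubling the effective order.
#'
#' @param lp_cutoff,hp_cutoff Low-pass and high-pass cutoffs in Hz.
#' @param order Butterworth order of each filter.
#' @param zero_phase Apply each filter forward-backward.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(lp_cutoff = 0.1, hp_cutoff = 0.01, order = 3,
                        zero_phase = TRUE) {
  if (order < 1) stop_param("order must be >= 1")
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff))
    stop_param("need 0 < hp_cutoff < lp_cutoff")
  structure(list(lp_cutoff = lp_cutoff, hp_cutoff = hp_cutoff,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# ---- Butterworth design (transfer-function form via bilinear transform) ----
# No DSP package ships with this stack, so the design is done from first
# principles: analog prototype poles on the unit circle, frequency prewarp,
# low/high-pass transform, bilinear map to z, polynomial expansion.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

butter_coeffs <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop_param("cutoff must lie in (0, fs/2)")
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP unit poles
  wc <- 2 * fs * tan(pi * cutoff / fs)                        # prewarped rad/s
  if (type == "low") {
    poles <- wc * proto
    zeros <- complex(0)
    gain <- wc^order
  } else {
    poles <- wc / proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  }
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, order - length(zeros)))  # zeros at infinity -> z=-1
  b <- Re(gd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Analytic magnitude response of the designed digital filter at frequency f.
butter_response <- function(coef, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  zp <- outer(z, 0:(length(coef$b) - 1), `^`)
  Mod((zp %*% coef$b) / (zp[, seq_along(coef$a), drop = FALSE] %*% coef$a))
}

# Direct-form IIR filtering via stats::filter (C speed): FIR numerator by
# convolution, then the recursive denominator.
filter_ba <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

# Zero-phase (forward-backward) filtering with odd-reflection end padding.
# padlen should cover the filter's settling time; callers size it from the
# slowest pole.
filtfilt_ba <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1, max(padlen, 3 * (max(length(a), length(b)) - 1)))
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- filter_ba(b, a, ext)
  y <- rev(filter_ba(b, a, rev(y)))
  y[padlen + seq_len(n)]
}

#' Band-limit a recording with the Butterworth cascade
#'
#' Applies the low-pass then the high-pass of `spec` to every channel of the
#' continuous recording (filtering before epoching lets edge transients fall
#' into rest periods). Triggers and sampling rate are unchanged.
#'
#' @param rec A `nirs_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `nirs_recording`.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(spec, "filter_spec"))
  if (spec$lp_cutoff >= rec$fs / 2)
    stop_param("lp_cutoff at or above Nyquist for fs = ", rec$fs)
  lp <- butter_coeffs(spec$order, spec$lp_cutoff, rec$fs, "low")
  hp <- butter_coeffs(spec$order, spec$hp_cutoff, rec$fs, "high")
  # settling time is set by the high-pass corner: pad ~ 18 time constants
  padlen <- ceiling(18 * rec$fs / (2 * pi * spec$hp_cutoff))
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    if (spec$zero_phase) {
      x <- filtfilt_ba(lp$b, lp$a, x, padlen)
      x <- filtfilt_ba(hp$b, hp$a, x, padlen)
    } else {
      x <- filter_ba(lp$b, lp$a, x)
      x <- filter_ba(hp$b, hp$a, x)
    }
    data[ch, ] <- x
  }
  rec$data <- data
  rec
}

# ---- Polyphase resampling -------------------------------------------------

rationalize <- function(ratio, max_den = 512) {
  # continued-fraction rational approximation of the rate ratio
  best <- c(1L, 1L); x <- ratio
  h <- c(0, 1); k <- c(1, 0)
  for (i in 1:32) {
    ai <- floor(x)
    h <- c(h[2], ai * h[2] + h[1])
    k <- c(k[2], ai * k[2] + k[1])
    if (k[2] > max_den) break
    best <- c(h[2], k[2])
    frac <- x - ai
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  as.integer(best)
}

# Windowed-sinc polyphase resampler for one signal; L/M in lowest terms.
# Each polyphase branch is normalized to unit DC gain so constants are
# preserved to machine precision.
resample_signal <- function(x, L, M) {
  if (L == M) return(x)
  n <- length(x)
  half_lobes <- 10
  hw <- half_lobes * max(L, M)
  idx <- (-hw):hw
  xs <- idx / max(L, M)
  h <- ifelse(idx == 0, 1, sin(pi * xs) / (pi * xs)) *
    (0.54 + 0.46 * cos(pi * idx / hw))                 # Hamming window
  # normalize per polyphase branch (branch p collects taps with idx %% L == p)
  ph <- ((idx %% L) + L) %% L
  for (p in unique(ph)) h[ph == p] <- h[ph == p] / sum(h[ph == p])

  pad <- ceiling(hw / L) + 1
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  nu <- length(xp) * L
  xu <- numeric(nu)
  xu[seq(1, by = L, length.out = length(xp))] <- xp

  yf <- stats::convolve(xu, rev(h), type = "open")     # length nu + 2*hw
  # upsampled-domain index of original sample j (1-based in xu): (pad+j-1)*L+1
  # full-conv centre offset is hw
  n_out <- ceiling(n * L / M)
  m <- 0:(n_out - 1)
  pos <- pad * L + m * M + 1          # position in xu (1-based, 0-based m*M/L)
  yf[pos + hw]
}

#' Down-sample a recording
#'
#' Anti-aliased polyphase (windowed-sinc) resampling of every channel from
#' `rec$fs` to `fs_target`; trigger onsets are rescaled to the new rate and
#' rounded half-up to the nearest sample.
#'
#' @param rec A `nirs_recording`.
#' @param fs_target Target rate in Hz, at most `rec$fs`.
#' @return The resampled `nirs_recording`.
#' @export
resample <- function(rec, fs_target) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (fs_target <= 0) stop_param("fs_target must be positive")
  if (fs_target > rec$fs) stop_param("fs_target must not exceed rec$fs")
  if (fs_target == rec$fs) return(rec)
  lm <- rationalize(fs_target / rec$fs)
  L <- lm[1]; M <- lm[2]
  data <- t(apply(rec$data, 1, function(x) resample_signal(x, L, M)))
  trig <- rec$triggers
  if (nrow(trig))
    trig$onset_sample <-
      as.integer(round_half_up((trig$onset_sample - 1) * L / M) + 1)
  new_recording(data, fs_target, rec$channel_labels, trig)
}

#' Epoch a recording into a trial tensor
#'
#' Cuts one fixed window per trigger, expressed in seconds relative to the
#' trigger (task onset), half-open `[start, end)`. Trials are ordered by
#' trigger onset.
#'
#' @param rec A `nirs_recording`.
#' @param window Length-2 numeric `(start_s, end_s)`.
#' @return A `trial_tensor`: list with `data` (trials x channels x samples
#'   array), `labels`, `fs`, `window`.
#' @export
epoch <- function(rec, window = c(0, 10)) {
  stopifnot(inherits(rec, "nirs_recording"), length(window) == 2,
            window[2] > window[1])
  n_samp <- round((window[2] - window[1]) * rec$fs)
  trig <- rec$triggers[order(rec$triggers$onset_sample), , drop = FALSE]
  n_tr <- nrow(trig)
  arr <- array(0, dim = c(n_tr, nrow(rec$data), n_samp))
  for (t in seq_len(n_tr)) {
    start <- trig$onset_sample[t] + round(window[1] * rec$fs)
    stop_ <- start + n_samp - 1
    if (start < 1 || stop_ > ncol(rec$data))
      stop_param("epoch window for trigger ", t, " (onset sample ",
                 trig$onset_sample[t], ") exceeds recording bounds")
    arr[t, , ] <- rec$data[, start:stop_]
  }
  structure(list(data = arr, labels = as.character(trig$label), fs = rec$fs,
                 window = window, channel_labels = rec$channel_labels),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("<trial_tensor> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}
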