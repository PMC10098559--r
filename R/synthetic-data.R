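#' Experimental paradigm configuration
#'
#' Describes the block design of a simulated fNIRS session: a pre-rest
#' baseline, a sequence of cued task trials (a visual cue, a task phase, and a
#' randomized rest interval), and a post-rest baseline. Defaults follow a
#' common motor-imagery / mental-arithmetic protocol: 36 channels acquired at
#' 12.5 Hz, 10 trials per class, 2 s cue, 10 s task, and rest drawn uniformly
#' from 15-17 s, with 60 s of rest at both ends of the session.
#'
#' @param n_channels Number of fNIRS channels.
#' @param fs_acquire Acquisition sampling rate in Hz.
#' @param fs_target Target rate (Hz) the recording is meant to be
#'   down-sampled to later; kept here for bookkeeping only.
#' @param n_trials_per_class Trials per class.
#' @param classes Character vector of class labels (2 or more).
#' @param cue_s,task_s Cue and task durations in seconds.
#' @param rest_s_range Length-2 numeric, uniform range of the inter-trial
#'   rest in seconds.
#' @param pre_rest_s,post_rest_s Session-initial and -final rest in seconds.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_channels = 36, fs_acquire = 12.5, fs_target = 10,
                            n_trials_per_class = 10,
                            classes = c("task", "baseline"),
                            cue_s = 2, task_s = 10, rest_s_range = c(15, 17),
                            pre_rest_s = 60, post_rest_s = 60) {
  if (n_channels < 1) stop_param("n_channels must be >= 1")
  if (fs_acquire <= 0 || fs_target <= 0) stop_param("sampling rates must be positive")
  if (fs_acquire < fs_target) stop_param("fs_acquire must be >= fs_target")
  if (n_trials_per_class < 1) stop_param("n_trials_per_class must be >= 1")
  if (length(classes) < 2) stop_param("need at least two classes")
  if (any(c(cue_s, task_s, pre_rest_s, post_rest_s) < 0) || task_s <= 0)
    stop_param("durations must be positive")
  if (length(rest_s_range) != 2 || any(rest_s_range <= 0) ||
      rest_s_range[1] > rest_s_range[2])
    stop_param("rest_s_range must be an increasing positive interval")
  structure(list(
    n_channels = as.integer(n_channels), fs_acquire = fs_acquire,
    fs_target = fs_target, n_trials_per_class = as.integer(n_trials_per_class),
    classes = as.character(classes), cue_s = cue_s, task_s = task_s,
    rest_s_range = rest_s_range, pre_rest_s = pre_rest_s,
    post_rest_s = post_rest_s
  ), class = "paradigm_config")
}

#' Activation and noise specification for the session generator
#'
#' Defines which channels carry a task-locked hemodynamic response for each
#' class, the response amplitude, and the additive noise model shared by all
#' channels: a slow linear drift, three physiological oscillations (Mayer
#' waves ~0.1 Hz, respiration ~0.25 Hz, cardiac ~1 Hz) with per-channel random
#' phase, and white measurement noise.
#'
#' @param informative_channels Named list (one entry per class label) of
#'   channel indices that activate during that class's task phase. Classes
#'   without an entry (or with `integer(0)`) carry no activation, which is how
#'   a "baseline" class is expressed.
#' @param amplitude Peak ΔHbO response amplitude in arbitrary concentration
#'   units. The default 0.5 puts the response at the scale of the physiological
#'   noise, so a classifier fed all channels is good but imperfect — the
#'   regime in which feature selection matters.
#' @param hrf_peak_s Hemodynamic impulse-response peak latency (s).
#' @param hrf_duration_s Impulse-response support (s).
#' @param noise Named list overriding any of: `drift_per_min`,
#'   `mayer_hz`, `mayer_amp`, `resp_hz`, `resp_amp`, `cardiac_hz`,
#'   `cardiac_amp`, `white_sd`.
#' @param seed RNG seed for the session draw.
#' @return An object of class `activation_spec`.
#' @export
activation_spec <- function(informative_channels = list(task = 1:4),
                            amplitude = 0.5, hrf_peak_s = 6, hrf_duration_s = 20,
                            noise = list(), seed = 1L) {
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  defaults <- list(drift_per_min = 0.01,
                   mayer_hz = 0.1, mayer_amp = 0.2,
                   resp_hz = 0.25, resp_amp = 0.1,
                   cardiac_hz = 1, cardiac_amp = 0.1,
                   white_sd = 0.2)
  unknown <- setdiff(names(noise), names(defaults))
  if (length(unknown)) stop_param("unknown noise component(s): ",
                                  paste(unknown, collapse = ", "))
  defaults[names(noise)] <- noise
  amps <- unlist(defaults[c("mayer_amp", "resp_amp", "cardiac_amp", "white_sd")])
  if (any(amps < 0)) stop_param("noise amplitudes must be >= 0")
  structure(list(
    informative_channels = lapply(informative_channels, as.integer),
    amplitude = amplitude, hrf_peak_s = hrf_peak_s,
    hrf_duration_s = hrf_duration_s, noise = defaults, seed = as.integer(seed)
  ), class = "activation_spec")
}

#' Canonical hemodynamic impulse response
#'
#' A unimodal gamma-shaped kernel standing in for the hemodynamic response
#' function (HRF): the slow blood-oxygenation change that follows neural
#' activation. The kernel is non-negative, peaks at `peak_s`, and is
#' normalized to unit maximum.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Kernel support in seconds.
#' @param peak_s Peak latency in seconds; must be < `duration_s`.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @examples
#' h <- generate_hrf_kernel(10, 20, 6)
#' which.max(h) - 1L   # peak at sample 60 (0-based), i.e. 6 s at 10 Hz
#' @export
generate_hrf_kernel <- function(fs, duration_s, peak_s = 6) {
  if (fs <= 0) stop_param("fs must be positive")
  if (!(duration_s > peak_s && peak_s > 0))
    stop_param("need duration_s > peak_s > 0")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  shape <- 6                       # gamma shape; mode = (shape - 1) * scale
  scale <- peak_s / (shape - 1)
  h <- stats::dgamma(t, shape = shape, scale = scale)
  h / max(h)
}

#' Simulate one fNIRS session
#'
#' Lays out the paradigm timeline (pre-rest, shuffled trials, post-rest),
#' convolves a task-phase boxcar with the HRF kernel on each class's
#' informative channels, adds drift, physiological oscillations, and white
#' noise to every channel, and returns the continuous recording with trigger
#' annotations at task onsets. Identical `activation$seed` gives a
#' bit-identical session.
#'
#' @param paradigm A [paradigm_config()].
#' @param activation An [activation_spec()].
#' @return A `nirs_recording`: list with `data` (channels x samples matrix of
#'   ΔHbO), `fs`, `channel_labels`, and `triggers` (data.frame with 1-based
#'   `onset_sample` at the task-phase start, and `label`).
#' @export
generate_session <- function(paradigm = paradigm_config(),
                             activation = activation_spec()) {
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(activation, "activation_spec"))
  bad <- setdiff(names(activation$informative_channels), paradigm$classes)
  if (length(bad)) stop_param("informative_channels for unknown class(es): ",
                              paste(bad, collapse = ", "))
  ch_all <- unlist(activation$informative_channels, use.names = FALSE)
  if (length(ch_all) && (any(ch_all < 1) || any(ch_all > paradigm$n_channels)))
    stop_param("informative channel index out of range 1..", paradigm$n_channels)

  fs <- paradigm$fs_acquire
  n_cls <- length(paradigm$classes)
  n_trials <- n_cls * paradigm$n_trials_per_class

  with_seed(activation$seed, {
    labels <- sample(rep(paradigm$classes, paradigm$n_trials_per_class))
    rests <- stats::runif(n_trials, paradigm$rest_s_range[1],
                          paradigm$rest_s_range[2])

    # Trial t occupies [cue_start, cue+task+rest); trigger at task onset.
    cue_starts <- paradigm$pre_rest_s +
      c(0, cumsum(paradigm$cue_s + paradigm$task_s + rests))[seq_len(n_trials)]
    task_starts <- cue_starts + paradigm$cue_s
    total_s <- paradigm$pre_rest_s +
      sum(paradigm$cue_s + paradigm$task_s + rests) + paradigm$post_rest_s
    n_samp <- ceiling(total_s * fs)
    t_sec <- (seq_len(n_samp) - 1) / fs

    hrf <- generate_hrf_kernel(fs, activation$hrf_duration_s,
                               activation$hrf_peak_s)

    # Class-wise stimulus boxcars convolved with the HRF.
    response <- matrix(0, nrow = n_cls, ncol = n_samp,
                       dimnames = list(paradigm$classes, NULL))
    n_task <- round(paradigm$task_s * fs)
    for (ci in seq_len(n_cls)) {
      box <- numeric(n_samp)
      for (tr in which(labels == paradigm$classes[ci])) {
        on <- round(task_starts[tr] * fs) + 1
        box[on:min(n_samp, on + n_task - 1)] <- 1
      }
      response[ci, ] <- stats::convolve(box, rev(hrf),
                                        type = "open")[seq_len(n_samp)]
    }
    # Scale so that a lone boxcar response has unit peak: conv peak = sum over
    # kernel of overlap; max attained when boxcar covers the kernel mass.
    peak_gain <- max(stats::convolve(c(rep(1, n_task), numeric(length(hrf))),
                                     rev(hrf), type = "open"))
    response <- response / peak_gain

    nz <- activation$noise
    data <- matrix(0, nrow = paradigm$n_channels, ncol = n_samp)
    for (ch in seq_len(paradigm$n_channels)) {
      x <- nz$drift_per_min / 60 * t_sec
      for (comp in list(c(nz$mayer_hz, nz$mayer_amp),
                        c(nz$resp_hz, nz$resp_amp),
                        c(nz$cardiac_hz, nz$cardiac_amp))) {
        if (comp[2] > 0)
          x <- x + comp[2] * sin(2 * pi * comp[1] * t_sec +
                                 stats::runif(1, 0, 2 * pi))
      }
      if (nz$white_sd > 0) x <- x + stats::rnorm(n_samp, sd = nz$white_sd)
      data[ch, ] <- x
    }
    for (cls in names(activation$informative_channels)) {
      chans <- activation$informative_channels[[cls]]
      if (length(chans))
        data[chans, ] <- data[chans, , drop = FALSE] +
          rep(activation$amplitude * response[cls, ], each = length(chans))
    }

    new_recording(
      data = data, fs = fs,
      channel_labels = sprintf("CH%02d", seq_len(paradigm$n_channels)),
      triggers = data.frame(onset_sample = round(task_starts * fs) + 1L,
                            label = labels, stringsAsFactors = FALSE)
    )
  })
}

# Constructor with invariant checks shared by the generator and the readers.
new_recording <- function(data, fs, channel_labels, triggers) {
  stopifnot(is.matrix(data), fs > 0)
  if (any(!is.finite(data))) stop_param("recording contains non-finite values")
  if (nrow(triggers) > 0) {
    if (is.unsorted(triggers$onset_sample, strictly = TRUE))
      stop_param("trigger onsets must be strictly increasing")
    if (any(triggers$onset_sample < 1) ||
        any(triggers$onset_sample > ncol(data)))
      stop_param("trigger onset outside recording")
  }
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 triggers = triggers),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d channels x %d samples @ %g Hz, %d triggers\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$triggers)))
  invisible(x)
}

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The matrix goes to `<path>.tsv` (samples as rows, channels as columns, one
#' header row of channel labels); sampling rate and triggers go to
#' `<path>.json`.
#'
#' @param rec A `nirs_recording`.
#' @param path Output path stem (no extension).
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns the reconstructed `nirs_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs,
         triggers = rec$triggers),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trig <- side$triggers
  if (is.null(trig) || length(trig) == 0)
    trig <- data.frame(onset_sample = integer(0), label = character(0))
  trig$onset_sample <- as.integer(trig$onset_sample)
  new_recording(data = t(m), fs = side$fs, channel_labels = colnames(m),
                triggers = trig)
}
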