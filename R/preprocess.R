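# EMG envelope preprocessing: rectify -> low-pass -> time-normalise ->
# window-integrate, the standard recipe upstream of the information pipeline.

#' Full-wave rectify a signal
#'
#' @param x numeric vector/matrix/array.
#' @return elementwise absolute value; idempotent.
#' @export
full_wave_rectify <- function(x) {
  .check_finite(x, "full_wave_rectify() input")
  abs(x)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a Butterworth low-pass filter (default
#' 4th order, 20 Hz cut-off), giving zero net phase shift and unit DC gain.
#' The signal is odd-reflection padded at both ends before filtering so that
#' startup transients do not reach the output.
#'
#' @param x numeric vector (one trial of one muscle).
#' @param sampling_rate sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz low-pass cut-off frequency in Hz (default 20).
#' @param order Butterworth order before the forward-backward pass.
#' @return filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, sampling_rate, cutoff_hz = 20, order = 4) {
  .check_finite(x, "lowpass_zero_phase() input")
  if (sampling_rate <= 2 * cutoff_hz) {
    stop("sampling_rate must exceed twice the cut-off frequency",
         call. = FALSE)
  }
  n <- length(x)
  if (n <= 3 * (2 * order + 1)) {
    stop("signal too short for zero-phase filtering", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = "low")
  np <- n - 1L # maximal odd reflection: transients decay well before the data
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1L):(np + n)]
}

#' Time-normalise a signal by cubic-spline resampling
#'
#' Resamples a trial onto a uniform grid of `n_samples` points spanning the
#' original support (endpoints preserved), using a cubic spline.
#'
#' @param x numeric vector, length at least 4.
#' @param n_samples target length (default 1000).
#' @return resampled signal of length `n_samples`.
#' @export
time_normalize <- function(x, n_samples = 1000) {
  .check_finite(x, "time_normalize() input")
  if (length(x) < 4L) stop("need at least 4 samples for spline resampling",
                           call. = FALSE)
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  stats::spline(x = seq_along(x), y = x,
                xout = seq(1, length(x), length.out = n_samples),
                method = "fmm")$y
}

#' Resample a task signal to match the EMG time base
#'
#' Cubic-spline resampling of kinematic/dynamic task recordings onto an
#' arbitrary target length; identical to [time_normalize()] with a free
#' target length.
#'
#' @param x numeric vector, length at least 4.
#' @param target_length desired output length.
#' @return resampled series of length `target_length`.
#' @export
resample_task_signal <- function(x, target_length) {
  time_normalize(x, n_samples = target_length)
}

#' Integrate a signal over consecutive non-overlapping windows
#'
#' Each output sample is the sum over one window of `window` input samples;
#' a trailing remainder shorter than `window` is dropped.
#'
#' @param x numeric vector of length at least `window`.
#' @param window window length in samples (default 20).
#' @return envelope of length `floor(length(x) / window)`.
#' @export
integrate_windows <- function(x, window = 20) {
  .check_finite(x, "integrate_windows() input")
  if (window <= 0) stop("window must be positive", call. = FALSE)
  nw <- length(x) %/% window
  if (nw < 1L) stop("signal shorter than one window", call. = FALSE)
  colSums(matrix(x[seq_len(nw * window)], nrow = window))
}

.canonical_steps <- c("rectify", "filter", "normalize", "integrate")

#' Preprocess raw EMG into normalised envelopes
#'
#' Applies the canonical envelope chain to every trial and muscle: full-wave
#' rectification, zero-phase low-pass Butterworth filtering, cubic-spline
#' time-normalisation to `n_samples` points, and integration over
#' non-overlapping `window`-sample intervals (1000/20 samples gives a
#' 50-point waveform). The step order is validated: requesting the filter
#' before rectification is rejected.
#'
#' @param emg numeric array `trials x muscles x samples` (a matrix is taken
#'   as one trial, `muscles x samples`).
#' @param sampling_rate sampling rate of the raw recordings in Hz (> 40).
#' @param cutoff_hz,order low-pass filter settings (20 Hz, 4th order).
#' @param n_samples time-normalisation length (1000).
#' @param window integration window (20 samples).
#' @param steps character vector naming the chain order; must equal the
#'   canonical order `c("rectify", "filter", "normalize", "integrate")`.
#' @return a `processed_emg` object: array `trials x muscles x T` with
#'   attribute `provenance` recording the applied steps and parameters.
#' @export
preprocess_emg <- function(emg, sampling_rate, cutoff_hz = 20, order = 4,
                           n_samples = 1000, window = 20,
                           steps = .canonical_steps) {
  if (!identical(steps, .canonical_steps)) {
    stop("invalid preprocessing order: the chain must be ",
         paste(.canonical_steps, collapse = " -> "), call. = FALSE)
  }
  if (sampling_rate <= 40) stop("sampling_rate must exceed 40 Hz",
                                call. = FALSE)
  if (is.matrix(emg)) emg <- array(emg, dim = c(1L, dim(emg)),
                                   dimnames = c(list(NULL), dimnames(emg)))
  stopifnot(length(dim(emg)) == 3L)
  .check_finite(emg, "raw EMG")
  n_trials <- dim(emg)[1L]; n_muscles <- dim(emg)[2L]
  T_out <- n_samples %/% window
  env <- array(0, dim = c(n_trials, n_muscles, T_out),
               dimnames = list(NULL, dimnames(emg)[[2L]], NULL))
  for (tr in seq_len(n_trials)) {
    for (m in seq_len(n_muscles)) {
      s <- full_wave_rectify(emg[tr, m, ])
      s <- lowpass_zero_phase(s, sampling_rate, cutoff_hz, order)
      s <- time_normalize(s, n_samples)
      # filtering of a rectified signal can dip below zero near sharp edges;
      # envelopes are non-negative by definition
      env[tr, m, ] <- pmax(0, integrate_windows(s, window))
    }
  }
  processed_emg(env, provenance = list(
    steps = .canonical_steps, sampling_rate = sampling_rate,
    cutoff_hz = cutoff_hz, order = order, n_samples = n_samples,
    window = window))
}

#' Construct a processed-EMG envelope object
#'
#' @param envelope non-negative array `trials x muscles x timepoints`.
#' @param provenance list describing how the envelope was produced.
#' @return a `processed_emg` object.
#' @export
processed_emg <- function(envelope, provenance = list(steps = "external")) {
  stopifnot(is.array(envelope), length(dim(envelope)) == 3L)
  .check_finite(envelope, "envelope")
  if (any(envelope < 0)) stop("envelope must be non-negative", call. = FALSE)
  structure(envelope, provenance = provenance, class = "processed_emg")
}

#' @export
print.processed_emg <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<processed_emg: %d trials x %d muscles x %d timepoints>\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}
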