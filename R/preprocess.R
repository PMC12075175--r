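#' Filter chain specification
#'
#' Software emulation of the acquisition front end: a Butterworth band-pass
#' (30--350 Hz, prototype order 2) followed by a power-line notch (50 or
#' 60 Hz biquad). The notch bandwidth is set through its quality factor Q
#' (default 30, about 1.7 Hz at 50 Hz).
#'
#' @param band Hz pair, band-pass corner frequencies.
#' @param band_order Butterworth prototype order per edge.
#' @param notch_hz power-line frequency, 50 or 60.
#' @param notch_q notch quality factor.
#' @param fs sampling rate the filters are designed for, Hz.
#' @return object of class \code{emg_filter_spec}.
#' @export
filter_spec <- function(band = c(30, 350), band_order = 2, notch_hz = 50,
                        notch_q = 30, fs = 1067) {
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("band infeasible: need 0 < low < high < fs/2")
  if (!notch_hz %in% c(50, 60)) stop("notch_hz must be 50 or 60")
  if (notch_hz >= fs / 2) stop("notch frequency above Nyquist")
  structure(list(band = band, band_order = band_order, notch_hz = notch_hz,
                 notch_q = notch_q, fs = fs), class = "emg_filter_spec")
}

# RBJ audio-EQ-cookbook notch biquad
.notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

#' Apply the band-pass + notch chain to a recording
#'
#' Each channel is filtered independently. The default is forward-backward
#' (zero-phase) filtering, appropriate for offline analysis; set
#' \code{zero_phase = FALSE} for a causal single pass matching a streaming
#' front end. The mode used is recorded in the output metadata.
#'
#' @param rec an \code{\link{emg_recording}}.
#' @param spec a \code{\link{filter_spec}}; its \code{fs} must match the
#'   recording.
#' @param zero_phase logical.
#' @return filtered \code{\link{emg_recording}} of identical shape.
#' @export
apply_filter_chain <- function(rec, spec = filter_spec(fs = rec$fs),
                               zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "emg_filter_spec"))
  if (abs(spec$fs - rec$fs) > 1e-9)
    stop("filter spec designed for a different sampling rate")
  bp <- signal::butter(spec$band_order, spec$band / (spec$fs / 2),
                       type = "pass")
  nc <- .notch_coefs(spec$notch_hz, spec$fs, spec$notch_q)
  run <- function(x) {
    if (zero_phase) {
      x <- signal::filtfilt(bp, x)
      signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), x)
    } else {
      x <- signal::filter(bp, x)
      as.numeric(signal::filter(signal::Arma(b = nc$b, a = nc$a), x))
    }
  }
  out <- apply(rec$data, 2, run)
  emg_recording(out, fs = rec$fs, labels = rec$labels,
                channel_map = rec$channel_map,
                meta = c(rec$meta, list(
                  filtered = list(band = spec$band,
                                  band_order = spec$band_order,
                                  notch_hz = spec$notch_hz,
                                  zero_phase = zero_phase))))
}

#' Overlapping analysis window specification
#'
#' Milliseconds are converted to sample counts with
#' \code{round(ms * fs / 1000)}; the defaults give 300-sample windows with a
#' 10-sample step at 1,067 Hz (281.1 ms / 9.3 ms).
#'
#' @param length_ms window length, ms.
#' @param step_ms increment between window starts, ms.
#' @param fs sampling rate, Hz.
#' @param length_samples,step_samples direct sample counts, overriding the
#'   millisecond values when given.
#' @return object of class \code{emg_window_spec} with fields
#'   \code{length_samples} and \code{step_samples}.
#' @export
window_spec <- function(length_ms = 281.1, step_ms = 9.3, fs = 1067,
                        length_samples = NULL, step_samples = NULL) {
  L <- if (is.null(length_samples)) round(length_ms * fs / 1000)
       else as.integer(length_samples)
  S <- if (is.null(step_samples)) round(step_ms * fs / 1000)
       else as.integer(step_samples)
  if (S < 1L) stop("step must be at least one sample")
  if (L <= S) stop("window length must exceed the step (overlapping scheme)")
  structure(list(length_ms = length_ms, step_ms = step_ms, fs = fs,
                 length_samples = as.integer(L), step_samples = as.integer(S)),
            class = "emg_window_spec")
}

#' Overlapping window index list
#'
#' @param n_samples recording length in samples (an
#'   \code{\link{emg_recording}} is also accepted).
#' @param spec an \code{\link{emg_window_spec}}.
#' @return data frame of half-open windows: columns \code{start} (1-based)
#'   and \code{end} (exclusive); each window is
#'   \code{start:(end - 1)}, \code{spec$length_samples} long. The number of
#'   rows is \code{floor((n - L) / S) + 1}.
#' @export
segment_windows <- function(n_samples, spec) {
  stopifnot(inherits(spec, "emg_window_spec"))
  if (inherits(n_samples, "emg_recording")) n_samples <- nrow(n_samples$data)
  n_samples <- as.integer(n_samples)
  L <- spec$length_samples; S <- spec$step_samples
  if (n_samples < L)
    stop("recording shorter than one analysis window")
  start <- seq.int(1L, n_samples - L + 1L, by = S)
  data.frame(start = start, end = start + L)
}
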