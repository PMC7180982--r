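#' Power-line notch filter (zero-phase)
#'
#' The only preprocessing applied to EEG before feature extraction: a
#' second-order IIR notch at the mains frequency, run forward-backward
#' (zero phase). No detrending or artifact rejection is performed anywhere
#' in the pipeline. The default quality factor Q = 30 gives a -3 dB notch
#' width of 2 Hz at 60 Hz, leaving the 35-80 Hz analysis band essentially
#' untouched beyond +/-3 Hz of the mains line.
#'
#' Biquad coefficients follow the standard constrained-poles-and-zeros
#' notch design: zeros on the unit circle at the notch frequency, poles at
#' radius set by the bandwidth `f0/Q`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f0 Notch center frequency in Hz (default 60; use 50 in 50 Hz
#'   mains regions). Must satisfy `0 < f0 < fs/2`.
#' @param Q Quality factor `f0 / bandwidth` (default 30).
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 60, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) {
    stop(sprintf("notch frequency %g Hz must lie in (0, %g) Hz", f0, fs / 2))
  }
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))
}

#' Low-passed version of a recording
#'
#' Emulates the clinically exported signal in which EEG high-frequency
#' content is removed by a 50 Hz low-pass: every EEG channel is filtered
#' with a zero-phase Butterworth low-pass; the EMG channel (if present) is
#' passed through unchanged, since only the EEG export was filtered.
#'
#' @param rec A [recording()].
#' @param cutoff Low-pass corner in Hz (default 50); must be below Nyquist.
#' @param order Butterworth order (default 6; the forward-backward pass
#'   doubles the effective order).
#' @param emg_channel Name of the EMG channel to leave untouched
#'   (default `"EMG"`).
#' @return A [recording()] with filtered EEG channels.
#' @export
lowpass_version <- function(rec, cutoff = 50, order = 6, emg_channel = "EMG") {
  stopifnot(inherits(rec, "recording"))
  if (cutoff >= rec$fs / 2) {
    stop(sprintf("cutoff %g Hz must be below Nyquist (%g Hz)", cutoff, rec$fs / 2))
  }
  bt <- signal::butter(order, cutoff / (rec$fs / 2), type = "low")
  out <- rec
  for (ch in names(rec$channels)) {
    if (identical(ch, emg_channel)) next
    out$channels[[ch]] <- as.numeric(signal::filtfilt(bt, rec$channels[[ch]]))
  }
  out
}
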