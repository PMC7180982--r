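#' Frequency bands used in the spectral analyses
#'
#' `analysis_bands()` are the six bands of the EEG-EMG correlation study;
#' `classifier_bands()` are the three high-frequency bands appended to the
#' scattering features for staging unfiltered EEG. Bands are half-open
#' `[low, high)` intervals in Hz, which prevents double counting at shared
#' edges (80 Hz, 150 Hz) and makes `(80,250)` exactly the sum of its two
#' sub-bands on a shared frequency grid.
#'
#' @return A list of `c(low, high)` pairs.
#' @export
analysis_bands <- function() {
  list(c(0.5, 15), c(15, 35), c(35, 80), c(80, 150), c(150, 250), c(80, 250))
}

#' @rdname analysis_bands
#' @export
classifier_bands <- function() {
  list(c(35, 80), c(80, 150), c(150, 250))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: Hamming windows of `window_sec` seconds
#' with 50% overlap. 2-s windows give 0.5 Hz resolution, matching the
#' coarsest band edge used in the analyses. The estimate is one-sided and
#' scaled so that `sum(psd) * df` approximates the mean signal power
#' (µV²); units are µV²/Hz.
#'
#' @param x Numeric signal (µV).
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds (default 2).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (µV²/Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  L <- as.integer(round(window_sec * fs))
  if (length(x) < L) {
    stop(sprintf("segment of %d samples is shorter than one %g-s Welch window",
                 length(x), window_sec))
  }
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hamming
  norm <- fs * sum(w^2)
  nb <- L %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- stats::fft(x[s:(s + L - 1L)] * w)[seq_len(nb)]
    acc <- acc + (Re(X)^2 + Im(X)^2)
  }
  psd <- acc / (length(starts) * norm)
  # fold negative frequencies into the one-sided estimate
  if (L %% 2L == 0L) {
    psd[2:(nb - 1L)] <- 2 * psd[2:(nb - 1L)]
  } else {
    psd[2:nb] <- 2 * psd[2:nb]
  }
  list(freq = (seq_len(nb) - 1L) * fs / L, psd = psd)
}

#' Spectral energy of a segment in a frequency band
#'
#' Sum of the Welch PSD over frequency bins in the half-open interval
#' `[low, high)`, times the bin width — the per-epoch quantity whose
#' EEG-EMG correlation is studied, in µV² (power integrated over the band,
#' i.e. the segment's mean-power contribution of the band).
#'
#' @param x 30-s sample segment (any length >= one Welch window works).
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz, within `[0, fs/2]`.
#' @param psd Optional precomputed [welch_psd()] result for `x`, to share
#'   one estimate across several bands.
#' @return Band energy in µV² (non-negative).
#' @export
band_energy <- function(x, fs, band, psd = NULL) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[1] < 0 || band[2] > fs / 2 + 1e-9) {
    stop(sprintf("band (%g, %g) Hz outside [0, %g] Hz", band[1], band[2], fs / 2))
  }
  if (is.null(psd)) psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  sum(psd$psd[sel]) * df
}

#' Log band-energy feature vector of a 30-s epoch
#'
#' `log10(band_energy + eps)` for each band, with `eps = 1e-12` µV² so
#' zero-signal epochs stay finite for the downstream CCA/SVM. Band
#' features are computed on the current 30-s epoch only, not the 90-s
#' scattering context.
#'
#' @param x 30-s sample segment.
#' @param fs Sampling rate in Hz.
#' @param bands List of bands; default [classifier_bands()].
#' @param eps Additive floor in µV² (default 1e-12).
#' @return Numeric vector, one log10 energy per band.
#' @export
stft_features <- function(x, fs, bands = classifier_bands(), eps = 1e-12) {
  psd <- welch_psd(x, fs)
  vapply(bands, function(b) log10(band_energy(x, fs, b, psd = psd) + eps), 0)
}
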