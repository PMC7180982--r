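#' Stage-dependent spectral model for synthetic polysomnography
#'
#' Describes, per sleep stage, the EEG base-band power spectral density
#' profile, the chin-EMG tone amplitude, and how much of the EMG process
#' leaks into the EEG channels above the leakage corner.
#'
#' The defaults encode standard sleep physiology: slow-wave (delta) power
#' grows from Awake through N3; alpha is prominent in relaxed wake; REM and
#' N1 share an identical EEG profile (mixed-frequency, low amplitude),
#' which is what makes them hard to separate from EEG alone. Muscle tone
#' separates them instead: the EMG amplitude is lowest in REM (atonia),
#' rises through N3/N2, and is clearly higher in N1 and Awake.
#'
#' The fifth EEG band (35-80 Hz) models genuine gamma-range brain
#' activity, at a common level across stages. It sits far above the leaked
#' EMG power, so muscle information in 35-80 Hz is masked by brain
#' activity and only the >80 Hz EEG content carries usable muscle tone —
#' the interference structure observed on real scalp recordings. A small broadband
#' background keeps every band's energy strictly positive.
#'
#' @param psd 5 x 5 matrix of PSD levels (µV²/Hz), rows in
#'   `stage_levels()` order, columns the EEG base bands
#'   (0.5-4, 4-8, 8-15, 15-35, 35-80 Hz).
#' @param sigma_emg Named numeric: EMG tone standard deviation per stage
#'   (µV). Must satisfy REM < N3 <= N2 < N1 < Awake.
#' @param leakage_gain Fraction `g >= 0` of the (high-passed) EMG process
#'   added into every EEG channel.
#' @param leak_highpass_hz Corner of the leakage shaping high-pass
#'   (default 35 Hz): EMG content below the corner is attenuated in EEG,
#'   reproducing that 25-80 Hz muscle activity is captured less well than
#'   >80 Hz.
#' @param emg_band Spectral support of the EMG process in Hz
#'   (default (25, 250)).
#' @param background_psd Flat EEG background level (µV²/Hz) above the
#'   gamma band (80 Hz to Nyquist), default 0.05.
#' @return A `stage_spectrum_model` list.
#' @export
stage_spectrum_model <- function(
    psd = matrix(c(10,  5, 20, 5, 1.2,   # Awake
                   20, 10,  5, 3, 1.2,   # REM
                   20, 10,  5, 3, 1.2,   # N1 (same EEG profile as REM)
                   60, 15,  8, 3, 1.2,   # N2
                  150, 20,  5, 2, 1.2),  # N3
                 nrow = 5, byrow = TRUE,
                 dimnames = list(stage_levels(),
                                 c("0.5-4", "4-8", "8-15", "15-35", "35-80"))),
    sigma_emg = c(Awake = 30, REM = 2, N1 = 15, N2 = 8, N3 = 5),
    leakage_gain = 0.3,
    leak_highpass_hz = 35,
    emg_band = c(25, 250),
    background_psd = 0.05) {
  stopifnot(is.matrix(psd), nrow(psd) == 5, ncol(psd) == 5, all(psd >= 0),
            all(sigma_emg >= 0), leakage_gain >= 0, background_psd >= 0)
  sigma_emg <- sigma_emg[stage_levels()]
  if (!(sigma_emg["REM"] < sigma_emg["N3"] &&
        sigma_emg["N3"] <= sigma_emg["N2"] &&
        sigma_emg["N2"] < sigma_emg["N1"] &&
        sigma_emg["N1"] < sigma_emg["Awake"])) {
    stop("sigma_emg must satisfy REM < N3 <= N2 < N1 < Awake (atonia in REM)")
  }
  structure(list(psd = psd, sigma_emg = sigma_emg,
                 leakage_gain = leakage_gain,
                 leak_highpass_hz = leak_highpass_hz,
                 emg_band = emg_band, background_psd = background_psd,
                 eeg_bands = list(c(0.5, 4), c(4, 8), c(8, 15), c(15, 35),
                                  c(35, 80))),
            class = "stage_spectrum_model")
}

#' Markov transition model for hypnogram simulation
#'
#' @param P 5 x 5 row-stochastic matrix over `stage_levels()` order.
#' @param init Initial stage distribution (default: the chain's stationary
#'   distribution if available, else uniform).
#' @return A `transition_model` list.
#' @export
transition_model <- function(P, init = NULL) {
  if (!is.matrix(P) || any(dim(P) != 5) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("P must be a 5x5 matrix with nonnegative entries and rows summing to 1 (within 1e-12)")
  }
  if (is.null(init)) {
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    init <- abs(v) / sum(abs(v))
  }
  stopifnot(length(init) == 5, all(init >= 0), abs(sum(init) - 1) < 1e-9)
  dimnames(P) <- list(stage_levels(), stage_levels())
  structure(list(P = P, init = as.numeric(init)), class = "transition_model")
}

#' Default sleep-architecture transition model
#'
#' Stage persistence 0.85 per 30-s epoch with re-draws from the overall
#' stage distribution (Awake 27%, REM 9%, N1 11%, N2 48%, N3 5%), which is
#' therefore the chain's exact stationary distribution. The proportions
#' match a typical clinical night with a large Awake/N2 share and rare
#' N1/N3.
#'
#' @param persistence Self-transition weight (default 0.85).
#' @param pi Stationary stage distribution.
#' @return A [transition_model()].
#' @export
sleep_transition_model <- function(persistence = 0.85,
                                   pi = c(Awake = 0.27, REM = 0.09,
                                          N1 = 0.11, N2 = 0.48, N3 = 0.05)) {
  stopifnot(persistence >= 0, persistence < 1, abs(sum(pi) - 1) < 1e-9)
  P <- persistence * diag(5) + (1 - persistence) * matrix(pi, 5, 5, byrow = TRUE)
  transition_model(P, init = as.numeric(pi))
}

#' Simulate a hypnogram from a Markov chain
#'
#' @param n_epochs Number of 30-s epochs (>= 1).
#' @param model A [transition_model()]; default [sleep_transition_model()].
#' @param seed Integer RNG seed; identical seeds give identical sequences.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(n_epochs, model = sleep_transition_model(),
                               seed = 1) {
  stopifnot(inherits(model, "transition_model"), n_epochs >= 1)
  set.seed(seed)
  s <- integer(n_epochs)
  s[1] <- sample.int(5, 1, prob = model$init)
  for (e in seq_len(n_epochs - 1L)) {
    s[e + 1L] <- sample.int(5, 1, prob = model$P[s[e], ])
  }
  hypnogram(stage_levels()[s])
}

# stationary unit-variance Gaussian noise band-limited to [lo, hi] Hz,
# built in the frequency domain (exact spectral support)
band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                    # alias to [0, fs/2]
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# unit-variance band components of ONE white noise realization on disjoint
# bands (disjoint spectral supports of a common white process are
# independent, so one forward FFT serves all bands)
multi_band_noise <- function(n, fs, bands) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  lapply(bands, function(b) {
    Xb <- X
    Xb[f < b[1] | f >= b[2]] <- 0
    y <- Re(stats::fft(Xb, inverse = TRUE)) / n
    y / stats::sd(y)
  })
}

# per-sample gain envelope from per-epoch values, with cosine cross-fades
# of `fade_sec` centered on each epoch boundary (avoids spectral splatter
# from abrupt amplitude steps)
stage_envelope <- function(values, spe, fs, fade_sec = 0.5) {
  env <- rep(values, each = spe)
  hw <- as.integer(round(fade_sec * fs / 2))   # half-width in samples
  if (hw < 1L || length(values) < 2L) return(env)
  ramp <- 0.5 * (1 - cos(pi * seq_len(2L * hw) / (2L * hw + 1L)))
  for (e in which(diff(values) != 0)) {
    b <- e * spe                               # boundary sample index
    idx <- (b - hw + 1L):(b + hw)
    env[idx] <- values[e] + (values[e + 1L] - values[e]) * ramp
  }
  env
}

#' Simulate a polysomnography recording for a hypnogram
#'
#' Per stage, each EEG channel is band-shaped Gaussian noise following the
#' model's PSD profile (piecewise-flat spectrum over the four base bands
#' plus a broadband background), with stage transitions cross-faded over
#' 0.5 s. A single band-limited EMG process drives both the EMG channel
#' (scaled by the stage's tone amplitude) and — after high-pass shaping at
#' the leakage corner and scaling by the leakage gain — an additive
#' component in every EEG channel. Because all channels share one EMG
#' realization, per-epoch EEG and EMG high-band energies are correlated by
#' construction whenever the gain is positive.
#'
#' @param hyp A [hypnogram()].
#' @param model A [stage_spectrum_model()].
#' @param fs Sampling rate in Hz (default 500); must resolve the EMG band.
#' @param channels EEG channel names (default C3-A2 and O2-A1).
#' @param seed Integer RNG seed; output is deterministic given
#'   (seed, parameters).
#' @param subject_id Subject label for the returned recording.
#' @return A [recording()] with the EEG channels plus an `"EMG"` channel.
#' @export
simulate_recording <- function(hyp, model = stage_spectrum_model(), fs = 500,
                               channels = c("C3-A2", "O2-A1"), seed = 1,
                               subject_id = "S1") {
  stopifnot(inherits(hyp, "hypnogram"), inherits(model, "stage_spectrum_model"))
  if (model$emg_band[2] > fs / 2) {
    stop(sprintf("fs = %g Hz cannot represent the EMG band up to %g Hz",
                 fs, model$emg_band[2]))
  }
  set.seed(seed)
  spe <- as.integer(round(fs * EPOCH_SEC))
  n <- length(hyp) * spe
  st <- as.integer(hyp)                     # 1..5 in stage_levels() order

  # shared EMG process: unit-variance band noise and its high-passed
  # version for leakage shaping (4th-order Butterworth magnitude)
  w <- band_noise(n, fs, model$emg_band[1], model$emg_band[2])
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  r4 <- (f / model$leak_highpass_hz)^4
  W <- W * r4 / sqrt(1 + r4^2)
  w_hp <- Re(stats::fft(W, inverse = TRUE)) / n

  sig_env <- stage_envelope(as.numeric(model$sigma_emg[st]), spe, fs)
  emg <- sig_env * w
  leak <- model$leakage_gain * sig_env * w_hp

  out <- vector("list", length(channels) + 1L)
  names(out) <- c(channels, "EMG")
  # disjoint bands: the five stage-profile bands plus a flat broadband
  # floor above the gamma band (keeps >80 Hz EEG energy positive at g = 0)
  nb <- length(model$eeg_bands)
  bands <- c(model$eeg_bands, list(c(model$eeg_bands[[nb]][2], fs / 2)))
  # per-band amplitude envelopes: sqrt of stage band variance (PSD x width)
  amp <- lapply(seq_along(bands), function(b) {
    w <- bands[[b]][2] - bands[[b]][1]
    v <- if (b <= nb) model$psd[, b] * w else rep(model$background_psd * w, 5)
    stage_envelope(sqrt(v)[st], spe, fs)
  })
  for (ch in channels) {
    comps <- multi_band_noise(n, fs, bands)
    x <- numeric(n)
    for (b in seq_along(bands)) x <- x + amp[[b]] * comps[[b]]
    out[[ch]] <- x + leak
  }
  out[["EMG"]] <- emg
  recording(out, fs = fs, subject_id = subject_id)
}

#' Simulate a cohort of subjects
#'
#' Convenience wrapper generating `n_subjects` independent nights with one
#' shared model; per-subject seeds are derived from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param n_epochs Epochs per subject (default 720, a ~6 h night).
#' @param model A [stage_spectrum_model()].
#' @param tm A [transition_model()].
#' @param fs Sampling rate (default 500).
#' @param channels EEG channel names.
#' @param seed Base seed.
#' @return List of `list(recording =, hypnogram =)` per subject.
#' @export
simulate_cohort <- function(n_subjects, n_epochs = 720,
                            model = stage_spectrum_model(),
                            tm = sleep_transition_model(), fs = 500,
                            channels = c("C3-A2", "O2-A1"), seed = 1) {
  sub_seed <- function(i) {
    as.integer((as.numeric(seed) * 1000 + i) %% 2147483629)
  }
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    hyp <- simulate_hypnogram(n_epochs, tm, seed = sub_seed(i))
    rec <- simulate_recording(hyp, model, fs = fs, channels = channels,
                              seed = sub_seed(500L + i), subject_id = sid)
    list(recording = rec, hypnogram = hyp)
  })
}
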