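#' Scattering transform configuration
#'
#' Settings of the order-2 wavelet scattering transform applied to 90-s EEG
#' context windows. First-layer filters are analytic Gaussian (Morlet-type)
#' band-passes, `Q1` per octave over `J` octaves descending from Nyquist;
#' the second layer uses `Q2` filters per octave. Output coefficients are
#' globally averaged over the window (one feature vector per window) and,
#' by default, log-transformed with an additive floor.
#'
#' @param Q1 First-layer filters per octave (default 8).
#' @param Q2 Second-layer filters per octave (default 1).
#' @param J Number of octaves below Nyquist (default 10; at 500 Hz this
#'   reaches ~0.26 Hz).
#' @param max_order 1 or 2 (default 2).
#' @param log_transform Apply `log(coef + eps)` (default `TRUE`).
#' @param eps Additive floor for the log (default 1e-12).
#' @param support_sigmas Spectral support kept per filter, in standard
#'   deviations of its Gaussian profile (default 4.5).
#' @param decim_margin Envelope oversampling margin: after each modulus the
#'   envelope is subsampled to at least `decim_margin` samples per filter
#'   bandwidth sigma (default 10; larger = closer to the full-resolution
#'   computation, slower).
#' @param decim_margin2 Margin for the second-layer outputs, relative to
#'   the effective bandwidth `min(sigma2, 3 * sigma1)` of the cascaded
#'   envelope (default 5).
#' @param taper_sec Cosine ramp length applied to each end of the window
#'   before the FFT, suppressing periodic wrap-around (default 1 s).
#' @return A `scattering_config` list.
#' @export
scattering_config <- function(Q1 = 8, Q2 = 1, J = 10, max_order = 2,
                              log_transform = TRUE, eps = 1e-12,
                              support_sigmas = 4.5, decim_margin = 10,
                              decim_margin2 = 5, taper_sec = 1) {
  stopifnot(Q1 >= 1, Q2 >= 1, J >= 1, max_order %in% c(1L, 2L))
  structure(list(Q1 = Q1, Q2 = Q2, J = J, max_order = as.integer(max_order),
                 log_transform = log_transform, eps = eps,
                 support_sigmas = support_sigmas,
                 decim_margin = decim_margin, decim_margin2 = decim_margin2,
                 taper_sec = taper_sec),
            class = "scattering_config")
}

# relative bandwidth sigma/fc for Q filters per octave: adjacent filters
# (ratio 2^(1/Q)) cross at half power; capped so second-layer (Q=1)
# filters keep negligible DC gain.
sigma_ratio <- function(Q) min(0.35, (2^(1 / (2 * Q)) - 1) / sqrt(log(2)))

# center frequencies of a bank descending geometrically from Nyquist
bank_centers <- function(fs, Q, J) {
  (fs / 2) * 2^(-(seq_len(Q * J) - 1) / Q)
}

divisors_of <- function(n) {
  d <- seq_len(n)
  d[n %% d == 0L]
}

# smallest divisor of n that is >= target (n itself is always a divisor)
pick_M <- function(divs, target) {
  divs[which(divs >= min(target, divs[length(divs)]))[1]]
}

# Gaussian filter on the global frequency grid: support bins and gains.
# Bins are 0-based; support clipped to [0, n/2] (analytic: no negative
# frequencies touched).
gauss_filter <- function(fc, sigma, df, n_half, support_sigmas) {
  lo <- max(0L, as.integer(ceiling((fc - support_sigmas * sigma) / df)))
  hi <- min(n_half, as.integer(floor((fc + support_sigmas * sigma) / df)))
  if (hi < lo) return(NULL)
  f <- (lo:hi) * df
  list(a = lo, h = exp(-(f - fc)^2 / (2 * sigma^2)))
}

#' Build the scattering filter bank for a given window length
#'
#' Constructs the frequency-domain filter bank: `Q1 * J` analytic Gaussian
#' band-passes plus a complementary low-pass, normalized so the
#' Littlewood-Paley sum `sum(|psi|^2) + |phi|^2` has maximum 1 on the
#' positive frequency axis (frame property; the infimum over the axis stays
#' within the documented deviation `delta <= 0.2`). The low-pass is the
#' exact spectral complement of the band-pass sum below the lowest filter
#' center, so coverage has no gap near DC. Each filter also carries its
#' envelope subsampling length `M` (a divisor of `n`) and, per first-layer
#' filter, the second-layer filters admissible under the rule
#' center(second) < center(first).
#'
#' @param config A [scattering_config()].
#' @param fs Sampling rate in Hz.
#' @param n Window length in samples; must satisfy `n >= 2^J`.
#' @return A `scattering_bank` list with elements `filters1`, `bank2`
#'   (per-first-layer lists of second-layer filters), `phi0` (low-pass DC
#'   gain), `fc1`, `fc2`, `pairs`, and grid metadata.
#' @export
build_filter_bank <- function(config, fs, n) {
  stopifnot(inherits(config, "scattering_config"))
  n <- as.integer(n)
  if (n < 2^config$J) {
    stop(sprintf("window of %d samples is too short for J = %d octaves; use a smaller J",
                 n, config$J))
  }
  df <- fs / n
  n_half <- n %/% 2L
  divs <- divisors_of(n)
  ss <- config$support_sigmas
  margin <- config$decim_margin

  fc1 <- bank_centers(fs, config$Q1, config$J)
  r1 <- sigma_ratio(config$Q1)
  filters1 <- vector("list", length(fc1))
  # Littlewood-Paley sum of the first-layer band-passes on the half grid
  lp <- numeric(n_half + 1L)
  for (k in seq_along(fc1)) {
    g <- gauss_filter(fc1[k], r1 * fc1[k], df, n_half, ss)
    if (is.null(g)) stop("empty filter support; J too large for this fs/n")
    M <- pick_M(divs, max(64, ceiling(margin * r1 * fc1[k] / df)))
    filters1[[k]] <- list(a = g$a, h = g$h, M = as.integer(M), fc = fc1[k])
    idx <- g$a + seq_along(g$h)            # 1-based bin index on half grid
    lp[idx] <- lp[idx] + g$h^2
  }
  A <- max(lp)
  # complementary low-pass: fills the spectrum below the lowest filter
  # center so the frame sum is exactly flat there
  knee_bin <- as.integer(floor(fc1[length(fc1)] * 2^(1 / config$Q1) / df))
  phi2 <- numeric(n_half + 1L)
  jj <- seq_len(min(knee_bin + 1L, n_half + 1L))
  phi2[jj] <- pmax(0, A - lp[jj])
  phi_h <- sqrt(phi2)
  # normalize the whole bank to Littlewood-Paley max 1
  sA <- sqrt(A)
  for (k in seq_along(filters1)) filters1[[k]]$h <- filters1[[k]]$h / sA
  phi_h <- phi_h / sA

  # second-layer prototype bank (Q2 per octave), own normalization <= 1
  fc2 <- bank_centers(fs, config$Q2, config$J)
  r2 <- sigma_ratio(config$Q2)
  lp2 <- numeric(n_half + 1L)
  proto2 <- vector("list", length(fc2))
  for (j in seq_along(fc2)) {
    g <- gauss_filter(fc2[j], r2 * fc2[j], df, n_half, ss)
    proto2[[j]] <- g
    idx <- g$a + seq_along(g$h)
    lp2[idx] <- lp2[idx] + g$h^2
  }
  sA2 <- sqrt(max(lp2))

  # admissible (first, second) pairs: center(second) < center(first);
  # second-layer filters are re-cut to each first-layer envelope grid M1
  pairs <- vector("list", length(fc1))
  bank2 <- vector("list", length(fc1))
  for (k in seq_along(fc1)) {
    adm <- which(fc2 < fc1[k])
    pairs[[k]] <- adm
    l2 <- vector("list", length(adm))
    M1 <- filters1[[k]]$M
    divs1 <- divisors_of(M1)
    for (i in seq_along(adm)) {
      j <- adm[i]
      g <- proto2[[j]]
      # keep only support below the envelope grid's Nyquist
      keep <- (g$a + seq_along(g$h) - 1L) < M1 %/% 2L
      sig_eff <- min(r2 * fc2[j], 3 * r1 * fc1[k])
      M2 <- pick_M(divs1, max(64, ceiling(config$decim_margin2 * sig_eff / df)))
      l2[[i]] <- list(a = g$a, h = g$h[keep] / sA2, M = as.integer(M2),
                      fc = fc2[j])
    }
    bank2[[k]] <- l2
  }

  structure(list(fs = fs, n = n, df = df,
                 filters1 = filters1, bank2 = bank2,
                 phi_h = phi_h, phi0 = phi_h[1],
                 lp = (lp + phi2) / A,
                 fc1 = fc1, fc2 = fc2, pairs = pairs,
                 config = config),
            class = "scattering_bank")
}

#' Littlewood-Paley sum of a filter bank
#'
#' The normalized frame sum `sum(|psi|^2) + |phi|^2` evaluated on the
#' positive-frequency bin grid, for inspecting the frame property.
#'
#' @param bank A [build_filter_bank()] result.
#' @return List with `freq` (Hz) and `lp` (dimensionless, max 1).
#' @export
littlewood_paley <- function(bank) {
  stopifnot(inherits(bank, "scattering_bank"))
  list(freq = (seq_along(bank$lp) - 1L) * bank$df, lp = bank$lp)
}

# bank cache: building a 45000-sample bank takes a moment, reuse across
# windows of one run
.scat_cache <- new.env(parent = emptyenv())

scat_bank_cached <- function(config, fs, n) {
  key <- paste(fs, n, config$Q1, config$Q2, config$J, config$support_sigmas,
               config$decim_margin, config$decim_margin2, sep = "|")
  b <- .scat_cache[[key]]
  if (is.null(b)) {
    b <- build_filter_bank(config, fs, n)
    .scat_cache[[key]] <- b
  }
  b
}

#' Number of scattering coefficients for a configuration
#'
#' `1 + Q1*J` order-0/1 coefficients plus one order-2 coefficient per
#' admissible filter pair (second-layer center below first-layer center).
#' A pure function of the configuration and sampling rate, equal to the
#' length of [scattering_transform()] output.
#'
#' @param config A [scattering_config()].
#' @param fs Sampling rate in Hz (the pair count depends only on center
#'   frequency ratios, fixed by `Q1`, `Q2`, `J`).
#' @return Integer feature count.
#' @export
scattering_feature_length <- function(config, fs = 500) {
  stopifnot(inherits(config, "scattering_config"))
  n1 <- as.integer(config$Q1 * config$J)
  if (config$max_order < 2L) return(1L + n1)
  fc1 <- bank_centers(fs, config$Q1, config$J)
  fc2 <- bank_centers(fs, config$Q2, config$J)
  1L + n1 + sum(vapply(fc1, function(f) sum(fc2 < f), 0L))
}

#' Order-2 scattering transform of a 90-s window
#'
#' Computes the globally averaged scattering coefficients of one window:
#' order 0 is the averaged low-passed input; order 1 is the window mean of
#' each filter's envelope `|x * psi|`; order 2 cascades a second
#' filter-modulus stage, restricted to second-layer centers below the
#' first-layer center. The window is tapered with cosine ramps before the
#' FFT. Coefficients are returned in a fixed layout: `S0`, then order-1 by
#' descending center frequency, then order-2 by (first-layer index,
#' second-layer index), with names recording the center frequencies.
#'
#' @param x Numeric window (typically `90 * fs` samples); all finite.
#' @param config A [scattering_config()].
#' @param fs Sampling rate in Hz.
#' @return Named numeric feature vector (log-transformed if configured).
#' @export
scattering_transform <- function(x, config = scattering_config(), fs = 500) {
  if (!all(is.finite(x))) stop("non-finite samples in scattering input")
  n <- length(x)
  bank <- scat_bank_cached(config, fs, n)

  nt <- as.integer(round(config$taper_sec * fs))
  if (nt > 1 && 2 * nt < n) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 1) / nt))
    x[seq_len(nt)] <- x[seq_len(nt)] * ramp
    x[n - seq_len(nt) + 1L] <- x[n - seq_len(nt) + 1L] * ramp
  }

  res <- scatter_window_cpp(x, bank$filters1, bank$bank2, config$max_order)
  s0 <- abs(bank$phi0 * mean(x))
  out <- c(s0, as.numeric(res$S1),
           if (config$max_order >= 2L) as.numeric(res$S2))

  nm <- c("S0", sprintf("S1_%0.4g", bank$fc1))
  if (config$max_order >= 2L) {
    for (k in seq_along(bank$fc1)) {
      adm <- bank$pairs[[k]]
      if (length(adm)) {
        nm <- c(nm, sprintf("S2_%0.4g_%0.4g", bank$fc1[k], bank$fc2[adm]))
      }
    }
  }
  names(out) <- nm
  if (config$log_transform) out <- log(out + config$eps)
  out
}
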