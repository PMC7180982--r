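#' Pooled per-stage EEG and EMG band energies
#'
#' For one EEG channel, one frequency band and one stage group, collects
#' the per-epoch band energies of the EEG channel and of the EMG channel
#' over all qualifying epochs of all subjects, in matching order — the
#' paired vectors whose Pearson correlation quantifies how much muscle
#' tone information the EEG band carries.
#'
#' @param cohort List of `list(recording =, hypnogram =)` pairs; every
#'   recording must contain `eeg_channel` and the EMG channel.
#' @param eeg_channel EEG channel name.
#' @param band `c(low, high)` Hz.
#' @param group One stage name or `"All"`.
#' @param log Return `log10(energy + eps)` (default `TRUE`, matching the
#'   logarithmic energies of the agreement analyses).
#' @param emg_channel EMG channel name (default `"EMG"`).
#' @param eps Log floor (default 1e-12).
#' @return List with numeric vectors `eeg` and `emg` (equal length) and
#'   `n`.
#' @export
pooled_energies <- function(cohort, eeg_channel, band, group = "All",
                            log = TRUE, emg_channel = "EMG", eps = 1e-12) {
  stopifnot(group %in% c(stage_levels(), "All"))
  eeg <- emg <- numeric(0)
  for (su in cohort) {
    rec <- su$recording; hyp <- su$hypnogram
    if (!emg_channel %in% names(rec$channels)) {
      stop("recording '", rec$subject_id, "' has no EMG channel")
    }
    check_alignment(rec, hyp)
    keep <- if (group == "All") rep(TRUE, length(hyp)) else hyp == group
    if (!any(keep)) next
    segs_eeg <- segment_epochs(rec, eeg_channel)
    segs_emg <- segment_epochs(rec, emg_channel)
    for (e in which(keep)) {
      eeg <- c(eeg, band_energy(segs_eeg[[e]], rec$fs, band))
      emg <- c(emg, band_energy(segs_emg[[e]], rec$fs, band))
    }
  }
  if (length(eeg) == 0L) {
    stop("no epochs in stage group '", group, "' across the cohort")
  }
  if (log) {
    eeg <- log10(eeg + eps); emg <- log10(emg + eps)
  }
  list(eeg = eeg, emg = emg, n = length(eeg))
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, length >= 3, each with
#'   nonzero variance.
#' @return The correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Two-sided permutation test for Pearson correlation
#'
#' Tests the null hypothesis that the paired energies are uncorrelated by
#' permuting `y` and recomputing `r`; the two-sided p-value uses the
#' add-one formula `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`,
#' which can never return 0. Deterministic given the seed.
#'
#' @param x,y As in [pearson_r()].
#' @param n_perm Number of permutations (>= 1). The analysis default is
#'   1e6; interactive work typically uses 1e3-1e4.
#' @param seed RNG seed.
#' @return List with `r` (observed), `p`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 1e6, seed = 1) {
  r_obs <- pearson_r(x, y)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  set.seed(seed)
  n <- length(x)
  xc <- (x - mean(x)) / (stats::sd(x) * (n - 1))
  yc <- y - mean(y)
  sy <- stats::sd(y)
  hits <- 0L
  block <- 2000L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    idx <- unlist(lapply(seq_len(b), function(i) sample.int(n)))
    P <- matrix(yc[idx], nrow = n)
    r_perm <- as.numeric(crossprod(xc, P)) / sy
    hits <- hits + sum(abs(r_perm) >= abs(r_obs))
    done <- done + b
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Bonferroni significance flags for a 36-cell correlation table
#'
#' The multiple-testing family is one channel's table: 6 bands x 6 stage
#' groups = 36 tests. A cell is flagged `"*"` when `p < alpha / 36` and
#' `"**"` when `p < 1e-5` (the stronger flag takes precedence). The cell
#' count is enforced so the correction denominator cannot silently drift.
#'
#' @param p_values Numeric vector of exactly 36 p-values.
#' @param alpha Family-wise level (default 0.05).
#' @return Character vector over `{"", "*", "**"}`.
#' @export
flag_significance <- function(p_values, alpha = 0.05) {
  if (length(p_values) != 36L) {
    stop("expected exactly 36 p-values (6 bands x 6 stage groups); got ",
         length(p_values))
  }
  ifelse(p_values < 1e-5, "**", ifelse(p_values < alpha / 36, "*", ""))
}

#' Bland-Altman agreement summary of two log-energy vectors
#'
#' Per epoch the mean `(x + y) / 2` and difference `x - y` of the two log
#' energies; the agreement interval is the empirical (2.5%, 97.5%)
#' quantile pair of the differences, using the linear-interpolation
#' quantile definition (R type 7).
#'
#' @param x_log,y_log Equal-length numeric vectors (length >= 2).
#' @return List with `mean`, `diff` (per point), and `interval`
#'   `c(lower, upper)`.
#' @export
bland_altman <- function(x_log, y_log) {
  if (length(x_log) != length(y_log)) stop("inputs differ in length")
  if (length(x_log) < 2L) stop("need at least 2 points")
  d <- x_log - y_log
  list(mean = (x_log + y_log) / 2, diff = d,
       interval = unname(stats::quantile(d, c(0.025, 0.975), type = 7)))
}

#' Full EEG-EMG correlation table for one channel
#'
#' The 6 bands x 6 stage-group table of pooled Pearson correlations with
#' permutation p-values and Bonferroni flags — the synthetic-data analogue
#' of the published per-channel correlation tables.
#'
#' @param cohort As in [pooled_energies()].
#' @param eeg_channel EEG channel name.
#' @param bands List of bands (default the six [analysis_bands()]).
#' @param n_perm Permutations per cell.
#' @param seed Base seed (each cell uses `seed + cell index`).
#' @param log Use log energies (default `TRUE`).
#' @return Data frame with columns band, group, n, r, p, flag.
#' @export
correlation_table <- function(cohort, eeg_channel, bands = analysis_bands(),
                              n_perm = 1e4, seed = 1, log = TRUE,
                              eps = 1e-12) {
  groups <- c(stage_levels(), "All")
  # one Welch PSD per epoch and channel, shared across all bands/groups
  stages <- character(0)
  E_eeg <- E_emg <- matrix(0, 0, length(bands))
  for (su in cohort) {
    rec <- su$recording
    check_alignment(rec, su$hypnogram)
    pe <- lapply(segment_epochs(rec, eeg_channel), welch_psd, fs = rec$fs)
    pm <- lapply(segment_epochs(rec, "EMG"), welch_psd, fs = rec$fs)
    eb <- function(psds) t(vapply(psds, function(p)
      vapply(bands, function(b) band_energy(numeric(0), rec$fs, b, psd = p), 0),
      numeric(length(bands))))
    E_eeg <- rbind(E_eeg, eb(pe))
    E_emg <- rbind(E_emg, eb(pm))
    stages <- c(stages, as.character(su$hypnogram))
  }
  if (log) {
    E_eeg <- log10(E_eeg + eps)
    E_emg <- log10(E_emg + eps)
  }
  rows <- list()
  i <- 0L
  for (bi in seq_along(bands)) for (g in groups) {
    i <- i + 1L
    keep <- if (g == "All") rep(TRUE, length(stages)) else stages == g
    if (!any(keep)) stop("no epochs in stage group '", g, "' across the cohort")
    pt <- permutation_test(E_eeg[keep, bi], E_emg[keep, bi],
                           n_perm = n_perm, seed = seed + i)
    rows[[i]] <- data.frame(band = sprintf("%g-%g", bands[[bi]][1],
                                           bands[[bi]][2]),
                            group = g, n = sum(keep), r = pt$r, p = pt$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$flag <- flag_significance(out$p)
  out
}
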