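#' Sleep stage labels
#'
#' Canonical 5-class stage order used throughout the package: Awake, REM,
#' N1, N2, N3. Confusion matrices, transition matrices and stage factors all
#' follow this order.
#'
#' @return Character vector of the five stage labels.
#' @export
stage_levels <- function() c("Awake", "REM", "N1", "N2", "N3")

#' Length of a scoring epoch in seconds
#' @keywords internal
EPOCH_SEC <- 30

# short codes used in hypnogram CSV files
stage_codes <- c(Awake = "W", REM = "R", N1 = "N1", N2 = "N2", N3 = "N3")

#' Polysomnography recording container
#'
#' A `recording` holds one or more equal-length channels sampled at a common
#' rate, in microvolts. Channels are named as in clinical montages
#' (e.g. "C3-A2", "O2-A1", "F3-A2", "EMG").
#'
#' @param channels Named list of equal-length numeric vectors (µV).
#' @param fs Sampling rate in Hz. `fs * 30` must be a whole number so 30-s
#'   epochs contain an integer number of samples.
#' @param subject_id Subject identifier string.
#' @param start_time Optional start timestamp (`POSIXct` or `NULL`).
#' @return An object of class `recording`.
#' @export
recording <- function(channels, fs, subject_id = "S1", start_time = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of numeric vectors")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must share the same length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar")
  }
  if (abs(fs * EPOCH_SEC - round(fs * EPOCH_SEC)) > 1e-9) {
    stop("fs * 30 must be an integer so 30-s epochs contain whole samples")
  }
  channels <- lapply(channels, as.numeric)
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         channels = channels, start_time = start_time),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channel(s) [%s], %.6g Hz, %.1f s\n",
              x$subject_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$fs, rec_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$channels[[1]]) / rec$fs
}

#' Number of complete 30-s epochs in a recording
#' @param rec A [recording()].
#' @return Integer epoch count (trailing partial epoch excluded).
#' @export
n_epochs <- function(rec) {
  as.integer(floor(rec_duration(rec) / EPOCH_SEC))
}

#' Hypnogram: per-epoch sleep stage labels
#'
#' @param stages Character vector or factor of stage labels, one per 30-s
#'   epoch, each one of `stage_levels()`.
#' @param epoch_len Epoch length in seconds; fixed at 30.
#' @return Object of class `hypnogram`: a factor with levels in canonical
#'   stage order and an `epoch_len` attribute.
#' @export
hypnogram <- function(stages, epoch_len = EPOCH_SEC) {
  if (epoch_len != EPOCH_SEC) stop("epoch_len is fixed at 30 s")
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  if (length(stages) < 1L) stop("hypnogram must contain at least one epoch")
  structure(factor(stages, levels = stage_levels()),
            epoch_len = EPOCH_SEC, class = c("hypnogram", "factor"))
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs (%.1f h): %s\n",
              length(x), length(x) * EPOCH_SEC / 3600,
              paste(sprintf("%s=%d", stage_levels(), table(x)), collapse = " ")))
  invisible(x)
}

#' Check that a hypnogram is aligned to a recording
#'
#' Misaligned labels silently corrupt every downstream analysis, so any
#' mismatch between the hypnogram length and the recording's complete-epoch
#' count is a hard error — never truncated.
#'
#' @param rec A [recording()].
#' @param hyp A [hypnogram()].
#' @return Invisibly `TRUE`, or an error.
#' @export
check_alignment <- function(rec, hyp) {
  ne <- n_epochs(rec)
  if (length(hyp) != ne) {
    stop(sprintf(
      "hypnogram has %d epochs but recording '%s' has %d complete 30-s epochs",
      length(hyp), rec$subject_id, ne))
  }
  invisible(TRUE)
}

#' Split a recording into 30-s epochs
#'
#' Epoch `i` (0-based) covers the half-open sample interval
#' `[i*30*fs, (i+1)*30*fs)`. A trailing partial epoch is discarded.
#'
#' @param rec A [recording()] of duration >= 30 s.
#' @param channel Optional channel name; default all channels.
#' @return If `channel` given, a list of numeric vectors (one per epoch);
#'   otherwise a named list of such lists, one per channel.
#' @export
segment_epochs <- function(rec, channel = NULL) {
  stopifnot(inherits(rec, "recording"))
  ne <- n_epochs(rec)
  if (ne < 1L) stop("recording shorter than one 30-s epoch")
  spe <- as.integer(round(rec$fs * EPOCH_SEC))
  cut_one <- function(x) {
    lapply(seq_len(ne) - 1L, function(i) x[(i * spe + 1L):((i + 1L) * spe)])
  }
  if (is.null(channel)) return(lapply(rec$channels, cut_one))
  if (!channel %in% names(rec$channels)) {
    stop("no channel named '", channel, "'")
  }
  cut_one(rec$channels[[channel]])
}

#' Extract a 90-s context window for one epoch
#'
#' Returns the current 30-s epoch preceded by the previous 60 s of signal,
#' as one contiguous 90-s segment — the input window of the scattering
#' transform. For the first two epochs of a recording there is no 60-s
#' history; the head of the recording is reflected leftward so the window
#' length is always `90 * fs`. Downstream feature tables flag these padded
#' epochs.
#'
#' @param rec A [recording()].
#' @param channel Channel name.
#' @param epoch_index 0-based epoch index, `< n_epochs(rec)`.
#' @return Numeric vector of length `90 * fs` with attribute `padded`
#'   (`TRUE` for epochs 0 and 1).
#' @export
epoch_with_context <- function(rec, channel, epoch_index) {
  stopifnot(inherits(rec, "recording"))
  if (!channel %in% names(rec$channels)) stop("no channel named '", channel, "'")
  ne <- n_epochs(rec)
  if (epoch_index < 0 || epoch_index >= ne) {
    stop(sprintf("epoch_index %d out of range [0, %d)", epoch_index, ne))
  }
  spe <- as.integer(round(rec$fs * EPOCH_SEC))
  x <- rec$channels[[channel]]
  to <- (epoch_index + 1L) * spe
  from <- to - 3L * spe + 1L
  if (from >= 1L) {
    out <- x[from:to]
    padded <- FALSE
  } else {
    need <- 1L - from                      # samples missing on the left
    head_seg <- x[1:to]
    # reflect the head of the recording (without repeating the edge sample)
    refl <- rev(x[2:(need + 1L)])
    out <- c(refl, head_seg)
    padded <- TRUE
  }
  stopifnot(length(out) == 3L * spe)
  attr(out, "padded") <- padded
  out
}
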