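#' Per-epoch feature table for one subject
#'
#' For every 30-s epoch and each of two EEG channels, computes scattering
#' features of the 90-s context window, concatenated (when `use_high_freq`
#' is on) with the three high-band log STFT energies of the current 30-s
#' epoch. The on/off pair realizes the filtered-vs-unfiltered comparison:
#' the filtered run uses scattering features only.
#'
#' The recording is expected to be notch-filtered already (see
#' [notch_filter()]); this function does not filter.
#'
#' @param rec A [recording()] containing both channels.
#' @param hyp A [hypnogram()] aligned to `rec`.
#' @param channels Two EEG channel names.
#' @param use_high_freq Append the high-band STFT features (default `TRUE`).
#' @param config A [scattering_config()].
#' @param bands High-frequency bands for the STFT features.
#' @return A `feature_table`: list with per-channel feature matrices
#'   `views` (epochs x features), `stage` factor, `epoch` (0-based),
#'   `subject`, `padded` flag (epochs lacking a full 60-s history), and
#'   `channels`.
#' @export
assemble_features <- function(rec, hyp, channels = c("C3-A2", "O2-A1"),
                              use_high_freq = TRUE,
                              config = scattering_config(),
                              bands = classifier_bands()) {
  stopifnot(inherits(rec, "recording"), length(channels) == 2L)
  missing_ch <- setdiff(channels, names(rec$channels))
  if (length(missing_ch)) stop("channel(s) absent: ", paste(missing_ch, collapse = ", "))
  check_alignment(rec, hyp)
  ne <- n_epochs(rec)
  views <- vector("list", 2L)
  names(views) <- channels
  padded <- logical(ne)
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    segs <- segment_epochs(rec, ch)
    rows <- vector("list", ne)
    for (e in seq_len(ne) - 1L) {
      ctx <- epoch_with_context(rec, ch, e)
      padded[e + 1L] <- attr(ctx, "padded")
      v <- scattering_transform(as.numeric(ctx), config, rec$fs)
      if (use_high_freq) {
        v <- c(v, stft_features(segs[[e + 1L]], rec$fs, bands))
      }
      rows[[e + 1L]] <- v
    }
    views[[ci]] <- do.call(rbind, rows)
  }
  structure(list(views = views, stage = factor(as.character(hyp),
                                               levels = stage_levels()),
                 epoch = seq_len(ne) - 1L,
                 subject = rep(rec$subject_id, ne),
                 padded = padded, channels = channels,
                 use_high_freq = use_high_freq),
            class = "feature_table")
}

#' Pool feature tables across subjects
#'
#' @param fts List of `feature_table`s with identical channels and
#'   feature dimension.
#' @return A pooled `feature_table`.
#' @export
bind_features <- function(fts) {
  stopifnot(length(fts) >= 1L,
            all(vapply(fts, inherits, TRUE, "feature_table")))
  dims <- vapply(fts, function(f) ncol(f$views[[1]]), 0L)
  if (length(unique(dims)) != 1L) stop("feature dimensions differ across subjects")
  structure(list(
    views = list(do.call(rbind, lapply(fts, function(f) f$views[[1]])),
                 do.call(rbind, lapply(fts, function(f) f$views[[2]]))),
    stage = factor(unlist(lapply(fts, function(f) as.character(f$stage))),
                   levels = stage_levels()),
    epoch = unlist(lapply(fts, function(f) f$epoch)),
    subject = unlist(lapply(fts, function(f) f$subject)),
    padded = unlist(lapply(fts, function(f) f$padded)),
    channels = fts[[1]]$channels,
    use_high_freq = fts[[1]]$use_high_freq), class = "feature_table")
}
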