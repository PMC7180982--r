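#' Write a recording to a European Data Format (EDF) file
#'
#' Standard 16-bit EDF: a 256-byte global header, one 256-byte header block
#' per signal, then data records of little-endian 2-byte integers. Samples
#' are scaled to the digital range -32768..32767 using per-channel physical
#' min/max taken from the data, so the round-trip quantization error is at
#' most half a quantization step. The physical dimension is microvolts.
#'
#' Record duration is chosen as 1 s when `fs` is an integer, otherwise 30 s
#' (an epoch), so each record holds a whole number of samples. A trailing
#' part-record is zero-padded on disk but trimmed on read via the recorded
#' duration; to keep reading simple, the signal is truncated to a whole
#' number of records on write (a warning is given if samples are dropped).
#'
#' @param rec A [recording()]; all samples must be finite.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$channels) == 0L) stop("recording has no channels")
  if (any(!vapply(rec$channels, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite samples cannot be written to EDF")
  }
  fs <- rec$fs
  rec_dur <- if (abs(fs - round(fs)) < 1e-9) 1 else EPOCH_SEC
  spr <- as.integer(round(fs * rec_dur))      # samples per record per channel
  n <- length(rec$channels[[1]])
  n_rec <- n %/% spr
  if (n_rec < 1L) stop("recording shorter than one EDF data record")
  if (n %% spr != 0L) {
    warning(sprintf("truncating %d trailing samples to whole EDF records",
                    n %% spr))
  }
  ns <- length(rec$channels)

  pad <- function(s, w) {
    s <- substr(as.character(s), 1L, w)
    formatC(s, width = -w, flag = " ")
  }
  # shortest %g representation fitting an 8-char EDF numeric field
  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- sprintf("%.*g", d, x)
      if (nchar(s) <= 8L) return(s)
    }
    s
  }
  num <- function(x, w) pad(fmt8(x), w)

  st <- rec$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad("0", 8L),
    pad(rec$subject_id, 80L),
    pad("sleephf recording", 80L),
    pad(format(st, "%d.%m.%y"), 8L),
    pad(format(st, "%H.%M.%S"), 8L),
    pad(hdr_bytes, 8L),
    pad("", 44L),
    pad(n_rec, 8L),
    num(rec_dur, 8L),
    pad(ns, 4L)
  ), con, eos = NULL)

  # per-channel scaling: physical min/max bracket the data range
  phys <- lapply(rec$channels, function(x) {
    x <- x[seq_len(n_rec * spr)]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1   # constant channel: avoid zero span
    c(lo, hi)
  })
  dmin <- -32768L; dmax <- 32767L

  field <- function(f, w) writeChar(paste0(vapply(f, pad, "", w), collapse = ""),
                                    con, eos = NULL)
  field(names(rec$channels), 16L)                       # label
  field(rep("", ns), 80L)                               # transducer
  field(rep("uV", ns), 8L)                              # physical dimension
  field(vapply(phys, function(p) fmt8(p[1]), ""), 8L)
  field(vapply(phys, function(p) fmt8(p[2]), ""), 8L)
  field(rep(dmin, ns), 8L)
  field(rep(dmax, ns), 8L)
  field(rep("", ns), 80L)                               # prefiltering
  field(rep(spr, ns), 8L)
  field(rep("", ns), 32L)                               # reserved

  # re-read the physical min/max exactly as printed so scaling is consistent
  pmin <- vapply(phys, function(p) as.numeric(fmt8(p[1])), 0)
  pmax <- vapply(phys, function(p) as.numeric(fmt8(p[2])), 0)

  dig <- matrix(0L, nrow = spr * ns, ncol = n_rec)
  for (j in seq_len(ns)) {
    x <- rec$channels[[j]][seq_len(n_rec * spr)]
    g <- (dmax - dmin) / (pmax[j] - pmin[j])
    d <- as.integer(round((x - pmin[j]) * g) + dmin)
    d[d > dmax] <- dmax; d[d < dmin] <- dmin
    dig[((j - 1L) * spr + 1L):(j * spr), ] <- matrix(d, nrow = spr)
  }
  writeBin(as.vector(dig), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a European Data Format (EDF) file into a recording
#'
#' Reads 16-bit EDF/EDF+ continuous recordings. All requested channels must
#' share one sampling rate: channels sampled at different rates are rejected
#' rather than resampled, because resampling alters the high-frequency
#' content this package analyses. Units must be microvolts (uV) or
#' millivolts (mV, converted to µV).
#'
#' @param path Path to an existing EDF file.
#' @param channels Optional character vector of channel labels to load;
#'   default all.
#' @return A [recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                                   # version
  patient <- rd(80L)
  rd(80L)                                  # recording id
  date_s <- rd(8L); time_s <- rd(8L)
  as.integer(rd(8L))                       # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count")

  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16L); fld(80L)
  units <- fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L)); fld(32L)

  sel <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(sel)) {
    stop("channel(s) not in file: ",
         paste(channels[is.na(sel)], collapse = ", "))
  }
  if (length(unique(spr[sel])) != 1L) {
    stop("mixed sampling rates among requested channels (",
         paste(sprintf("%s:%g", labels[sel], spr[sel] / rec_dur),
               collapse = ", "),
         "); resampling is refused — select channels of one rate")
  }
  u <- tolower(units[sel])
  scale_u <- ifelse(u %in% c("uv", "µv", ""), 1,
                    ifelse(u == "mv", 1000, NA_real_))
  if (anyNA(scale_u)) {
    stop("unknown physical unit(s): ", paste(unique(units[sel]), collapse = ", "))
  }

  total_spr <- sum(spr)
  raw <- readBin(con, "integer", n = total_spr * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < total_spr * n_rec) stop("EDF file truncated")
  offs <- c(0L, cumsum(spr))
  out <- vector("list", length(sel))
  names(out) <- labels[sel]
  for (k in seq_along(sel)) {
    j <- sel[k]
    idx <- as.vector(outer((offs[j] + 1L):offs[j + 1L],
                           (seq_len(n_rec) - 1L) * total_spr, `+`))
    g <- (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    out[[k]] <- (raw[idx] - dmin[j]) * g + pmin[j]
    out[[k]] <- out[[k]] * scale_u[k]
  }
  st <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  recording(out, fs = spr[sel[1]] / rec_dur,
            subject_id = if (nzchar(patient)) patient else "unknown",
            start_time = st)
}

#' Write a hypnogram to CSV
#'
#' Two columns with a header row: `epoch_index` (0-based) and `stage`, coded
#' `W,R,N1,N2,N3`.
#'
#' @param hyp A [hypnogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp) - 1L,
                   stage = unname(stage_codes[as.character(hyp)]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Expects the two-column format of [write_hypnogram()]; epochs must form
#' the contiguous 0-based sequence.
#'
#' @param path CSV path.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index, stage")
  }
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    stop("epoch_index must be the contiguous sequence 0..n-1")
  }
  inv <- stats::setNames(names(stage_codes), stage_codes)
  st <- inv[as.character(df$stage)]
  if (anyNA(st)) {
    stop("unknown stage code(s): ",
         paste(unique(df$stage[is.na(st)]), collapse = ", "))
  }
  hypnogram(unname(st))
}
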