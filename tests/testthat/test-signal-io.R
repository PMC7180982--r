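test_that("recording enforces equal channel lengths and whole-sample epochs", {
  expect_error(recording(list(a = 1:10, b = 1:9), fs = 1), "length")
  expect_error(recording(list(a = 1:10), fs = 0.21), "integer")
  rec <- toy_recording(3)
  expect_equal(n_epochs(rec), 3L)
  expect_equal(rec_duration(rec), 90)
})

test_that("hypnogram validates labels and alignment is a hard error", {
  expect_error(hypnogram(c("Awake", "REM", "Deep")), "unknown stage")
  rec <- toy_recording(4)
  expect_error(check_alignment(rec, toy_hypnogram(3)), "4 complete")
  expect_silent(check_alignment(rec, toy_hypnogram(4)))
})

test_that("epochs partition the truncated signal exactly", {
  rec <- toy_recording(3)
  # add 5 s of trailing partial epoch
  rec$channels <- lapply(rec$channels, function(x) c(x, rnorm(5 * FS)))
  segs <- segment_epochs(rec, "C3-A2")
  expect_length(segs, 3L)
  expect_true(all(lengths(segs) == SPE))
  expect_identical(unlist(segs), rec$channels[["C3-A2"]][1:(3L * SPE)])
})

test_that("segment_epochs rejects sub-epoch recordings", {
  rec <- recording(list(a = rnorm(10 * FS)), fs = FS)
  expect_error(segment_epochs(rec), "shorter")
})

test_that("context windows are 90 s, padded by reflection for epochs 0-1", {
  n_ep <- 5
  ramp <- recording(list(a = as.numeric(seq_len(n_ep * SPE))), fs = FS)
  # i >= 2: raw slice, no padding
  w <- epoch_with_context(ramp, "a", 2)
  expect_length(w, 3L * SPE)
  expect_false(attr(w, "padded"))
  expect_identical(as.numeric(w), as.numeric(seq_len(3L * SPE)))
  expect_true(all(diff(w) > 0))
  # i = 5 slice arithmetic
  w5 <- epoch_with_context(ramp, "a", 4)
  expect_identical(as.numeric(w5), as.numeric((2L * SPE + 1L):(5L * SPE)))
  # i = 0: padded, last 30 s equal epoch 0
  w0 <- epoch_with_context(ramp, "a", 0)
  expect_length(w0, 3L * SPE)
  expect_true(attr(w0, "padded"))
  expect_identical(as.numeric(w0[(2L * SPE + 1L):(3L * SPE)]),
                   as.numeric(seq_len(SPE)))
  expect_true(attr(epoch_with_context(ramp, "a", 1), "padded"))
  expect_error(epoch_with_context(ramp, "a", 5), "out of range")
})

test_that("context windows agree with segment_epochs on the last 30 s", {
  rec <- toy_recording(4)
  segs <- segment_epochs(rec, "O2-A1")
  for (i in 2:3) {
    w <- epoch_with_context(rec, "O2-A1", i)
    expect_identical(as.numeric(w[(2L * SPE + 1L):(3L * SPE)]), segs[[i + 1L]])
  }
})

test_that("EDF round-trip is sample-identical within 16-bit quantization", {
  rec <- toy_recording(2)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  rec2 <- read_edf(path)
  expect_equal(rec2$fs, rec$fs)
  expect_identical(names(rec2$channels), names(rec$channels))
  for (ch in names(rec$channels)) {
    qstep <- diff(range(rec$channels[[ch]])) / (2^16 - 1)
    expect_lt(max(abs(rec$channels[[ch]] - rec2$channels[[ch]])),
              qstep * 0.5 + 1e-12)
  }
  # 2 channels at 500 Hz, 60 s -> 30000 samples each
  expect_length(rec2$channels[[1]], 30000L)
})

test_that("EDF writer rejects degenerate input and bad reads error", {
  expect_error(write_edf(recording(list(a = c(1, NA, 3) * 0 + c(1, NaN, 3)),
                                   fs = 0.1), "x"), "non-finite")
  expect_error(read_edf("/nonexistent/file.edf"), "not found")
})

test_that("EDF header physical min/max bracket the data and an independent reader agrees", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  rec <- recording(list(sine = sinusoid(10, dur = 30)), fs = FS,
                   subject_id = "OSC")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # header inspection: physical min/max fields bracket the data range
  con <- file(path, "rb")
  hdr <- readChar(con, 256 + 256, useBytes = TRUE)
  close(con)
  pmin <- as.numeric(trimws(substr(hdr, 256 + 16 + 80 + 8 + 1, 256 + 16 + 80 + 8 + 8)))
  pmax <- as.numeric(trimws(substr(hdr, 256 + 16 + 80 + 16 + 1, 256 + 16 + 80 + 16 + 8)))
  expect_lte(pmin, min(rec$channels$sine))
  expect_gte(pmax, max(rec$channels$sine))
  # independent established EDF reader (mne) reads the same samples
  out <- withr::local_tempfile(fileext = ".csv")
  code <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(%s, verbose='error')\n",
    "np.savetxt(%s, raw[:][0][0] * 1e6)\n"),
    deparse(path), deparse(out))
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(code, script)
  res <- system2("python", script, stdout = TRUE, stderr = TRUE)
  vals <- as.numeric(readLines(out))
  expect_length(vals, length(rec$channels$sine))
  expect_lt(mean(abs(vals - rec$channels$sine)), 1e-3)
})

test_that("hypnogram CSV round-trips with W/R/N codes", {
  hyp <- hypnogram(c("Awake", "REM", "N1", "N2", "N3", "REM"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(hyp, path)
  df <- read.csv(path)
  expect_identical(names(df), c("epoch_index", "stage"))
  expect_identical(df$stage, c("W", "R", "N1", "N2", "N3", "R"))
  hyp2 <- read_hypnogram(path)
  expect_identical(as.character(hyp2), as.character(hyp))
})
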