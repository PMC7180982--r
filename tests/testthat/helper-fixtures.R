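# Small fixtures built in code; all tests are deterministic given the
# seeds fixed here.

FS <- 500L
SPE <- FS * 30L

# a short multi-channel recording with deterministic content
toy_recording <- function(n_epochs = 4, fs = FS, seed = 42,
                          channels = c("C3-A2", "O2-A1")) {
  set.seed(seed)
  n <- n_epochs * fs * 30L
  chans <- c(lapply(channels, function(ch) rnorm(n, sd = 20)),
             list(rnorm(n, sd = 5)))
  names(chans) <- c(channels, "EMG")
  recording(chans, fs = fs, subject_id = "TOY")
}

toy_hypnogram <- function(n_epochs = 4) {
  hypnogram(rep(c("Awake", "N2"), length.out = n_epochs))
}

# unit-amplitude sinusoid segment
sinusoid <- function(freq, dur = 30, fs = FS, phase = 0) {
  sin(2 * pi * freq * (seq_len(dur * fs) - 1) / fs + phase)
}

# fast scattering profile for multi-window tests
fast_scat <- function(...) {
  scattering_config(decim_margin = 5, decim_margin2 = 2.5, ...)
}

# confusion matrices as printed in the staging comparison (row order
# Awake, REM, N1, N2, N3; rows = expert, columns = predicted)
table4_matrix <- function() {
  matrix(c(1894, 26,  91,  67,   1,
             27, 470,  54, 162,   0,
            258, 137, 181, 238,   2,
             97,  83, 116, 3143, 152,
              0,   0,   1,  97,  259),
         5, 5, byrow = TRUE,
         dimnames = list(expert = stage_levels(), predicted = stage_levels()))
}

table5_matrix <- function() {
  matrix(c(1817, 36, 164,  62,   0,
             15, 576,  48,  74,   0,
            262,  90, 249, 213,   2,
             84,  54, 184, 3106, 163,
              0,   0,   1,  95,  261),
         5, 5, byrow = TRUE,
         dimnames = list(expert = stage_levels(), predicted = stage_levels()))
}
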