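N90 <- 90L * FS

test_that("bank has Q1*J first-layer filters with decreasing centers and a tight frame", {
  cfg <- scattering_config()
  b <- build_filter_bank(cfg, FS, N90)
  expect_length(b$filters1, cfg$Q1 * cfg$J)
  fc <- vapply(b$filters1, `[[`, 0, "fc")
  expect_true(all(diff(fc) < 0))
  lp <- littlewood_paley(b)
  expect_lte(max(lp$lp), 1 + 1e-12)
  expect_gte(min(lp$lp), 1 - 0.2)
  expect_error(build_filter_bank(cfg, FS, 512), "smaller J")
})

test_that("feature length is a pure function of the config and matches output", {
  cfg1 <- scattering_config(max_order = 1)
  expect_identical(scattering_feature_length(cfg1), 1L + 80L)
  cfg2 <- scattering_config()
  set.seed(12)
  s <- scattering_transform(rnorm(N90), cfg2, FS)
  expect_length(s, scattering_feature_length(cfg2))
  # growing J strictly increases the feature count
  l5 <- scattering_feature_length(scattering_config(J = 5))
  l10 <- scattering_feature_length(scattering_config(J = 10))
  expect_gt(l10, l5)
})

test_that("zero input gives zero raw coefficients (log floor when transformed)", {
  cfg <- scattering_config(log_transform = FALSE)
  expect_true(all(scattering_transform(numeric(N90), cfg, FS) == 0))
  sl <- scattering_transform(numeric(N90), scattering_config(), FS)
  expect_true(all(abs(sl - log(1e-12)) < 1e-9))
  expect_error(scattering_transform(c(NaN, numeric(N90 - 1)),
                                    scattering_config(), FS), "non-finite")
})

test_that("raw coefficients are exactly positive-homogeneous; log shifts by log a", {
  cfg <- scattering_config(log_transform = FALSE)
  set.seed(13)
  x <- rnorm(N90)
  s1 <- scattering_transform(x, cfg, FS)
  s3 <- scattering_transform(3 * x, cfg, FS)
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
  sl1 <- scattering_transform(x, scattering_config(eps = 0), FS)
  sl3 <- scattering_transform(3 * x, scattering_config(eps = 0), FS)
  expect_equal(unname(sl3 - sl1), rep(log(3), length(sl1)), tolerance = 1e-9)
})

test_that("envelope decimation reproduces the full-resolution transform", {
  set.seed(14)
  x <- rnorm(N90)
  s <- scattering_transform(x, scattering_config(log_transform = FALSE), FS)
  full <- scattering_transform(
    x, scattering_config(log_transform = FALSE,
                         decim_margin = 1e9, decim_margin2 = 1e9), FS)
  expect_lt(sqrt(sum((s - full)^2)) / sqrt(sum(full^2)), 2e-3)
})

test_that("the transform is non-expansive in RMS norm over random pairs", {
  cfg <- scattering_config(log_transform = FALSE, taper_sec = 0)
  set.seed(15)
  worst <- 0
  for (i in 1:50) {
    x <- rnorm(N90, sd = runif(1, 0.5, 2))
    y <- x + rnorm(N90, sd = runif(1, 0.05, 1))
    ds <- sqrt(sum((scattering_transform(x, cfg, FS) -
                      scattering_transform(y, cfg, FS))^2))
    dx <- sqrt(mean((x - y)^2))
    worst <- max(worst, ds / dx)
  }
  expect_lte(worst, 1.2)
})

test_that("order-2 energy is below order-1 energy for broadband noise", {
  cfg <- scattering_config(log_transform = FALSE)
  set.seed(16)
  for (i in 1:3) {
    s <- scattering_transform(rnorm(N90), cfg, FS)
    e1 <- sum(s[2:81]^2)
    e2 <- sum(s[-(1:81)]^2)
    expect_lt(e2, e1)
  }
})

test_that("features tolerate sub-second circular shifts of band-limited input", {
  cfg <- scattering_config(log_transform = FALSE)
  x <- sinusoid(8, dur = 90) + 0.7 * sinusoid(31, dur = 90, phase = 1) +
    0.3 * sinusoid(97, dur = 90, phase = 2)
  s0 <- scattering_transform(x, cfg, FS)
  for (shift_s in c(0.2, 1)) {
    xs <- c(x[-(seq_len(shift_s * FS))], x[seq_len(shift_s * FS)])
    ss <- scattering_transform(xs, cfg, FS)
    expect_lt(sqrt(sum((ss - s0)^2)) / sqrt(sum(s0^2)), 0.01)
  }
})

test_that("scattering distance under a 1% time warp is below the signal distance", {
  cfg <- scattering_config(log_transform = FALSE)
  t <- (seq_len(N90) - 1) / FS
  chirp <- function(tt) sin(2 * pi * (2 * tt + 0.5 * tt^2 / 90))
  x <- chirp(t)
  x_tau <- chirp(t * 1.01)
  rel_sig <- sqrt(sum((x - x_tau)^2)) / sqrt(sum(x^2))
  sx <- scattering_transform(x, cfg, FS)
  st <- scattering_transform(x_tau, cfg, FS)
  rel_feat <- sqrt(sum((sx - st)^2)) / sqrt(sum(sx^2))
  expect_lt(rel_feat, rel_sig)
})

test_that("identical input and config give bit-identical features", {
  set.seed(17)
  x <- rnorm(N90)
  expect_identical(scattering_transform(x, scattering_config(), FS),
                   scattering_transform(x, scattering_config(), FS))
})
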