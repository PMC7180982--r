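test_that("pearson_r matches hand computation and handles exact linearity", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10)
  y <- c(2, 3, 1, 9, 6, 8, 2, 5, 8, 11)
  # brute-force covariance / sigma formula
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("permutation p attains its minimum for perfect correlation and is seeded", {
  set.seed(22)
  x <- rnorm(50)
  pt <- permutation_test(x, x, n_perm = 999, seed = 5)
  expect_equal(pt$p, 1 / 1000)
  pt2 <- permutation_test(x, x, n_perm = 999, seed = 5)
  expect_identical(pt$p, pt2$p)
  expect_error(permutation_test(x, x, n_perm = 0), "n_perm")
})

test_that("permutation p is invariant to monotone rescaling of x", {
  set.seed(23)
  x <- rnorm(80)
  y <- x + rnorm(80, sd = 2)
  p1 <- permutation_test(x, y, n_perm = 500, seed = 7)$p
  p2 <- permutation_test(10 * x + 3, y, n_perm = 500, seed = 7)$p
  expect_identical(p1, p2)
})

test_that("type-I error of the permutation test is calibrated near alpha", {
  set.seed(24)
  rej <- replicate(200, {
    x <- rnorm(60); y <- rnorm(60)
    permutation_test(x, y, n_perm = 200, seed = sample.int(1e6, 1))$p < 0.05
  })
  # binomial 3-sigma band around 0.05 with 200 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("significance flags implement the 36-test Bonferroni family", {
  p <- rep(0.5, 36)
  p[1] <- 0.0013   # below 0.05/36 = 0.00139
  p[2] <- 0.002    # above the corrected threshold
  p[3] <- 5e-6     # below the ** level
  fl <- flag_significance(p)
  expect_identical(fl[1:3], c("*", "", "**"))
  expect_error(flag_significance(rep(0.01, 35)), "36")
})

test_that("bland_altman uses the documented interpolation quantile rule", {
  x <- as.numeric(1:100)
  ba <- bland_altman(x, rep(0, 100))
  expect_equal(ba$interval, c(3.475, 97.525))
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$interval, c(0, 0))
  expect_true(all(ba0$diff == 0))
  expect_length(ba$mean, 100L)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("pooled energies count epochs and pool by concatenation", {
  hyp <- hypnogram(rep(c("Awake", "N2"), 3))
  cohort <- list(
    list(recording = simulate_recording(hyp, seed = 31, subject_id = "A"),
         hypnogram = hyp),
    list(recording = simulate_recording(hyp, seed = 32, subject_id = "B"),
         hypnogram = hyp))
  pe_all <- pooled_energies(cohort, "C3-A2", c(80, 250), "All")
  expect_equal(pe_all$n, 12L)
  pe_a <- pooled_energies(cohort[1], "C3-A2", c(80, 250), "All")
  pe_b <- pooled_energies(cohort[2], "C3-A2", c(80, 250), "All")
  expect_equal(pe_all$eeg, c(pe_a$eeg, pe_b$eeg))
  expect_equal(pe_all$emg, c(pe_a$emg, pe_b$emg))
  pe_w <- pooled_energies(cohort, "C3-A2", c(80, 250), "Awake")
  expect_equal(pe_w$n, 6L)
  expect_error(pooled_energies(cohort, "C3-A2", c(80, 250), "REM"), "REM")
})

test_that("the synthetic correlation table is higher in (150,250) than (35,80)", {
  # ordering checked on the tone-bearing groups; REM is atonic by design
  # (leaked power ~2% of the band energy), so its within-group r is noise
  hyp <- hypnogram(rep(stage_levels(), times = 30))
  cohort <- list(list(recording = simulate_recording(hyp, seed = 34),
                      hypnogram = hyp))
  tab <- correlation_table(cohort, "C3-A2", n_perm = 200, seed = 35)
  expect_equal(nrow(tab), 36L)
  for (g in c("Awake", "N1", "All")) {
    r_hi <- tab$r[tab$band == "150-250" & tab$group == g]
    r_lo <- tab$r[tab$band == "35-80" & tab$group == g]
    expect_gt(r_hi, r_lo)
  }
  # the pooled high-band correlation itself is strong: its permutation p
  # bottoms out at the add-one minimum for the permutation count used
  expect_gt(tab$r[tab$band == "80-250" & tab$group == "All"], 0.8)
  expect_equal(tab$p[tab$band == "80-250" & tab$group == "All"], 1 / 201)
})
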