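# feature assembly, CCA fusion, SVM and LOSOCV

small_cohort <- function(n_subjects = 3, n_epochs = 8, seed = 40) {
  simulate_cohort(n_subjects, n_epochs, seed = seed)
}

test_that("assemble_features has the documented dimensions and padded flags", {
  su <- small_cohort(1)[[1]]
  cfg <- fast_scat()
  ft_off <- assemble_features(su$recording, su$hypnogram,
                              use_high_freq = FALSE, config = cfg)
  d_scat <- scattering_feature_length(cfg)
  expect_equal(ncol(ft_off$views[[1]]), d_scat)
  expect_equal(ncol(ft_off$views[[2]]), d_scat)
  ft_on <- assemble_features(su$recording, su$hypnogram,
                             use_high_freq = TRUE, config = cfg)
  expect_equal(ncol(ft_on$views[[1]]), d_scat + 3L)
  expect_identical(ft_on$padded, c(TRUE, TRUE, rep(FALSE, 6)))
  expect_error(assemble_features(su$recording, hypnogram(rep("N2", 5)),
                                 config = cfg), "epochs")
  expect_error(assemble_features(su$recording, su$hypnogram,
                                 channels = c("C3-A2", "F3-A2"), config = cfg),
               "absent")
})

test_that("bind_features concatenates subjects row-wise", {
  cohort <- small_cohort(2)
  cfg <- fast_scat()
  fts <- lapply(cohort, function(su)
    assemble_features(su$recording, su$hypnogram, config = cfg))
  ft <- bind_features(fts)
  expect_equal(nrow(ft$views[[1]]), 16L)
  expect_identical(unique(ft$subject), c("S01", "S02"))
})

test_that("CCA recovers perfect correlation for identical views", {
  set.seed(41)
  X <- matrix(rnorm(40 * 5), 40, 5)
  p <- fit_cca(X, X, k = 3)
  expect_true(all(abs(p$rho - 1) < 1e-6))
  expect_true(all(diff(p$rho) <= 1e-12))
})

test_that("independent views have near-zero canonical correlations", {
  set.seed(42)
  X <- matrix(rnorm(2000 * 4), 2000, 4)
  Y <- matrix(rnorm(2000 * 4), 2000, 4)
  p <- fit_cca(X, Y, k = 3)
  expect_true(all(p$rho < 0.1))
})

test_that("canonical correlations match the generalized-eigenvalue oracle", {
  set.seed(43)
  X <- matrix(rnorm(50 * 8), 50, 8)
  Y <- matrix(rnorm(50 * 6), 50, 6)
  Y[, 1] <- 0.7 * X[, 2] + rnorm(50, sd = 0.4)
  p <- fit_cca(X, Y, k = 4)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Cxx <- crossprod(Xc) / 49; Cyy <- crossprod(Yc) / 49
  Cxy <- crossprod(Xc, Yc) / 49
  ev <- eigen(solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy)))$values
  rho_oracle <- sqrt(sort(Re(ev), decreasing = TRUE)[1:4])
  expect_equal(p$rho, rho_oracle, tolerance = 1e-8)
  expect_error(fit_cca(X, Y, k = 7), "exceeds")
})

test_that("CCA is affine invariant and apply_cca reproduces training correlations", {
  set.seed(44)
  X <- matrix(rnorm(60 * 6), 60, 6)
  Y <- matrix(rnorm(60 * 5), 60, 5)
  p <- fit_cca(X, Y, k = 3)
  A <- matrix(rnorm(36), 6, 6)
  p2 <- fit_cca(X %*% A, Y, k = 3)
  expect_equal(p2$rho, p$rho, tolerance = 1e-6)
  Fz <- apply_cca(p, X, Y)
  expect_equal(ncol(Fz), 6L)
  got <- vapply(1:3, function(j) cor(Fz[, j], Fz[, 3 + j]), 0)
  expect_equal(got, p$rho, tolerance = 1e-8)
  expect_error(apply_cca(p, X[, 1:3], Y), "dimensions")
})

test_that("the SVM separates separable blobs and ignores row duplication", {
  set.seed(45)
  X <- rbind(matrix(rnorm(100 * 2, mean = 0), 100, 2),
             matrix(rnorm(100 * 2, mean = 4), 100, 2))
  y <- factor(rep(c("REM", "N1"), each = 100), levels = stage_levels())
  m <- train_svm(X, y, cost = 10)
  expect_gte(mean(predict(m, X) == y), 0.99)
  m2 <- train_svm(rbind(X, X), c(y, y), cost = 10)
  Xg <- matrix(rnorm(200 * 2, mean = 2), 200, 2)
  expect_gte(mean(predict(m, Xg) == predict(m2, Xg)), 0.98)
  expect_error(train_svm(X, factor(rep("N1", 200))), "single class")
})

test_that("grouped tuning picks hyperparameters from the grid", {
  set.seed(46)
  X <- rbind(matrix(rnorm(60 * 2), 60, 2),
             matrix(rnorm(60 * 2, mean = 3), 60, 2))
  y <- factor(rep(c("Awake", "N2"), each = 60), levels = stage_levels())
  g <- rep(sprintf("S%d", 1:6), times = 20)
  m <- train_svm(X, y, tune = TRUE, groups = g, seed = 2,
                 tune_grid = list(cost = c(1, 10), gamma_scale = c(1, 3)))
  expect_true(m$cost %in% c(1, 10))
})

test_that("LOSOCV predicts each epoch once and is invariant to subject order", {
  cohort <- small_cohort(4, 10, seed = 47)
  cfg <- fast_scat()
  fts <- lapply(cohort, function(su)
    assemble_features(su$recording, su$hypnogram, config = cfg))
  ft <- bind_features(fts)
  cv1 <- losocv(ft, k_cca = 10)
  expect_equal(nrow(cv1$predictions), 40L)
  expect_equal(length(cv1$folds), 4L)
  key1 <- paste(cv1$predictions$subject, cv1$predictions$epoch_index)
  expect_false(any(duplicated(key1)))
  # shuffle subject blocks: per-epoch predictions must not change
  ord <- c(3, 1, 4, 2)
  ft2 <- bind_features(fts[ord])
  cv2 <- losocv(ft2, k_cca = 10)
  m1 <- cv1$predictions[order(key1), ]
  key2 <- paste(cv2$predictions$subject, cv2$predictions$epoch_index)
  m2 <- cv2$predictions[order(key2), ]
  expect_identical(m1$predicted_stage, m2$predicted_stage)
  expect_error(losocv(bind_features(fts[1:2])), "3 subjects")
})

test_that("label-permuted features score near chance under LOSOCV", {
  set.seed(48)
  n_sub <- 5; n_ep <- 60
  ft <- structure(list(
    views = list(matrix(rnorm(n_sub * n_ep * 6), n_sub * n_ep, 6),
                 matrix(rnorm(n_sub * n_ep * 6), n_sub * n_ep, 6)),
    stage = factor(sample(stage_levels(), n_sub * n_ep, TRUE),
                   levels = stage_levels()),
    epoch = rep(seq_len(n_ep) - 1L, n_sub),
    subject = rep(sprintf("S%d", seq_len(n_sub)), each = n_ep),
    padded = rep(FALSE, n_sub * n_ep),
    channels = c("a", "b"), use_high_freq = FALSE),
    class = "feature_table")
  cv <- losocv(ft, k_cca = 4)
  acc <- mean(cv$predictions$true_stage == cv$predictions$predicted_stage)
  se <- sqrt(0.2 * 0.8 / (n_sub * n_ep))
  expect_lt(abs(acc - 0.2), 3 * se + 0.02)
})
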