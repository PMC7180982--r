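#' Train the stage classifier (RBF-kernel SVM)
#'
#' One-vs-one multiclass SVM with a Gaussian kernel and class weights
#' inversely proportional to training class frequency (N1 and N3 are rare
#' in clinical hypnograms and an unweighted SVM tends to collapse them).
#' Hyperparameters can either be fixed or chosen by subject-grouped inner
#' cross-validation over a small grid.
#'
#' @param X Fused feature matrix (rows = epochs).
#' @param y Stage labels (factor over `stage_levels()`, >= 2 classes).
#' @param cost SVM cost parameter (default 10).
#' @param gamma Kernel width; default `1/ncol(X)`.
#' @param tune If `TRUE`, select `cost`/`gamma` by inner CV (see
#'   `tune_grid`).
#' @param tune_grid List with numeric vectors `cost` and `gamma_scale`
#'   (multiples of `1/ncol(X)`); default 3 x 3 grid.
#' @param groups Subject labels for grouped inner CV (required when
#'   `tune = TRUE`).
#' @param inner_folds Inner CV fold count (default 3), grouped by subject
#'   so tuning never mixes a subject across fold sides.
#' @param seed Seed for the inner fold assignment.
#' @return Object of class `stage_svm`: the fitted e1071 model plus the
#'   chosen hyperparameters.
#' @export
train_svm <- function(X, y, cost = 10, gamma = NULL, tune = FALSE,
                      tune_grid = list(cost = c(1, 10, 100),
                                       gamma_scale = c(0.3, 1, 3)),
                      groups = NULL, inner_folds = 3, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  X <- as.matrix(X)
  g0 <- 1 / ncol(X)
  if (is.null(gamma)) gamma <- g0
  cw <- 1 / table(y)
  cw <- cw / mean(cw)
  if (tune) {
    if (is.null(groups)) stop("grouped tuning requires `groups`")
    groups <- as.character(groups)
    gs <- unique(groups)
    set.seed(seed)
    fold_of <- setNames(sample(rep_len(seq_len(inner_folds), length(gs))), gs)
    best <- c(acc = -1, cost = cost, gamma = gamma)
    for (co in tune_grid$cost) for (ga in tune_grid$gamma_scale * g0) {
      hits <- 0L
      for (f in seq_len(inner_folds)) {
        te <- fold_of[groups] == f
        if (!any(te) || !any(!te) || nlevels(droplevels(y[!te])) < 2L) next
        m <- e1071::svm(X[!te, , drop = FALSE], y[!te], kernel = "radial",
                        cost = co, gamma = ga, scale = FALSE,
                        class.weights = 1 / table(droplevels(y[!te])) *
                          mean(table(droplevels(y[!te]))))
        hits <- hits + sum(predict(m, X[te, , drop = FALSE]) == y[te])
      }
      if (hits / length(y) > best["acc"]) {
        best <- c(acc = hits / length(y), cost = co, gamma = ga)
      }
    }
    cost <- best[["cost"]]; gamma <- best[["gamma"]]
  }
  fit <- e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE, class.weights = cw)
  structure(list(fit = fit, cost = cost, gamma = gamma,
                 levels = levels(y)), class = "stage_svm")
}

#' @export
predict.stage_svm <- function(object, newdata, ...) {
  factor(as.character(predict(object$fit, as.matrix(newdata))),
         levels = stage_levels())
}

# per-column standardization fitted on training rows only
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(mu = mu, sd = sd_)
}
apply_standardizer <- function(std, X) {
  sweep(sweep(as.matrix(X), 2, std$mu), 2, std$sd, "/")
}

#' Leave-one-subject-out cross-validated staging
#'
#' One fold per subject: feature standardization, the CCA fusion and the
#' SVM are all fitted on the training subjects only, and the held-out
#' subject's epochs are predicted. Every epoch is predicted exactly once;
#' fold membership is determined by subject identity alone, so subject
#' order cannot change any prediction. A hard internal assertion guarantees
#' no test-subject row ever reaches the training side.
#'
#' @param ft A pooled [bind_features()] `feature_table` over >= 3 subjects.
#' @param k_cca Number of canonical directions (default `min(50, view
#'   rank)`; the fused matrix then has `2 * k_cca` columns).
#' @param ridge CCA ridge (default 1e-4; the scattering features are
#'   strongly collinear).
#' @param cost,gamma,tune,tune_grid,inner_folds Passed to [train_svm()].
#' @param seed Seed for inner tuning folds.
#' @return List with `predictions` data frame (subject, epoch_index,
#'   true_stage, predicted_stage, padded), per-fold metadata `folds`, and
#'   the call parameters.
#' @export
losocv <- function(ft, k_cca = 50, ridge = 1e-4, cost = 10, gamma = NULL,
                   tune = FALSE, tune_grid = list(cost = c(1, 10, 100),
                                                  gamma_scale = c(0.3, 1, 3)),
                   inner_folds = 3, seed = 1) {
  stopifnot(inherits(ft, "feature_table"))
  subjects <- sort(unique(ft$subject))
  if (length(subjects) < 3L) stop("LOSOCV needs at least 3 subjects")
  k <- min(k_cca, ncol(ft$views[[1]]), ncol(ft$views[[2]]))
  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  names(preds) <- names(folds) <- subjects
  for (s in subjects) {
    te <- ft$subject == s
    tr <- !te
    stopifnot(!any(ft$subject[tr] == s))      # no-leakage assertion
    std1 <- fit_standardizer(ft$views[[1]][tr, , drop = FALSE])
    std2 <- fit_standardizer(ft$views[[2]][tr, , drop = FALSE])
    X1tr <- apply_standardizer(std1, ft$views[[1]][tr, , drop = FALSE])
    X2tr <- apply_standardizer(std2, ft$views[[2]][tr, , drop = FALSE])
    proj <- fit_cca(X1tr, X2tr, k = k, ridge = ridge)
    Ftr <- apply_cca(proj, X1tr, X2tr)
    model <- train_svm(Ftr, ft$stage[tr], cost = cost, gamma = gamma,
                       tune = tune, tune_grid = tune_grid,
                       groups = ft$subject[tr], inner_folds = inner_folds,
                       seed = seed)
    Fte <- apply_cca(proj,
                     apply_standardizer(std1, ft$views[[1]][te, , drop = FALSE]),
                     apply_standardizer(std2, ft$views[[2]][te, , drop = FALSE]))
    preds[[s]] <- data.frame(
      subject = s, epoch_index = ft$epoch[te],
      true_stage = as.character(ft$stage[te]),
      predicted_stage = as.character(predict(model, Fte)),
      padded = ft$padded[te], stringsAsFactors = FALSE)
    folds[[s]] <- list(subject = s, n_train = sum(tr), n_test = sum(te),
                       cost = model$cost, gamma = model$gamma,
                       rho = proj$rho)
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  stopifnot(nrow(out) == length(ft$stage))    # one prediction per epoch
  list(predictions = out, folds = folds,
       params = list(k_cca = k, ridge = ridge, tune = tune, seed = seed))
}

#' Filtered-vs-unfiltered staging experiment on one cohort
#'
#' Runs the full pipeline twice on the same recordings: once on 50 Hz
#' low-passed EEG with scattering features only (the clinically filtered
#' export), and once on unfiltered EEG with the three high-band STFT
#' features appended. Both runs share the notch preprocessing, CCA fusion
#' and LOSOCV protocol, so metric differences isolate the contribution of
#' the >35 Hz content.
#'
#' @param cohort A [simulate_cohort()] result (or an equivalent list of
#'   `list(recording =, hypnogram =)` pairs).
#' @param channels Two EEG channel names.
#' @param config A [scattering_config()] used for both runs.
#' @param notch_hz Mains frequency for the notch (default 60).
#' @param ... Passed to [losocv()].
#' @return List with elements `filtered` and `unfiltered`, each holding
#'   the [losocv()] result, its [confusion()] matrix and [stage_metrics()].
#' @export
staging_experiment <- function(cohort, channels = c("C3-A2", "O2-A1"),
                               config = scattering_config(),
                               notch_hz = 60, ...) {
  run <- function(filtered) {
    fts <- lapply(cohort, function(su) {
      rec <- su$recording
      if (filtered) rec <- lowpass_version(rec)
      for (ch in channels) {
        rec$channels[[ch]] <- notch_filter(rec$channels[[ch]], rec$fs,
                                           f0 = notch_hz)
      }
      assemble_features(rec, su$hypnogram, channels,
                        use_high_freq = !filtered, config = config)
    })
    cv <- losocv(bind_features(fts), ...)
    M <- confusion(cv$predictions$true_stage, cv$predictions$predicted_stage)
    list(cv = cv, confusion = M, metrics = stage_metrics(M))
  }
  list(filtered = run(TRUE), unfiltered = run(FALSE))
}
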