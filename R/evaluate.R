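#' Confusion matrix of expert vs predicted stages
#'
#' Unnormalized 5 x 5 counts in `stage_levels()` order: entry (p, q) is
#' the number of expert-assigned p-class epochs predicted as class q.
#'
#' @param true,predicted Equal-length stage label vectors (each label one
#'   of the five stages).
#' @return Integer matrix of class `confusion_matrix` with stage
#'   dimnames.
#' @export
confusion <- function(true, predicted) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop("true and predicted stage sequences differ in length")
  }
  bad <- setdiff(unique(c(true, predicted)), stage_levels())
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  M <- table(factor(true, levels = stage_levels()),
             factor(predicted, levels = stage_levels()))
  M <- matrix(as.integer(M), 5, 5,
              dimnames = list(expert = stage_levels(),
                              predicted = stage_levels()))
  class(M) <- c("confusion_matrix", class(M))
  M
}

#' Staging performance metrics from a confusion matrix
#'
#' Per class: precision `PR = Mpp / column sum`, recall `RE = Mpp / row
#' sum`, and their harmonic mean F1; overall accuracy `trace / total`;
#' Cohen's kappa from the row/column marginals; and the macro F1 score,
#' the unweighted mean of the five per-class F1 values. All metrics are
#' computed from unrounded intermediates; percentages are on the 0-100
#' scale. A class never predicted gets PR = 0 (and F1 = 0 if also never
#' present), keeping macro F1 defined.
#'
#' @param M A 5 x 5 [confusion()] matrix (or plain matrix of counts).
#' @return List with `per_class` data frame (PR, RE, F1 in percent),
#'   `accuracy`, `macro_f1` (percent), `kappa`, and `total`.
#' @export
stage_metrics <- function(M) {
  M <- unclass(as.matrix(M))
  if (any(dim(M) != 5) || any(M < 0)) stop("M must be a 5x5 nonnegative matrix")
  total <- sum(M)
  if (total <= 0) stop("empty confusion matrix")
  rs <- rowSums(M); cs <- colSums(M); dg <- diag(M)
  pr <- ifelse(cs > 0, dg / cs, 0)
  re <- ifelse(rs > 0, dg / rs, 0)
  f1 <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  acc <- sum(dg) / total
  pe <- sum(rs * cs) / total^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  list(per_class = data.frame(stage = stage_levels(),
                              PR = 100 * pr, RE = 100 * re, F1 = 100 * f1,
                              row.names = NULL),
       accuracy = 100 * acc,
       macro_f1 = 100 * mean(f1),
       kappa = kappa,
       total = total)
}

#' Round half away from zero
#'
#' The rounding style used in printed clinical staging tables (e.g. row
#' percentages), as opposed to R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a metrics report the way staging papers print it
#'
#' Percentages at 2 decimals, kappa at 4, per-class values at integer
#' precision (half-away-from-zero).
#'
#' @param m A [stage_metrics()] result.
#' @return Character vector of report lines (also printed).
#' @export
format_metrics <- function(m) {
  lines <- c(
    sprintf("Overall accuracy: %.2f%%", m$accuracy),
    sprintf("Macro F1:         %.2f%%", m$macro_f1),
    sprintf("Cohen's kappa:    %.4f", m$kappa),
    "stage    PR   RE   F1",
    sprintf("%-6s %4d %4d %4d", m$per_class$stage,
            round_half_up(m$per_class$PR), round_half_up(m$per_class$RE),
            round_half_up(m$per_class$F1)))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a metrics report as JSON
#'
#' @param m A [stage_metrics()] result.
#' @param path Output path.
#' @param ... Extra named fields stored alongside the metrics (e.g. seed,
#'   configuration).
#' @return `path`, invisibly.
#' @export
metrics_json <- function(m, path, ...) {
  payload <- c(m[c("accuracy", "macro_f1", "kappa", "total")],
               list(per_class = m$per_class), list(...))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a confusion matrix as CSV
#'
#' CSV with a header row and a leading column of expert stage names.
#'
#' @param M A [confusion()] matrix.
#' @param path CSV path.
#' @return `path` (write) or a `confusion_matrix` (read).
#' @export
write_confusion <- function(M, path) {
  df <- data.frame(stage = rownames(M), unclass(as.matrix(M)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 6L) stop("confusion CSV must have a stage column plus 5 count columns")
  M <- as.matrix(df[, -1])
  storage.mode(M) <- "integer"
  dimnames(M) <- list(expert = stage_levels(), predicted = stage_levels())
  class(M) <- c("confusion_matrix", class(M))
  M
}
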