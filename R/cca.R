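#' Canonical correlation analysis with ridge regularization
#'
#' Finds paired linear projections of two feature views maximizing their
#' correlation, subject to unit variance and orthogonality across
#' directions — used to fuse the two EEG channels' features and reduce
#' their dimension. Solved by whitening each view's (ridge-stabilized)
#' covariance and taking the SVD of the whitened cross-covariance; the
#' canonical correlations are the singular values, non-increasing in
#' `1:k`. The per-direction sign ambiguity is fixed by making the
#' largest-magnitude loading of the first view positive.
#'
#' @param X,Y Feature matrices with equal row counts `n >= k + 2`.
#' @param k Number of canonical directions (`<= min(ncol(X), ncol(Y))`).
#' @param ridge Relative ridge `eps` added to each view's covariance as
#'   `eps * mean(diag(C)) * I` (default 1e-9: numerically negligible on
#'   well-conditioned views, set larger, e.g. 1e-4, for collinear
#'   high-dimensional features; rank deficiency is always handled by the
#'   ridge, never by dropping dimensions).
#' @return A `cca_projection`: per-view maps `wx`, `wy` (columns are
#'   directions), canonical correlations `rho`, centering vectors, and the
#'   ridge used.
#' @export
fit_cca <- function(X, Y, k, ridge = 1e-9) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("views must have equal row counts")
  if (k > min(ncol(X), ncol(Y))) {
    stop(sprintf("k = %d exceeds the smaller view dimension %d",
                 k, min(ncol(X), ncol(Y))))
  }
  if (n < k + 2) stop("need at least k + 2 rows")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  Cxx <- crossprod(Xc) / (n - 1)
  Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  inv_sqrt <- function(C, eps) {
    d <- mean(diag(C))
    if (d <= 0) d <- 1
    e <- eigen(C + eps * d * diag(nrow(C)), symmetric = TRUE)
    ev <- pmax(e$values, max(e$values) * 1e-14)
    e$vectors %*% (t(e$vectors) / sqrt(ev))
  }
  Wx <- inv_sqrt(Cxx, ridge)
  Wy <- inv_sqrt(Cyy, ridge)
  s <- svd(Wx %*% Cxy %*% Wy, nu = k, nv = k)
  rho <- pmin(s$d[seq_len(k)], 1 + 1e-9)
  wx <- Wx %*% s$u
  wy <- Wy %*% s$v
  # fix signs: largest-magnitude loading of wx positive per direction
  for (j in seq_len(k)) {
    i <- which.max(abs(wx[, j]))
    if (wx[i, j] < 0) {
      wx[, j] <- -wx[, j]
      wy[, j] <- -wy[, j]
    }
  }
  structure(list(wx = wx, wy = wy, rho = rho, cx = cx, cy = cy,
                 k = k, ridge = ridge),
            class = "cca_projection")
}

#' Apply a fitted CCA projection to two views
#'
#' Projects each view onto its canonical directions (centering with the
#' training means only) and concatenates the two projected `k`-vectors per
#' row, giving the fused `2k`-column feature matrix.
#'
#' @param proj A [fit_cca()] result.
#' @param X,Y Views with the dimensions the projection was fitted on.
#' @return Fused matrix with `2 * k` columns.
#' @export
apply_cca <- function(proj, X, Y) {
  stopifnot(inherits(proj, "cca_projection"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != length(proj$cx) || ncol(Y) != length(proj$cy)) {
    stop("view dimensions do not match the fitted projection")
  }
  cbind(sweep(X, 2, proj$cx) %*% proj$wx,
        sweep(Y, 2, proj$cy) %*% proj$wy)
}
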