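#' Gaussian-copula mutual information between neural responses and a binary class
#'
#' The estimator rank-transforms each response dimension to standard-normal
#' scores (the Gaussian copula transform) and then applies a parametric
#' Gaussian model: MI is estimated as the difference between the entropy of the
#' pooled scores and the label-weighted class-conditional entropies, each
#' computed from a covariance log-determinant with an analytic small-sample
#' bias correction (digamma expectation of the log-determinant of a Wishart
#' matrix). The result is a lower bound on the true MI that is exactly
#' invariant to strictly monotone per-dimension transforms of the input.
#'
#' @name gcmi
NULL

## ---- copula transform -------------------------------------------------------

#' Rank-transform a vector to standard-normal scores
#'
#' Maps value `i` to `qnorm(rank_i / (n + 1))`. Ties are broken by stable input
#' order (`ties.method = "first"`), so the transform is deterministic and
#' strictly monotone in the input.
#'
#' @param x numeric vector, length >= 2.
#' @return Numeric vector of standard-normal scores.
#' @examples
#' copula_normalize(c(3.2, -1.0, 0.5))  # qnorm(c(.75, .25, .5))
#' @export
copula_normalize <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  if (!all(is.finite(x))) stop("input must be finite")
  if (max(x) == min(x)) stop("degenerate ranks: all input values are equal")
  stats::qnorm(rank(x, ties.method = "first") / (n + 1))
}

## Copula-normalize every column of a [n x m] matrix.
.copula_cols <- function(X) {
  apply(X, 2L, copula_normalize)
}

## ---- bias-corrected Gaussian entropies -------------------------------------

## Additive bias-correction term for a d-dimensional Gaussian entropy
## estimated from n samples (expected log-determinant of the sample
## covariance): sum over dims of digamma((n - i)/2)/2 plus d*(log 2 -
## log(n-1))/2.  Constants 0.5*d*log(2*pi*e) are omitted throughout; they
## cancel in every MI difference.
.ent_bias <- function(n, d) {
  sum(digamma((n - seq_len(d)) / 2)) / 2 + d * (log(2) - log(n - 1)) / 2
}

## 0.5*logdet of covariance of X (columns centered at `center`), ridge-
## regularized if numerically singular.
.half_logdet_cov <- function(X, center) {
  n <- nrow(X); d <- ncol(X)
  Xc <- sweep(X, 2L, center)
  C <- crossprod(Xc) / (n - 1)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance; applying ridge regularization")
    C <- C + diag(1e-9 * sum(diag(C)) / d, d)
    ch <- chol(C)
  }
  sum(log(diag(ch)))
}

## Raw (unfloored) Gaussian-model MI in bits between copula scores Z [n x d]
## and a two-level label vector.
.mi_model_raw <- function(Z, s) {
  n <- nrow(Z); d <- ncol(Z)
  lev <- unique(s)
  if (length(lev) != 2L) stop("labels must have exactly two classes")
  i1 <- s == lev[1L]
  n1 <- sum(i1); n0 <- n - n1
  if (min(n1, n0) < 2L) stop("both classes need at least 2 trials")
  H  <- .half_logdet_cov(Z, colMeans(Z)) + .ent_bias(n, d)
  Z1 <- Z[i1, , drop = FALSE]; Z0 <- Z[!i1, , drop = FALSE]
  H1 <- .half_logdet_cov(Z1, colMeans(Z1)) + .ent_bias(n1, d)
  H0 <- .half_logdet_cov(Z0, colMeans(Z0)) + .ent_bias(n0, d)
  (H - (n1 / n) * H1 - (n0 / n) * H0) / log(2)
}

## ---- public estimator -------------------------------------------------------

#' Mutual information between a continuous response and a binary class
#'
#' @param x numeric vector or `[trial x dim]` matrix of continuous responses.
#' @param s label vector with exactly two levels (e.g. standard/deviant).
#' @param floor if `TRUE` (default), negative estimates are floored at 0 for
#'   reporting. Permutation-null machinery uses `floor = FALSE`: flooring
#'   would bias the null quantiles.
#' @return MI in bits (per sample). See [bits_per_second()] to convert to an
#'   information rate.
#' @details The per-class trial count must be at least three times the
#'   response dimension, so the class covariances are well conditioned.
#' @export
mi_mixed <- function(x, s, floor = TRUE) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(X) != length(s)) stop("length of `s` must match rows of `x`")
  lev <- unique(s)
  if (length(lev) != 2L) stop("labels must have exactly two classes")
  ncls <- min(sum(s == lev[1L]), sum(s != lev[1L]))
  if (ncol(X) > ncls / 3)
    stop(sprintf("dim (%d) too large for per-class trial count (%d); need dim <= n_class/3",
                 ncol(X), ncls))
  Z <- .copula_cols(X)
  mi <- .mi_model_raw(Z, s)
  if (floor) max(mi, 0) else mi
}

## ---- vectorized kernels (shared by the chart and permutation machinery) -----

## Raw 1-D MI in bits for every column of a score matrix Z [n x m], for one
## label split given as a logical vector. Uses sufficient statistics only.
.mi_cols_1d <- function(Z, i1) {
  n <- nrow(Z)
  n1 <- sum(i1); n0 <- n - n1
  Z2 <- Z * Z
  cs <- colSums(Z); vs <- colSums(Z2)
  m1 <- colSums(Z[i1, , drop = FALSE]); v1 <- colSums(Z2[i1, , drop = FALSE])
  m0 <- cs - m1; v0 <- vs - v1
  eps <- .Machine$double.eps
  vC  <- pmax((vs - cs^2 / n)  / (n - 1), eps)
  vC1 <- pmax((v1 - m1^2 / n1) / (n1 - 1), eps)
  vC0 <- pmax((v0 - m0^2 / n0) / (n0 - 1), eps)
  b  <- .ent_bias(n, 1L); b1 <- .ent_bias(n1, 1L); b0 <- .ent_bias(n0, 1L)
  (0.5 * log(vC) + b -
     (n1 / n) * (0.5 * log(vC1) + b1) -
     (n0 / n) * (0.5 * log(vC0) + b0)) / log(2)
}

## As .mi_cols_1d but for B label splits at once. P is a [B x n] 0/1 matrix
## (rows: splits, 1 = class 1); every row must have the same class-1 count.
## Returns a [B x m] matrix of raw MI values in bits.
.mi_cols_1d_perm <- function(Z, P) {
  n <- nrow(Z)
  n1 <- sum(P[1L, ]); n0 <- n - n1
  Z2 <- Z * Z
  cs <- colSums(Z); vs <- colSums(Z2)
  M1 <- P %*% Z; V1 <- P %*% Z2
  M0 <- sweep(-M1, 2L, cs, "+"); V0 <- sweep(-V1, 2L, vs, "+")
  eps <- .Machine$double.eps
  vC  <- pmax((vs - cs^2 / n) / (n - 1), eps)            # split-independent
  vC1 <- pmax((V1 - M1^2 / n1) / (n1 - 1), eps)
  vC0 <- pmax((V0 - M0^2 / n0) / (n0 - 1), eps)
  b  <- .ent_bias(n, 1L); b1 <- .ent_bias(n1, 1L); b0 <- .ent_bias(n0, 1L)
  H <- 0.5 * log(vC) + b
  out <- sweep(-((n1 / n) * (0.5 * log(vC1) + b1) +
                   (n0 / n) * (0.5 * log(vC0) + b0)), 2L, H, "+")
  out / log(2)
}

## Raw 2-D joint MI in bits for every column pair (i of Za, j of Zb).
## Za [n x Ta], Zb [n x Tb], i1 logical class-1 membership.
## Returns a [Ta x Tb] matrix. Near-singular 2x2 determinants are floored
## relative to the variance product (ridge in determinant form).
.mi_pairs_2d <- function(Za, Zb, i1) {
  n <- nrow(Za)
  n1 <- sum(i1); n0 <- n - n1
  half_logdet <- function(A, B, idx, nn) {
    A <- A[idx, , drop = FALSE]; B <- B[idx, , drop = FALSE]
    Ac <- sweep(A, 2L, colMeans(A)); Bc <- sweep(B, 2L, colMeans(B))
    va <- colSums(Ac * Ac) / (nn - 1)
    vb <- colSums(Bc * Bc) / (nn - 1)
    Cab <- crossprod(Ac, Bc) / (nn - 1)
    det2 <- outer(va, vb) - Cab^2
    det2 <- pmax(det2, 1e-12 * outer(va, vb))
    0.5 * log(det2)
  }
  all_idx <- rep(TRUE, n)
  b  <- .ent_bias(n, 2L); b1 <- .ent_bias(n1, 2L); b0 <- .ent_bias(n0, 2L)
  H  <- half_logdet(Za, Zb, all_idx, n)  + b
  H1 <- half_logdet(Za, Zb, i1, n1)      + b1
  H0 <- half_logdet(Za, Zb, !i1, n0)     + b0
  (H - (n1 / n) * H1 - (n0 / n) * H0) / log(2)
}
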