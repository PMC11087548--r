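#' Multivariate co-information via cross-validated decision values
#'
#' To capture stimulus information carried by spatial patterns across a whole
#' region, a regularized linear-discriminant classifier is trained per
#' timepoint with stratified 10-fold cross-validation; the out-of-fold
#' decision values (signed distance to the discriminant hyperplane, before
#' thresholding) reduce the multichannel pattern to one scalar per trial.
#' Co-information between the decision-value signals of two decoders
#' (different timepoints and/or regions) then quantifies redundancy and
#' synergy between whole-region representations. The joint-information term
#' is the maximum of three estimates (max single-region MI, MI of the 2-D
#' decision-value pair, MI of a joint decoder trained on both regions'
#' channels), each a lower bound on the joint information.
#'
#' @name mvcoi
NULL

## ---- regularized LDA --------------------------------------------------------

## Ledoit-Wolf shrinkage of a pooled within-class covariance toward a scaled
## identity. X: [n x p] with class means already removed.
.lw_cov <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) return(diag(mu, p))
  xs2 <- rowSums(Xc^2)
  # (1/n^2) * sum_k || x_k x_k' - S ||_F^2
  b2 <- (sum(xs2^2) / n - sum(S^2)) / n
  rho <- min(1, max(0, b2 / d2))
  rho * diag(mu, p) + (1 - rho) * S
}

## Fit a binary shrinkage-LDA; returns the weight vector and offset such
## that dval = X %*% w + b is the signed distance-like discriminant score.
.lda_fit <- function(X, y1) {
  m1 <- colMeans(X[y1, , drop = FALSE])
  m0 <- colMeans(X[!y1, , drop = FALSE])
  Xc <- X
  Xc[y1, ] <- sweep(X[y1, , drop = FALSE], 2L, m1)
  Xc[!y1, ] <- sweep(X[!y1, , drop = FALSE], 2L, m0)
  S <- .lw_cov(Xc)
  w <- solve(S, m1 - m0)
  list(w = w, b = -sum(w * (m1 + m0) / 2))
}

## Stratified k-fold assignment (balanced per class, counts differ by <= 1).
.stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## Out-of-fold decision values for one feature matrix [n x p].
.cv_dvals <- function(X, y1, fold) {
  dv <- numeric(nrow(X))
  for (f in unique(fold)) {
    te <- fold == f
    fit <- .lda_fit(X[!te, , drop = FALSE], y1[!te])
    dv[te] <- X[te, , drop = FALSE] %*% fit$w + fit$b
  }
  dv
}

## ---- decision values --------------------------------------------------------

#' Cross-validated LDA decision values for every timepoint of a region
#'
#' Folds are stratified by class and, within one call, the same fold
#' partition is reused across all timepoints so temporal comparisons share
#' partitions. Every trial's decision value comes from a model never trained
#' on that trial.
#'
#' @param x an [epoch_set] (balanced internally).
#' @param region region tag selecting the channels (`"temporal"`,
#'   `"frontal"`, `"other"`), or `NULL` for all channels.
#' @param k number of folds (default 10).
#' @param seed integer seed (balancing + folding).
#' @param decim keep every `decim`-th timepoint.
#' @return An object of class `decision_values`: `dval` (`[trial x time]`),
#'   `fold_id`, `region`, `trained_time` (ms), `labels`.
#' @export
lda_cv_dvals <- function(x, region = NULL, k = 10, seed = 1, decim = 1) {
  stopifnot(inherits(x, "epoch_set"))
  x <- balance_trials(x, seed = seed)
  ch <- if (is.null(region)) seq_len(dim(x$data)[2L])
        else which(x$regions == region)
  if (length(ch) < 1) stop("region has no channels")
  keep <- seq(1L, dim(x$data)[3L], by = decim)
  y1 <- x$labels == "deviant"
  fold <- .stratified_folds(x$labels, k, seed)
  dv <- vapply(keep, function(t)
    .cv_dvals(matrix(x$data[, ch, t], nrow = dim(x$data)[1L]), y1, fold),
    numeric(dim(x$data)[1L]))
  structure(list(dval = dv, fold_id = fold, region = region %||% "all",
                 trained_time = epoch_times(x)[keep], labels = x$labels),
            class = "decision_values")
}

## ---- joint information ------------------------------------------------------

#' Joint stimulus information for a pair of decision-value signals
#'
#' Maximum of three lower-bound estimates of `I(X,Y;S)`: (i) the larger
#' single-signal MI (the data-processing inequality makes it a lower bound on
#' the joint), (ii) MI of the 2-D decision-value pair, and (iii) MI of
#' cross-validated decision values from a joint decoder trained on the
#' concatenated channels of both regions (which can capture between-region
#' synergy).
#'
#' @param dval_a,dval_b decision-value vectors (aligned trials).
#' @param s binary label vector.
#' @param x_joint optional `[trial x features]` matrix of concatenated
#'   channels from both regions at the two timepoints; if supplied, estimate
#'   (iii) is included.
#' @param k,seed folding parameters for the joint decoder.
#' @return Joint MI in bits (unfloored maximum of the estimates).
#' @export
joint_info <- function(dval_a, dval_b, s, x_joint = NULL, k = 10, seed = 1) {
  if (length(dval_a) != length(dval_b) || length(dval_a) != length(s))
    stop("trial misalignment between decision values and labels")
  za <- copula_normalize(dval_a); zb <- copula_normalize(dval_b)
  ia <- .mi_model_raw(matrix(za), s)
  ib <- .mi_model_raw(matrix(zb), s)
  est <- c(max(ia, ib), .mi_model_raw(cbind(za, zb), s))
  if (!is.null(x_joint)) {
    y1 <- s == unique(s)[1]  # either level; MI is symmetric in labels
    fold <- .stratified_folds(s, k, seed)
    dvj <- .cv_dvals(x_joint, y1, fold)
    est <- c(est, .mi_model_raw(matrix(copula_normalize(dvj)), s))
  }
  max(est)
}

## ---- batched CV decoders ----------------------------------------------------

## Cross-validated decision values for a whole chart at once: per-timepoint
## decoders of region A and region B plus the joint decoder of every
## timepoint pair, all sharing one fold partition and one label vector.
## Amat/Bmat are [n x (p*T)] with columns grouped per timepoint. Per fold,
## class means and the full training cross-covariance are computed once and
## every decoder solves a small subset system (with the same Ledoit-Wolf
## shrinkage as .lda_fit). For within-region charts the diagonal joint
## decoder is degenerate and is replaced by the single-timepoint decoder.
.cv_dvals_grid <- function(Amat, pA, Bmat, pB, y1, fold, within) {
  n <- nrow(Amat); Tn <- ncol(Amat) %/% pA
  X <- cbind(Amat, Bmat)
  dva <- matrix(0, n, Tn); dvb <- matrix(0, n, Tn)
  dvj <- matrix(0, n, Tn * Tn)
  for (f in unique(fold)) {
    te <- which(fold == f); tr <- which(fold != f)
    y_tr <- y1[tr]; ntr <- length(tr)
    Xtr <- X[tr, , drop = FALSE]
    m1 <- colMeans(Xtr[y_tr, , drop = FALSE])
    m0 <- colMeans(Xtr[!y_tr, , drop = FALSE])
    Xc <- Xtr
    Xc[y_tr, ] <- sweep(Xtr[y_tr, , drop = FALSE], 2L, m1)
    Xc[!y_tr, ] <- sweep(Xtr[!y_tr, , drop = FALSE], 2L, m0)
    S <- crossprod(Xc) / ntr
    dm <- m1 - m0
    Xte <- X[te, , drop = FALSE]
    solve_dec <- function(idx) {
      Ssub <- S[idx, idx, drop = FALSE]
      p <- length(idx)
      mu <- sum(diag(Ssub)) / p
      d2 <- sum((Ssub - diag(mu, p))^2)
      if (d2 > .Machine$double.eps) {
        xs2 <- rowSums(Xc[, idx, drop = FALSE]^2)
        b2 <- (sum(xs2^2) / ntr - sum(Ssub^2)) / ntr
        rho <- min(1, max(0, b2 / d2))
        Ssub <- rho * diag(mu, p) + (1 - rho) * Ssub
      } else Ssub <- diag(mu, p)
      w <- solve(Ssub, dm[idx])
      drop(Xte[, idx, drop = FALSE] %*% w) - sum(w * (m1[idx] + m0[idx]) / 2)
    }
    offB <- Tn * pA
    for (t in seq_len(Tn)) {
      ia <- ((t - 1) * pA + 1):(t * pA)
      dva[te, t] <- solve_dec(ia)
      ib <- offB + ((t - 1) * pB + 1):(t * pB)
      dvb[te, t] <- if (within) dva[te, t] else solve_dec(ib)
    }
    for (j in seq_len(Tn)) for (i in seq_len(Tn)) {
      if (within && i == j) next
      ia <- ((i - 1) * pA + 1):(i * pA)
      ib <- offB + ((j - 1) * pB + 1):(j * pB)
      dvj[te, (j - 1) * Tn + i] <- solve_dec(c(ia, ib))
    }
  }
  if (within)
    for (t in seq_len(Tn)) dvj[, (t - 1) * Tn + t] <- dva[, t]
  list(dva = dva, dvb = dvb, dvj = dvj)
}

## chart statistics (marginal MI vectors, max-of-three joint, co-I matrix)
## for one label split, given the grid of decision values
.mvcoi_stats <- function(grid, y1, within) {
  Za <- .copula_cols(grid$dva)
  Zb <- if (within) Za else .copula_cols(grid$dvb)
  Tn <- ncol(Za)
  ia <- .mi_cols_1d(Za, y1)
  ib <- if (within) ia else .mi_cols_1d(Zb, y1)
  ZJ <- .copula_cols(grid$dvj)
  joint <- pmax(outer(ia, ib, pmax),
                .mi_pairs_2d(Za, Zb, y1),
                matrix(.mi_cols_1d(ZJ, y1), Tn, Tn))
  coi <- outer(ia, ib, "+") - joint
  if (within) diag(coi) <- ia
  list(coi = coi, ia = ia, ib = ib)
}

## ---- MVCo-I charts ----------------------------------------------------------

#' Multivariate co-information chart between (or within) regions
#'
#' Cell `(t1, t2)` is `I(dvalA(t1);S) + I(dvalB(t2);S) - Ijoint`, where the
#' decision values come from per-timepoint cross-validated decoders of each
#' region and `Ijoint` is the [joint_info()] maximum (including a joint
#' decoder trained on both regions' channels at the two timepoints). The
#' within-region variant (`region_a == region_b`) uses two timepoints of one
#' region's decoders; its diagonal is the per-timepoint decoder MI.
#' Significance masks come from label-permutation maximum statistics with the
#' decision values held fixed (only the MI estimation is permuted).
#'
#' @inheritParams lda_cv_dvals
#' @param region_a,region_b region tags for the two axes.
#' @param n_perm permutations for the significance masks.
#' @param alpha total family-wise error rate.
#' @return A `coi_chart` object (axes carry the regions), plus element
#'   `dvals` with the two `decision_values` objects.
#' @export
mvcoi_chart <- function(x, region_a, region_b = region_a, k = 10,
                        n_perm = 1000, seed = 1, alpha = 0.05, decim = 1) {
  stopifnot(inherits(x, "epoch_set"))
  .check_nperm(n_perm)
  x <- balance_trials(x, seed = seed)
  within <- identical(region_a, region_b)
  n <- dim(x$data)[1L]
  y1 <- x$labels == "deviant"
  fold <- .stratified_folds(x$labels, k, seed)
  cha <- which(x$regions == region_a)
  chb <- which(x$regions == region_b)
  if (length(cha) < 1 || length(chb) < 1) stop("region has no channels")
  keep <- seq(1L, dim(x$data)[3L], by = decim)
  Tn <- length(keep)
  Amat <- matrix(x$data[, cha, keep], n)
  Bmat <- matrix(x$data[, chb, keep], n)
  grid <- .cv_dvals_grid(Amat, length(cha), Bmat, length(chb), y1, fold,
                         within)
  obs <- .mvcoi_stats(grid, y1, within)$coi
  # permutation null with full decoder retraining: the out-of-fold decision
  # values of cross-validated decoders are weakly coupled to their training
  # labels even under the null, so permuting labels against fixed decision
  # values is anticonservative; each permutation therefore re-stratifies the
  # folds and refits every decoder on the permuted labels
  P <- .perm_matrix(n, sum(y1), n_perm, seed)
  maxs <- numeric(n_perm); mins <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- P[b, ] == 1
    foldp <- .stratified_folds(ifelse(yp, "a", "b"), k, seed + b)
    gridp <- .cv_dvals_grid(Amat, length(cha), Bmat, length(chb), yp,
                            foldp, within)
    cp <- .mvcoi_stats(gridp, yp, within)$coi
    maxs[b] <- max(cp); mins[b] <- min(cp)
  }
  upper <- stats::quantile(maxs, 1 - alpha / 2, names = FALSE)
  lower <- stats::quantile(mins, alpha / 2, names = FALSE)
  times <- epoch_times(x)[keep]
  dva <- structure(list(dval = grid$dva, fold_id = fold, region = region_a,
                        trained_time = times, labels = x$labels),
                   class = "decision_values")
  dvb <- structure(list(dval = grid$dvb, fold_id = fold, region = region_b,
                        trained_time = times, labels = x$labels),
                   class = "decision_values")
  structure(list(
    coi = obs,
    sig_redundant = obs > upper & obs > 0,
    sig_synergistic = obs < lower & obs < 0,
    thresholds = c(upper = upper, lower = lower),
    times_x = times, times_y = times,
    axes = list(x = list(region = region_a, signal = "dval"),
                y = list(region = region_b, signal = "dval")),
    symmetric = within, n_perm = n_perm,
    meta = list(sided = "separate max/min statistics at alpha/2 per sign",
                alpha = alpha, k = k,
                folds = "stratified, reused across timepoints",
                null = "decoders retrained per permutation"),
    dvals = list(a = dva, b = dvb)),
    class = "coi_chart")
}
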