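#' SSIM-based comparison of co-information charts
#'
#' To compare the structure of two co-I charts (e.g. simulated vs recorded),
#' both are min-max normalized to [0, 1] on a common scale and the Structural
#' Similarity Index (SSIM; 11 x 11 Gaussian window, standard stabilization
#' constants, dynamic range 1) is computed between the resulting images.
#' Chance level is assessed by shuffling the pixels of the second image and
#' recomputing the score 1000 times.
#'
#' @name compare
NULL

#' Convert one or two co-I charts to normalized images
#'
#' Min-max normalizes to [0, 1]; when a pair is given, a common scale (the
#' pooled min and max) is used so relative magnitudes are preserved, and the
#' second image is resampled (bilinear) to the first's grid if the shapes
#' differ.
#'
#' @param chart a `coi_chart` or numeric matrix.
#' @param chart2 optional second chart/matrix.
#' @return A normalized matrix, or a list of two when `chart2` is given.
#' @export
chart_to_image <- function(chart, chart2 = NULL) {
  m1 <- if (inherits(chart, "coi_chart")) chart$coi else chart
  if (any(!is.finite(m1))) stop("chart contains non-finite values")
  if (is.null(chart2)) {
    rg <- range(m1)
    if (diff(rg) == 0) stop("zero dynamic range: chart is constant")
    return((m1 - rg[1]) / diff(rg))
  }
  m2 <- if (inherits(chart2, "coi_chart")) chart2$coi else chart2
  if (any(!is.finite(m2))) stop("chart contains non-finite values")
  if (!identical(dim(m1), dim(m2))) m2 <- .resample_bilinear(m2, dim(m1))
  rg <- range(c(m1, m2))
  if (diff(rg) == 0) stop("zero dynamic range: charts are constant")
  list((m1 - rg[1]) / diff(rg), (m2 - rg[1]) / diff(rg))
}

## bilinear resampling of a matrix onto a new grid
.resample_bilinear <- function(m, dims) {
  nr <- dims[1]; nc <- dims[2]
  xi <- seq(1, nrow(m), length.out = nr)
  yi <- seq(1, ncol(m), length.out = nc)
  x0 <- pmin(floor(xi), nrow(m) - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), ncol(m) - 1L); fy <- yi - y0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    c0 <- m[, y0[j]] * (1 - fy[j]) + m[, y0[j] + 1L] * fy[j]
    out[, j] <- c0[x0] * (1 - fx) + c0[x0 + 1L] * fx
  }
  out
}

## 2-d 'valid' convolution with a separable Gaussian kernel
.gauss_filter_valid <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  nr <- nrow(m) - 2L * r; nc <- ncol(m) - 2L * r
  tmp <- matrix(0, nr, ncol(m))
  for (k in -r:r) tmp <- tmp + kern[k + r + 1L] * m[(1L + r + k):(nr + r + k), ]
  out <- matrix(0, nr, nc)
  for (k in -r:r) out <- out + kern[k + r + 1L] * tmp[, (1L + r + k):(nc + r + k)]
  out
}

#' Structural Similarity Index between two images
#'
#' Standard SSIM with an 11 x 11 Gaussian weighting window (sigma 1.5),
#' stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic
#' range `L = 1`, averaged over all fully-interior windows.
#'
#' @param a,b numeric matrices of identical shape, values in [0, 1].
#' @param data_range dynamic range `L` (default 1).
#' @return The mean SSIM score.
#' @export
ssim <- function(a, b, data_range = 1) {
  if (!identical(dim(a), dim(b))) stop("image shape mismatch")
  if (min(dim(a)) < 11) stop("images must be at least 11 x 11")
  sig <- 1.5
  kern <- exp(-((-5:5)^2) / (2 * sig^2)); kern <- kern / sum(kern)
  mu_a <- .gauss_filter_valid(a, kern)
  mu_b <- .gauss_filter_valid(b, kern)
  va <- .gauss_filter_valid(a * a, kern) - mu_a^2
  vb <- .gauss_filter_valid(b * b, kern) - mu_b^2
  cab <- .gauss_filter_valid(a * b, kern) - mu_a * mu_b
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Shuffle-surrogate significance test for an SSIM score
#'
#' Computes the observed SSIM between two chart images, then builds a
#' surrogate distribution by shuffling the pixel positions of the second
#' image `n` times. The p-value is `(1 + #{surrogate >= observed}) /
#' (n + 1)`. Scores are reported clipped to [0, 1].
#'
#' @param chart_a,chart_b charts or matrices (normalized jointly via
#'   [chart_to_image()]).
#' @param n number of surrogates (default 1000).
#' @param seed integer seed.
#' @return An `ssim_result`: `ssim` (clipped to [0, 1]), `surrogate`
#'   (length-`n` scores), `p`.
#' @export
ssim_surrogate_test <- function(chart_a, chart_b, n = 1000, seed = 1) {
  if (n < 100) warning("fewer than 100 surrogates: p-value is coarse")
  im <- chart_to_image(chart_a, chart_b)
  obs <- ssim(im[[1]], im[[2]])
  d <- dim(im[[2]])
  surr <- with_seed(seed, vapply(seq_len(n), function(i)
    ssim(im[[1]], matrix(sample(im[[2]]), d[1], d[2])), 0))
  structure(list(ssim = min(max(obs, 0), 1), raw_ssim = obs,
                 surrogate = surr,
                 p = (1 + sum(surr >= obs)) / (n + 1), n = n),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("SSIM = %.3f (p = %.4f, %d pixel-shuffle surrogates)\n",
              x$ssim, x$p, x$n))
  invisible(x)
}
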