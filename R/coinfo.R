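#' Co-information analysis of paired neural signals
#'
#' Co-information decomposes the stimulus information carried by two signals:
#' `coI(X;Y;S) = I(X;S) + I(Y;S) - I(X,Y;S)`. Positive co-I is redundancy
#' (shared information about the stimulus class); negative co-I is synergy
#' (extra information available only from the joint response). MI terms are
#' estimated with the Gaussian-copula estimator ([mi_mixed]); significance is
#' assessed with label-permutation maximum statistics, which controls the
#' family-wise error rate across all tested timepoints (and cells) at 0.05.
#'
#' @name coinfo
NULL

## B label permutations as a [B x n] 0/1 indicator matrix (1 = class 1).
## One stream is shared across all cells of a chart, preserving cross-cell
## dependence, as is standard for maximum statistics.
.perm_matrix <- function(n, n1, B, seed) {
  with_seed(seed, {
    P <- matrix(0, B, n)
    for (b in seq_len(B)) P[b, sample.int(n, n1)] <- 1
    P
  })
}

.check_nperm <- function(n_perm) {
  if (n_perm < 100)
    warning("fewer than 100 permutations: threshold quantile is unstable")
}

## ---- MI time series ---------------------------------------------------------

#' MI time series for one channel with permutation max-statistics
#'
#' For every timepoint, MI between the single-channel response and the trial
#' class; the null is built from label permutations, taking each
#' permutation's maximum over timepoints, and the 95th percentile of those
#' maxima is the significance threshold (FWER 0.05 over the time family).
#'
#' @param x an [epoch_set] (balanced internally via [balance_trials] if
#'   needed).
#' @param channel channel index.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for balancing and permutations.
#' @param alpha family-wise error rate (default 0.05).
#' @return An object of class `mi_series`: `mi` (bits, floored at 0), `raw`
#'   (unfloored), `threshold`, `sig` (`raw > threshold`), `n_perm`,
#'   `times_ms`, `channel`.
#' @export
mi_timeseries <- function(x, channel, n_perm = 1000, seed = 1,
                          alpha = 0.05) {
  stopifnot(inherits(x, "epoch_set"))
  .check_nperm(n_perm)
  x <- balance_trials(x, seed = seed)
  Z <- .copula_cols(x$data[, channel, ])
  i1 <- x$labels == "deviant"
  raw <- .mi_cols_1d(Z, i1)
  P <- .perm_matrix(length(i1), sum(i1), n_perm, seed)
  null_max <- apply(.mi_cols_1d_perm(Z, P), 1L, max)
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  structure(list(mi = pmax(raw, 0), raw = raw, threshold = thr,
                 sig = raw > thr, n_perm = n_perm,
                 times_ms = epoch_times(x), channel = channel),
            class = "mi_series")
}

#' MI map over all channels and timepoints with a single max-statistics family
#'
#' Computes MI for every channel and timepoint and thresholds all of them as
#' one family: each label permutation contributes its maximum over all
#' channels and timepoints, so the dataset-wide FWER is `alpha`.
#'
#' @inheritParams mi_timeseries
#' @return List with `mi` (`[channel x time]`, floored), `raw`, `threshold`,
#'   `sig` mask, `series` (per-channel `mi_series` sharing the common
#'   threshold), `n_perm`, `times_ms`.
#' @export
mi_map <- function(x, n_perm = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(x, "epoch_set"))
  .check_nperm(n_perm)
  x <- balance_trials(x, seed = seed)
  d <- dim(x$data)
  Z <- .copula_cols(matrix(x$data, d[1], d[2] * d[3]))
  i1 <- x$labels == "deviant"
  raw <- matrix(.mi_cols_1d(Z, i1), d[2], d[3])
  P <- .perm_matrix(d[1], sum(i1), n_perm, seed)
  null_max <- apply(.mi_cols_1d_perm(Z, P), 1L, max)
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  times <- epoch_times(x)
  series <- lapply(seq_len(d[2]), function(ch)
    structure(list(mi = pmax(raw[ch, ], 0), raw = raw[ch, ],
                   threshold = thr, sig = raw[ch, ] > thr,
                   n_perm = n_perm, times_ms = times, channel = ch),
              class = "mi_series"))
  list(mi = pmax(raw, 0), raw = raw, threshold = thr, sig = raw > thr,
       series = series, n_perm = n_perm, times_ms = times)
}

## ---- scalar co-information --------------------------------------------------

#' Co-information between two responses about the trial class
#'
#' `coI = I(X;S) + I(Y;S) - I(X,Y;S)` with unfloored Gaussian-copula MI
#' terms. Positive values indicate redundancy, negative synergy.
#'
#' @param x,y numeric response vectors (equal length).
#' @param s binary label vector.
#' @return Co-information in bits.
#' @export
coinformation <- function(x, y, s) {
  if (length(x) != length(y)) stop("x and y must have equal trial counts")
  zx <- copula_normalize(x); zy <- copula_normalize(y)
  ix <- .mi_model_raw(matrix(zx), s)
  iy <- .mi_model_raw(matrix(zy), s)
  ij <- .mi_model_raw(cbind(zx, zy), s)
  ix + iy - ij
}

## ---- co-information charts --------------------------------------------------

## internal: build a coi_chart object with two-sided max-statistics masks.
## obs: observed coi matrix; perm_fun(i1perm) -> coi matrix for one split.
.coi_chart <- function(obs, Za, Zb, i1, symmetric, n_perm, seed, alpha,
                       times_x, times_y, axes) {
  n <- nrow(Za)
  P <- .perm_matrix(n, sum(i1), n_perm, seed)
  maxs <- numeric(n_perm); mins <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ip <- P[b, ] == 1
    i1a <- .mi_cols_1d(Za, ip)
    i1b <- if (symmetric) i1a else .mi_cols_1d(Zb, ip)
    cp <- outer(i1a, i1b, "+") - .mi_pairs_2d(Za, Zb, ip)
    if (symmetric) diag(cp) <- i1a
    maxs[b] <- max(cp); mins[b] <- min(cp)
  }
  # two-sided control: redundancy and synergy thresholded separately at
  # alpha/2 each, total FWER ~ alpha
  upper <- stats::quantile(maxs, 1 - alpha / 2, names = FALSE)
  lower <- stats::quantile(mins, alpha / 2, names = FALSE)
  structure(list(
    coi = obs,
    sig_redundant = obs > upper & obs > 0,
    sig_synergistic = obs < lower & obs < 0,
    thresholds = c(upper = upper, lower = lower),
    times_x = times_x, times_y = times_y, axes = axes,
    symmetric = symmetric, n_perm = n_perm,
    meta = list(sided = "separate max/min statistics at alpha/2 per sign",
                alpha = alpha)),
    class = "coi_chart")
}

#' Temporal co-information chart within one channel
#'
#' `chart[t1, t2] = coI(x(t1); x(t2); S)` over all timepoint pairs of one
#' channel's signal; symmetric by construction. The diagonal is defined as
#' the MI at that timepoint (the limit of `y = x + e` as `e -> 0`).
#' Two-sided permutation maximum statistics over all cells yield disjoint
#' redundancy (`coi > 0`) and synergy (`coi < 0`) masks at total FWER
#' `alpha`.
#'
#' @inheritParams mi_timeseries
#' @param decim keep every `decim`-th timepoint (runtime control; default 1 =
#'   every 2 ms sample at 500 Hz).
#' @return A `coi_chart` object.
#' @export
temporal_coi_chart <- function(x, channel, n_perm = 1000, seed = 1,
                               alpha = 0.05, decim = 1) {
  stopifnot(inherits(x, "epoch_set"))
  .check_nperm(n_perm)
  x <- balance_trials(x, seed = seed)
  keep <- seq(1L, dim(x$data)[3L], by = decim)
  Z <- .copula_cols(x$data[, channel, keep])
  i1 <- x$labels == "deviant"
  i1d <- .mi_cols_1d(Z, i1)
  obs <- outer(i1d, i1d, "+") - .mi_pairs_2d(Z, Z, i1)
  diag(obs) <- i1d
  times <- epoch_times(x)[keep]
  .coi_chart(obs, Z, Z, i1, symmetric = TRUE, n_perm, seed, alpha,
             times, times,
             axes = list(x = list(channel = channel, signal = x$signal_kind),
                         y = list(channel = channel, signal = x$signal_kind)))
}

#' Spatio-temporal co-information chart between two channels
#'
#' `chart[t1, t2] = coI(A(t1); B(t2); S)` between the signals of two
#' channels (typically one temporal and one frontal electrode); not symmetric
#' in general. Requesting the same channel twice delegates to
#' [temporal_coi_chart()].
#'
#' @inheritParams temporal_coi_chart
#' @param channel_a,channel_b channel indices for the X and Y axes.
#' @return A `coi_chart` object.
#' @export
spatiotemporal_coi_chart <- function(x, channel_a, channel_b, n_perm = 1000,
                                     seed = 1, alpha = 0.05, decim = 1) {
  stopifnot(inherits(x, "epoch_set"))
  if (channel_a == channel_b)
    return(temporal_coi_chart(x, channel_a, n_perm, seed, alpha, decim))
  .check_nperm(n_perm)
  x <- balance_trials(x, seed = seed)
  keep <- seq(1L, dim(x$data)[3L], by = decim)
  Za <- .copula_cols(x$data[, channel_a, keep])
  Zb <- .copula_cols(x$data[, channel_b, keep])
  i1 <- x$labels == "deviant"
  obs <- outer(.mi_cols_1d(Za, i1), .mi_cols_1d(Zb, i1), "+") -
    .mi_pairs_2d(Za, Zb, i1)
  times <- epoch_times(x)[keep]
  .coi_chart(obs, Za, Zb, i1, symmetric = FALSE, n_perm, seed, alpha,
             times, times,
             axes = list(x = list(channel = channel_a,
                                  region = x$regions[channel_a],
                                  signal = x$signal_kind),
                         y = list(channel = channel_b,
                                  region = x$regions[channel_b],
                                  signal = x$signal_kind)))
}

## ---- aggregation across subjects/runs ---------------------------------------

#' Aggregate co-information charts across subjects or simulation runs
#'
#' @param charts list of `coi_chart` objects sharing shape and axes.
#' @return List with `mean` (cell-wise mean chart), `positive_mean`
#'   (negative cells zeroed before averaging: redundancy only),
#'   `negative_mean` (synergy only), and `prop_significant` (fraction of
#'   charts significant per cell, either sign).
#' @export
aggregate_charts <- function(charts) {
  stopifnot(length(charts) >= 1,
            all(vapply(charts, inherits, TRUE, "coi_chart")))
  d <- dim(charts[[1]]$coi)
  if (!all(vapply(charts, function(ch) identical(dim(ch$coi), d), TRUE)))
    stop("charts must share the same shape")
  A <- vapply(charts, function(ch) ch$coi, charts[[1]]$coi)
  A <- array(A, c(d, length(charts)))
  S <- vapply(charts, function(ch) ch$sig_redundant | ch$sig_synergistic,
              charts[[1]]$sig_redundant)
  S <- array(S, c(d, length(charts)))
  list(mean = apply(A, c(1, 2), mean),
       positive_mean = apply(pmax(A, 0), c(1, 2), mean),
       negative_mean = apply(pmin(A, 0), c(1, 2), mean),
       prop_significant = apply(S, c(1, 2), mean),
       n = length(charts))
}

## ---- output helpers ---------------------------------------------------------

#' Write a co-information chart (and masks) as CSV + JSON metadata
#'
#' @param chart a `coi_chart`.
#' @param base path prefix; writes `<base>_coi.csv`, `<base>_sig.csv`,
#'   `<base>.json`.
#' @export
write_coi_chart <- function(chart, base) {
  utils::write.csv(chart$coi, paste0(base, "_coi.csv"), row.names = FALSE)
  sig <- matrix(0L, nrow(chart$coi), ncol(chart$coi))
  sig[chart$sig_redundant] <- 1L
  sig[chart$sig_synergistic] <- -1L
  utils::write.csv(sig, paste0(base, "_sig.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = as.list(chart$thresholds), axes = chart$axes,
         symmetric = chart$symmetric, n_perm = chart$n_perm,
         times_x = chart$times_x, times_y = chart$times_y,
         meta = chart$meta),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Plot a co-information chart in the red/blue + grey-scale layout
#'
#' Renders the full chart with a blue-white-red palette (blue = synergy,
#' red = redundancy) and, for aggregates, the proportion-significant map in
#' grey scale.
#'
#' @param chart a `coi_chart` or the output of [aggregate_charts()].
#' @param file optional PNG path; if `NULL`, plots to the active device.
#' @export
plot_coi_chart <- function(chart, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  if (inherits(chart, "coi_chart")) {
    m <- chart$coi
    lim <- max(abs(m))
    graphics::par(mfrow = c(1, 2))
    graphics::image(chart$times_x, chart$times_y, m, zlim = c(-lim, lim),
                    col = pal, xlab = "time (ms)", ylab = "time (ms)",
                    main = "co-information (bits)")
    sig <- matrix(0, nrow(m), ncol(m))
    sig[chart$sig_redundant] <- 1; sig[chart$sig_synergistic] <- -1
    graphics::image(chart$times_x, chart$times_y, sig, zlim = c(-1, 1),
                    col = pal, xlab = "time (ms)", ylab = "time (ms)",
                    main = "significant cells")
  } else {
    graphics::par(mfrow = c(1, 2))
    lim <- max(abs(chart$mean))
    graphics::image(chart$mean, zlim = c(-lim, lim), col = pal,
                    main = "mean co-information")
    graphics::image(chart$prop_significant, zlim = c(0, 1),
                    col = grDevices::grey.colors(64, 1, 0),
                    main = "proportion significant")
  }
  invisible(chart)
}
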