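#' Raw recordings to prediction-error markers (ERP and broadband)
#'
#' Two markers are extracted from each recording. The ERP path is:
#' common-average reference, anti-aliased downsampling to 500 Hz, zero-phase
#' 1--40 Hz Butterworth band-pass, epoching to the half-open [-100, 350) ms
#' window, and subtraction of the per-trial mean of the 100 ms pre-onset
#' baseline. The broadband (BB) path estimates time-resolved power spectral
#' densities per epoch, normalizes each trial's PSD by the condition-pooled
#' mean power per frequency, log-transforms, eigendecomposes the
#' across-frequency covariance (principal spectral components), projects onto
#' the first component, z-scores per trial, applies `exp(x) - 1`, and
#' subtracts the pre-stimulus mean.
#'
#' @name preproc
NULL

## ---- epoch bookkeeping ------------------------------------------------------

## Labelled tone onsets for a given contrast.
## roving: labelled tones are the first (deviant) and last (standard) of each
## train. local: 5th tone of each test train, deviant if frequency deviates.
## global: 5th tone of each test train, deviant if the pattern violates the
## block rule.
.event_onsets <- function(events, contrast = c("roving", "local", "global")) {
  contrast <- match.arg(contrast)
  if (contrast == "roving") {
    keep <- !is.na(events$status)
    data.frame(onset_ms = events$onset_ms[keep],
               label = events$status[keep])
  } else {
    fifth <- events[seq(5, nrow(events), by = 5), ]
    fifth <- fifth[fifth$phase == "test", ]
    dev <- if (contrast == "local") fifth$is_deviant else fifth$global_deviant
    data.frame(onset_ms = fifth$onset_ms,
               label = ifelse(dev, "deviant", "standard"))
  }
}

## Cut [win[1], win[2]) ms epochs around onsets from a [channel x sample]
## matrix. Epochs exceeding the record bounds are dropped with a message.
.cut_epochs <- function(rec, fs, onsets_ms, labels, win) {
  n_time <- round((win[2] - win[1]) / 1000 * fs)
  start <- round(onsets_ms / 1000 * fs) + round(win[1] / 1000 * fs) + 1L
  ok <- start >= 1L & (start + n_time - 1L) <= ncol(rec)
  if (any(!ok))
    message(sum(!ok), " epoch(s) exceeded record bounds and were dropped")
  start <- start[ok]; labels <- labels[ok]
  dat <- array(0, c(length(start), nrow(rec), n_time))
  for (k in seq_along(start))
    dat[k, , ] <- rec[, start[k]:(start[k] + n_time - 1L)]
  list(data = dat, labels = labels)
}

## common-average reference: subtract the cross-channel mean at every sample
.car <- function(rec) {
  if (nrow(rec) < 2) stop("common average reference needs at least 2 channels")
  sweep(rec, 2L, colMeans(rec))
}

## ---- ERP --------------------------------------------------------------------

#' Extract ERP epochs from a continuous recording
#'
#' @param x a recording list as returned by [gen_oddball_recording()]
#'   (elements `record`, `fs`, `events`, `regions`), with `fs >= 1000`.
#' @param contrast which deviance labelling to use: `"roving"` (first/last
#'   tone of each train), `"local"` or `"global"` (5th-tone contrasts).
#' @param band band-pass edges in Hz (zero-phase Butterworth).
#' @param order Butterworth order (applied forward-backward).
#' @param window epoch window in ms, half-open.
#' @return An [epoch_set] with `signal_kind = "erp"` at 500 Hz.
#' @export
erp_extract <- function(x, contrast = c("roving", "local", "global"),
                        band = c(1, 40), order = 4,
                        window = c(-100, 350)) {
  contrast <- match.arg(contrast)
  stopifnot(is.list(x), !is.null(x$record), !is.null(x$fs))
  if (x$fs < 1000) stop("raw input must be sampled at >= 1000 Hz")
  fs_target <- 500
  rec <- .car(x$record)
  q <- x$fs / fs_target
  if (q != round(q)) stop("fs must be an integer multiple of 500 Hz")
  if (q > 1)   # anti-aliased decimation, per channel
    rec <- t(apply(rec, 1L, function(v)
      signal::decimate(v, q, ftype = "iir")))
  bf <- signal::butter(order, band / (fs_target / 2), type = "pass")
  rec <- t(apply(rec, 1L, function(v) signal::filtfilt(bf, v)))
  ev <- .event_onsets(x$events, contrast)
  ep <- .cut_epochs(rec, fs_target, ev$onset_ms, ev$label, window)
  # per-trial baseline: mean of the 100 ms pre-onset window
  n_pre <- round(-window[1] / 1000 * fs_target)
  base <- apply(ep$data[, , seq_len(n_pre), drop = FALSE], c(1, 2), mean)
  dat <- sweep(ep$data, c(1, 2), base)
  epoch_set(dat, fs_target, window, ep$labels, x$regions, "erp")
}

## ---- broadband --------------------------------------------------------------

## Short-time Welch PSD of one epoch vector: windows of `nwin` samples with
## hop `nhop`; within each window, three half-length Hann-tapered
## sub-segments (50% overlap) are averaged, trading frequency resolution for
## the periodogram-variance reduction the spectral PCA needs. Returns
## list(freqs, psd [freq x bins], centers (1-based sample index per bin)).
.stft_psd <- function(v, fs, nwin, nhop) {
  starts <- seq(1L, length(v) - nwin + 1L, by = nhop)
  nseg <- nwin %/% 2L
  sub_off <- c(0L, nseg %/% 2L, nwin - nseg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  nf <- nseg %/% 2 + 1L
  psd <- matrix(0, nf, length(starts))
  u <- sum(w^2)
  for (b in seq_along(starts)) {
    acc <- numeric(nf)
    for (so in sub_off) {
      seg <- v[(starts[b] + so):(starts[b] + so + nseg - 1L)] * w
      sp <- abs(stats::fft(seg))[seq_len(nf)]^2 / (u * fs)
      sp[2:(nf - 1L)] <- 2 * sp[2:(nf - 1L)]
      acc <- acc + sp
    }
    psd[, b] <- acc / length(sub_off)
  }
  list(freqs = (seq_len(nf) - 1L) * fs / nseg, psd = psd,
       centers = starts + nwin %/% 2)
}

#' Extract spectral-PCA broadband epochs
#'
#' @inheritParams erp_extract
#' @param psd_win_ms short-time PSD window length in ms (default 100, 50%
#'   overlap).
#' @param freq_range frequencies (Hz) entering the spectral PCA.
#' @param model optionally, a previously fitted spectral model (list per
#'   channel) to reuse instead of refitting.
#' @return A list with `epochs` (an [epoch_set], `signal_kind = "bb"`, 500 Hz
#'   grid) and `models` — one `spectral_model` per channel with elements
#'   `freqs`, `mean_power`, `psc_matrix` (orthonormal columns), `eigvals`
#'   (descending).
#' @details The first principal spectral component is oriented so that its
#'   mean loading above 100 Hz is positive, making broadband power increases
#'   positive. Channels with non-finite PSDs (silent channels) are flagged and
#'   excluded (their BB trace is set to zero with a warning).
#' @export
bb_extract <- function(x, contrast = c("roving", "local", "global"),
                       psd_win_ms = 100, freq_range = c(0, Inf),
                       window = c(-100, 350), model = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(is.list(x), !is.null(x$record), !is.null(x$fs))
  fs <- x$fs
  rec <- .car(x$record)
  ev <- .event_onsets(x$events, contrast)
  ep <- .cut_epochs(rec, fs, ev$onset_ms, ev$label, window)
  n_trial <- dim(ep$data)[1]; n_chan <- dim(ep$data)[2]
  nwin <- round(psd_win_ms / 1000 * fs)
  nhop <- nwin %/% 2
  fs_out <- 500
  n_out <- round((window[2] - window[1]) / 1000 * fs_out)
  t_out <- window[1] + (seq_len(n_out) - 1) * 1000 / fs_out
  bb <- array(0, c(n_trial, n_chan, n_out))
  models <- vector("list", n_chan)
  for (ch in seq_len(n_chan)) {
    # stack time-resolved PSDs over trials
    p1 <- .stft_psd(ep$data[1, ch, ], fs, nwin, nhop)
    nf_all <- length(p1$freqs)
    sel <- p1$freqs >= freq_range[1] & p1$freqs <= freq_range[2] &
      p1$freqs > 0 & p1$freqs < fs / 2
    nb <- ncol(p1$psd)
    P <- array(0, c(n_trial, sum(sel), nb))
    P[1, , ] <- p1$psd[sel, ]
    for (k in 2:n_trial)
      P[k, , ] <- .stft_psd(ep$data[k, ch, ], fs, nwin, nhop)$psd[sel, ]
    if (!all(is.finite(P)) || any(apply(P, 2, max) == 0)) {
      warning(sprintf("channel %d flagged silent/non-finite; excluded", ch))
      models[[ch]] <- NULL
      next
    }
    freqs <- p1$freqs[sel]
    if (is.null(model)) {
      mp <- apply(P, 2L, mean)                    # pooled mean power per freq
      L <- log(sweep(P, 2L, mp, "/"))             # normalized log power
      # covariance between frequencies over all (trial, bin) samples
      Lm <- matrix(aperm(L, c(1, 3, 2)), ncol = sum(sel))
      eg <- eigen(stats::cov(Lm), symmetric = TRUE)
      V <- eg$vectors
      # orient PSC1: mean loading above 100 Hz positive
      hi <- freqs > 100
      ref <- if (any(hi)) mean(V[hi, 1]) else mean(V[, 1])
      if (ref < 0) V[, 1] <- -V[, 1]
      mod <- structure(list(freqs = freqs, mean_power = mp,
                            psc_matrix = V, eigvals = eg$values),
                       class = "spectral_model")
    } else {
      mod <- model[[ch]]
      L <- log(sweep(P, 2L, mod$mean_power, "/"))
    }
    models[[ch]] <- mod
    proj <- apply(L, c(1, 3), function(v) sum(v * mod$psc_matrix[, 1]))
    # interpolate bin-centred projections back onto the epoch grid
    t_bins <- window[1] + (p1$centers[seq_len(nb)] - 1) * 1000 / fs
    for (k in seq_len(n_trial)) {
      tr <- stats::approx(t_bins, proj[k, ], xout = t_out, rule = 2)$y
      zs <- (tr - mean(tr)) / stats::sd(tr)       # z-score per trial
      bb[k, ch, ] <- exp(zs) - 1
    }
  }
  # baseline: subtract the pre-stimulus (-100..0 ms) mean per trial/channel
  pre <- t_out < 0
  base <- apply(bb[, , pre, drop = FALSE], c(1, 2), mean)
  bb <- sweep(bb, c(1, 2), base)
  es <- epoch_set(bb, fs_out, window, ep$labels, x$regions, "bb")
  list(epochs = es, models = models)
}

## ---- trial balancing & channel selection ------------------------------------

#' Equalize standard and deviant trial counts
#'
#' Randomly subsamples the majority class to the minority count (the MI
#' estimator assumes balanced classes). Deterministic given `seed`; an
#' already-balanced set is returned unchanged.
#'
#' @param x an [epoch_set].
#' @param seed integer seed.
#' @return A balanced [epoch_set].
#' @export
balance_trials <- function(x, seed = 1) {
  stopifnot(inherits(x, "epoch_set"))
  tab <- table(x$labels)
  if (length(tab) < 2 || any(tab == 0)) stop("both classes must be present")
  if (tab[1] == tab[2]) return(x)
  n_min <- min(tab)
  with_seed(seed, {
    keep <- unlist(lapply(names(tab), function(cl) {
      idx <- which(x$labels == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
    epoch_subset(x, trials = sort(keep))
  })
}

#' Select significant channels and per-region best channels
#'
#' @param mis list of `mi_series` objects (one per channel, from
#'   [mi_timeseries()] or [mi_map()]).
#' @param regions per-channel region tags.
#' @param window_ms restrict the peak search to this window (default 0--350 ms
#'   post-onset).
#' @param times_ms per-sample times; defaults to the times stored in the
#'   first series.
#' @return List with `significant` (channel indices with any supra-threshold
#'   timepoint) and `best` (named integer: for each region, the significant
#'   channel with the greatest peak MI in the window; ties go to the lower
#'   channel index). Regions with no significant channel are omitted with a
#'   warning.
#' @export
select_channels <- function(mis, regions, window_ms = c(0, 350),
                            times_ms = NULL) {
  stopifnot(length(mis) == length(regions))
  times_ms <- times_ms %||% mis[[1]]$times_ms
  sig <- which(vapply(mis, function(m) any(m$sig), TRUE))
  inwin <- times_ms >= window_ms[1] & times_ms < window_ms[2]
  best <- integer(0)
  for (rg in unique(regions)) {
    cand <- intersect(sig, which(regions == rg))
    if (length(cand) == 0) {
      warning(sprintf("no significant channel in region '%s'", rg))
      next
    }
    peaks <- vapply(cand, function(ch) max(mis[[ch]]$mi[inwin]), 0)
    best[rg] <- cand[which.max(peaks)]   # which.max: first (lowest) index wins
  }
  list(significant = sig, best = best)
}
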