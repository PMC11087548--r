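#' Synthetic inputs with known information-theoretic ground truth
#'
#' Two families of generators drive every test in the package: Gaussian trial
#' ensembles whose redundancy/synergy structure has a closed-form target under
#' the Gaussian-copula estimator, and oddball-task recordings that emulate the
#' two auditory paradigms (roving oddball; local/global) with injected
#' ERP-like deflections and broadband power increases on deviant tones.
#'
#' @name synthdata
NULL

## ---- Gaussian coding ensembles ---------------------------------------------

#' Specification of a Gaussian trial ensemble with prescribed coding structure
#'
#' @param n_trials trials per class (>= 2).
#' @param structure one of `"null"`, `"redundant"`, `"synergistic"`,
#'   `"informative-single"`.
#' @param rho correlation magnitude in `[0, 1)` (synergistic/redundant
#'   constructions).
#' @param delta class mean separation in z-units (redundant /
#'   informative-single constructions).
#' @param seed integer seed.
#' @return A `gaussian_coding_spec` list.
#' @export
gaussian_coding_spec <- function(n_trials = 500,
                                 structure = c("null", "redundant",
                                               "synergistic",
                                               "informative-single"),
                                 rho = 0.8, delta = 1, seed = 1) {
  structure <- match.arg(structure)
  if (n_trials < 2) stop("invalid spec: n_trials must be >= 2 per class")
  if (rho < 0 || rho >= 1) stop("invalid spec: rho must be in [0, 1)")
  structure(list(n_trials = as.integer(n_trials), structure = structure,
                 rho = rho, delta = delta, seed = as.integer(seed)),
            class = "gaussian_coding_spec")
}

#' Generate a two-variable Gaussian trial ensemble with known co-information
#'
#' Produces paired responses (X, Y) and balanced binary labels S whose
#' redundancy/synergy is known analytically for the Gaussian-model estimator:
#' \describe{
#'   \item{null}{X, Y, S mutually independent; truth (0, 0, 0).}
#'   \item{redundant}{X = Z + e1, Y = Z + e2 with the common source Z shifted
#'     by `delta` between classes; co-I is positive and close to I(X;S).}
#'   \item{synergistic}{standard-normal marginals in both classes, but the
#'     X-Y correlation is `+rho` in one class and `-rho` in the other; the
#'     marginals carry nothing while the joint carries
#'     `-0.5*log2(1 - rho^2)` bits, so co-I = `+0.5*log2(1 - rho^2)` (< 0).}
#'   \item{informative-single}{only X is class-shifted; co-I ~ 0.}
#' }
#'
#' The ensemble is returned as a 2-channel, 1-sample [epoch_set] so the full
#' pipeline can consume it; `analytic_truth` holds the Gaussian-model targets
#' `(I_X, I_Y, coI)` in bits.
#'
#' @param spec a [gaussian_coding_spec].
#' @param noise_sd for the redundant construction, the sd of the private
#'   noise added to each copy of the shared source (default 0.05).
#' @return A list with `epochs` (an [epoch_set], channels = X and Y) and
#'   `analytic_truth` (named numeric: `I_X`, `I_Y`, `coI`).
#' @export
gen_gaussian_trials <- function(spec, noise_sd = 0.05) {
  stopifnot(inherits(spec, "gaussian_coding_spec"))
  n <- spec$n_trials
  rho <- spec$rho; delta <- spec$delta
  with_seed(spec$seed, {
    lab <- rep(c("standard", "deviant"), each = n)
    X <- numeric(2 * n); Y <- numeric(2 * n)
    truth <- switch(spec$structure,
      "null" = {
        X <- stats::rnorm(2 * n); Y <- stats::rnorm(2 * n)
        c(I_X = 0, I_Y = 0, coI = 0)
      },
      "redundant" = {
        zshift <- ifelse(lab == "deviant", delta / 2, -delta / 2)
        Z <- stats::rnorm(2 * n) + zshift
        X <- Z + stats::rnorm(2 * n, sd = noise_sd)
        Y <- Z + stats::rnorm(2 * n, sd = noise_sd)
        s2 <- 1 + noise_sd^2
        Ix <- 0.5 * log2((s2 + delta^2 / 4) / s2)
        # near-duplicated signal: co-I ~ I(X;S)
        c(I_X = Ix, I_Y = Ix, coI = Ix)
      },
      "synergistic" = {
        # class-conditional correlation sign flip; identical N(0,1) marginals
        z1 <- stats::rnorm(2 * n); z2 <- stats::rnorm(2 * n)
        r <- ifelse(lab == "deviant", rho, -rho)
        X <- z1
        Y <- r * z1 + sqrt(1 - r^2) * z2
        Ij <- -0.5 * log2(1 - rho^2)
        c(I_X = 0, I_Y = 0, coI = -Ij)
      },
      "informative-single" = {
        X <- stats::rnorm(2 * n) + ifelse(lab == "deviant", delta / 2,
                                          -delta / 2)
        Y <- stats::rnorm(2 * n)
        Ix <- 0.5 * log2((1 + delta^2 / 4))
        c(I_X = Ix, I_Y = 0, coI = 0)
      })
    dat <- array(c(X, Y), dim = c(2 * n, 2, 1))
    # a single-sample pseudo-window: 1 sample at 500 Hz
    es <- epoch_set(dat, fs = 500, window = c(0, 2), labels = lab,
                    regions = c("temporal", "frontal"), signal_kind = "raw")
    list(epochs = es, analytic_truth = truth)
  })
}

## ---- oddball grammars -------------------------------------------------------

#' Oddball task grammar
#'
#' Describes one of the two auditory paradigms. The roving grammar presents
#' trains of 3, 5 or 11 identical tones drawn from 20 frequencies (64 ms
#' tones, 503 ms onset asynchrony); adjacent trains differ in frequency, and
#' the first tone of each train is labelled deviant, the last standard. The
#' local/global grammar presents 5-tone sequences (50 ms tones, 150 ms SOA)
#' in blocks of 25 trains, 20 standard-pattern and 5 deviant-pattern, after a
#' 20-train habituation run.
#'
#' @param task `"roving"` or `"local_global"`.
#' @param n_tone_frequencies number of tone frequencies (roving default 20).
#' @param train_lengths allowed train lengths (roving default `c(3, 5, 11)`).
#' @param tone_ms tone duration in ms.
#' @param soa_ms stimulus onset asynchrony in ms.
#' @param deviant_fraction fraction of deviant-pattern trains (local/global
#'   default 0.20).
#' @return An `oddball_grammar` list.
#' @export
oddball_grammar <- function(task = c("roving", "local_global"),
                            n_tone_frequencies = 20,
                            train_lengths = c(3, 5, 11),
                            tone_ms = NULL, soa_ms = NULL,
                            deviant_fraction = 0.20) {
  task <- match.arg(task)
  tone_ms <- tone_ms %||% if (task == "roving") 64 else 50
  soa_ms  <- soa_ms  %||% if (task == "roving") 503 else 150
  if (soa_ms < tone_ms)
    stop("invalid grammar: tones overlap (soa_ms < tone_ms)")
  structure(list(task = task, n_tone_frequencies = n_tone_frequencies,
                 train_lengths = train_lengths, tone_ms = tone_ms,
                 soa_ms = soa_ms, deviant_fraction = deviant_fraction),
            class = "oddball_grammar")
}

## tone frequency grid: 250 Hz up in quarter octaves
.tone_freqs <- function(k) 250 * 2^((seq_len(k) - 1) / 4)

## Event table for a roving sequence of n_trains trains.
.roving_events <- function(grammar, n_trains) {
  freqs <- .tone_freqs(grammar$n_tone_frequencies)
  lens <- sample(grammar$train_lengths, n_trains, replace = TRUE)
  fidx <- integer(n_trains)
  fidx[1] <- sample.int(length(freqs), 1)
  for (k in seq_len(n_trains - 1L))
    fidx[k + 1] <- sample(setdiff(seq_along(freqs), fidx[k]), 1)
  onset <- 0
  rows <- vector("list", n_trains)
  for (k in seq_len(n_trains)) {
    m <- lens[k]
    status <- rep(NA_character_, m)
    status[1] <- "deviant"; status[m] <- "standard"
    if (m == 1) status[1] <- "deviant"
    rows[[k]] <- data.frame(
      onset_ms = onset + (seq_len(m) - 1) * grammar$soa_ms,
      freq_hz = freqs[fidx[k]],
      is_deviant = c(TRUE, rep(FALSE, m - 1)),
      status = status,
      train_id = k)
    onset <- onset + m * grammar$soa_ms
  }
  do.call(rbind, rows)
}

## Event table for local/global blocks. Each block: 20-train habituation of
## the standard pattern, then 25 test trains (20 standard-pattern, 5
## deviant-pattern, shuffled, never first). Pattern xxxxx vs xxxxY.
.local_global_events <- function(grammar, n_blocks) {
  fx <- 707; fy <- 4000
  soa <- grammar$soa_ms
  rows <- list(); onset <- 0; train_id <- 0
  for (b in seq_len(n_blocks)) {
    std_is_xy <- (b %% 2 == 0)   # alternate blocks use xxxxY as the standard
    emit <- function(pattern_xy, phase) {
      train_id <<- train_id + 1
      f5 <- if (pattern_xy) fy else fx
      local_dev <- pattern_xy
      global_dev <- (phase == "test") && (pattern_xy != std_is_xy)
      df <- data.frame(
        onset_ms = onset + (0:4) * soa,
        freq_hz = c(rep(fx, 4), f5),
        is_deviant = c(rep(FALSE, 4), local_dev),
        status = NA_character_,
        train_id = train_id,
        phase = phase,
        pattern = if (pattern_xy) "xY" else "xx",
        global_deviant = global_dev)
      onset <<- onset + 5 * soa
      df
    }
    for (i in 1:20) rows[[length(rows) + 1]] <- emit(std_is_xy, "habituation")
    n_test <- 25
    n_dev <- round(grammar$deviant_fraction * n_test)
    patt <- sample(c(rep(!std_is_xy, n_dev), rep(std_is_xy, n_test - n_dev)))
    while (patt[1] != std_is_xy) patt <- sample(patt)  # never open with a deviant
    for (p in patt) rows[[length(rows) + 1]] <- emit(p, "test")
  }
  do.call(rbind, rows)
}

## difference-of-Gaussians deflection peaking near `peak_ms` after onset
.dog_bump <- function(t_ms, peak_ms, amp) {
  amp * (exp(-(t_ms - peak_ms)^2 / (2 * 35^2)) -
           0.5 * exp(-(t_ms - peak_ms)^2 / (2 * 80^2)))
}

#' Generate a continuous multichannel oddball recording
#'
#' Emulates a raw ECoG record: per-channel independent Gaussian background
#' noise plus, on deviant tones, (i) an added ERP-like difference-of-Gaussians
#' deflection peaking 150--250 ms post-onset on designated "effect" channels
#' and (ii) a multiplicative variance gain on a 70--200 Hz band-limited noise
#' carrier (the broadband marker).
#'
#' @param grammar an [oddball_grammar].
#' @param n_trains number of trains (roving) or blocks (local/global).
#' @param effects list with `erp_amp` (a.u.), `erp_latency_ms` (peak latency),
#'   `bb_gain` (multiplicative sd gain on the high-frequency carrier for
#'   deviants).
#' @param n_channels total channels; the first half are tagged temporal, the
#'   rest frontal.
#' @param effect_channels channels carrying the injected effects (default:
#'   channel 1 and the first frontal channel).
#' @param fs sampling rate of the raw record (>= 1000 Hz).
#' @param noise_sd background noise sd.
#' @param seed integer seed.
#' @return List with `record` (`[channel x sample]` matrix), `fs`, `events`
#'   (data.frame: onset_ms, freq_hz, is_deviant, status, train_id, ...), and
#'   `regions`.
#' @export
gen_oddball_recording <- function(grammar, n_trains = 60,
                                  effects = list(erp_amp = 1,
                                                 erp_latency_ms = 180,
                                                 bb_gain = 2),
                                  n_channels = 4,
                                  effect_channels = NULL,
                                  fs = 1000, noise_sd = 1, seed = 1) {
  stopifnot(inherits(grammar, "oddball_grammar"))
  if (!all(vapply(effects, is.finite, TRUE))) stop("effects must be finite")
  with_seed(seed, {
    events <- if (grammar$task == "roving") .roving_events(grammar, n_trains)
              else .local_global_events(grammar, n_trains)
    total_ms <- max(events$onset_ms) + 600
    n_samp <- ceiling(total_ms / 1000 * fs)
    rec <- matrix(stats::rnorm(n_channels * n_samp, sd = noise_sd),
                  n_channels, n_samp)
    regions <- rep(c("temporal", "frontal"),
                   c(ceiling(n_channels / 2), floor(n_channels / 2)))
    effect_channels <- effect_channels %||%
      c(1L, which(regions == "frontal")[1])
    effect_channels <- effect_channels[!is.na(effect_channels)]
    t_resp <- seq(0, 400, by = 1000 / fs)          # response support, ms
    bump <- .dog_bump(t_resp, effects$erp_latency_ms, effects$erp_amp)
    # band-limited high-frequency carrier (70-200 Hz) for the BB effect
    bf <- signal::butter(4, c(70, 200) / (fs / 2), type = "pass")
    for (ch in effect_channels) {
      carrier <- signal::filtfilt(bf, stats::rnorm(n_samp))
      carrier <- carrier / stats::sd(carrier) * 0.5 * noise_sd
      gain <- rep(1, n_samp)
      for (k in seq_len(nrow(events))) {
        i0 <- round(events$onset_ms[k] / 1000 * fs) + 1L
        idx <- i0:(i0 + length(t_resp) - 1L)
        idx <- idx[idx <= n_samp]
        if (events$is_deviant[k]) {
          rec[ch, idx] <- rec[ch, idx] + bump[seq_along(idx)]
          win <- exp(-(t_resp[seq_along(idx)] - 150)^2 / (2 * 60^2))
          gain[idx] <- pmax(gain[idx], 1 + (effects$bb_gain - 1) * win)
        }
      }
      rec[ch, ] <- rec[ch, ] + carrier * gain
    }
    list(record = rec, fs = fs, events = events, regions = regions)
  })
}

#' Generate i.i.d. Gaussian null epochs
#'
#' Data independent of labels, balanced classes: the calibration input for
#' family-wise error-rate checks of the permutation machinery.
#'
#' @param n_trials total trials (must be even).
#' @param n_channels,n_time array dimensions.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return An [epoch_set] with 50/50 standard/deviant labels.
#' @export
gen_null_epochs <- function(n_trials, n_channels, n_time, fs = 500, seed = 1) {
  if (n_trials %% 2 != 0) stop("n_trials must be even for a balanced split")
  stopifnot(n_trials > 0, n_channels > 0, n_time > 0)
  with_seed(seed, {
    dat <- array(stats::rnorm(n_trials * n_channels * n_time),
                 dim = c(n_trials, n_channels, n_time))
    lab <- sample(rep(c("standard", "deviant"), each = n_trials / 2))
    win0 <- -100
    epoch_set(dat, fs = fs, window = c(win0, win0 + n_time * 1000 / fs),
              labels = lab, signal_kind = "raw")
  })
}

#' Write an event table as CSV
#'
#' @param events event data.frame from [gen_oddball_recording()].
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
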