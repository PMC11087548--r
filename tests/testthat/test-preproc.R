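rec_fixture <- function(n_trains = 40, seed = 2, n_channels = 6, ...)
  gen_oddball_recording(oddball_grammar("roving"), n_trains = n_trains,
                        n_channels = n_channels, seed = seed, ...)

test_that("ERP extraction referencing, baseline and grid conventions hold", {
  rec <- rec_fixture()
  suppressMessages(es <- erp_extract(rec))
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$data)[3], 225)        # [-100, 350) ms at 500 Hz
  expect_equal(es$fs, 500)
  tt <- epoch_times(es)
  expect_equal(tt[1], -100)
  expect_equal(tt[51], 0)                   # onset at sample 51 (1-based)
  # per-trial pre-stimulus mean is zero after baseline correction
  base <- apply(es$data[, , tt < 0], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
  expect_error(erp_extract(list(record = rec$record[1, , drop = FALSE],
                                fs = 1000, events = rec$events,
                                regions = "other")),
               "2 channels")
})

test_that("common average referencing zeroes the cross-channel mean", {
  rec <- rec_fixture(n_trains = 5)
  ref <- coinfoPE:::.car(rec$record)
  expect_lt(max(abs(colMeans(ref))), 1e-10)
})

test_that("band-pass keeps the deviance bump and attenuates 60 Hz by >20 dB", {
  rec <- rec_fixture(n_trains = 80, seed = 6)
  # inject a strong 60 Hz tone pre-filter
  t_s <- seq_len(ncol(rec$record)) / rec$fs
  rec$record[1, ] <- rec$record[1, ] + 5 * sin(2 * pi * 60 * t_s)
  suppressMessages(es <- erp_extract(rec))
  tt <- epoch_times(es)
  # bump survives: deviant-minus-standard peaks between 100 and 300 ms
  dd <- colMeans(es$data[es$labels == "deviant", 1, ]) -
    colMeans(es$data[es$labels == "standard", 1, ])
  pk <- tt[which.max(abs(dd))]
  expect_gt(pk, 100); expect_lt(pk, 300)
  # 60 Hz attenuation: compare post-filter amplitude to the injected 5
  sp <- function(v, f, fs) {
    n <- length(v)
    2 * abs(sum(v * exp(-2i * pi * f * seq_len(n) / fs))) / n
  }
  amp60 <- mean(apply(es$data[, 1, ], 1, sp, f = 60, fs = es$fs))
  expect_lt(20 * log10(amp60 / 5), -20)
})

test_that("broadband extraction finds injected high-frequency gain with a clean PSC", {
  rec <- rec_fixture(n_trains = 90, seed = 7, n_channels = 8)
  suppressMessages(out <- bb_extract(rec))
  es <- out$epochs
  expect_identical(es$signal_kind, "bb")
  tt <- epoch_times(es)
  # pre-stimulus mean is 0 per trial by construction
  base <- apply(es$data[, , tt < 0], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
  # PSC orthonormality
  m <- out$models[[1]]
  G <- crossprod(m$psc_matrix)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_true(all(diff(m$eigvals) <= 1e-12))
  # effect channel: first-PSC loadings share one sign across 70-200 Hz
  band <- m$freqs >= 70 & m$freqs <= 200
  expect_true(all(m$psc_matrix[band, 1] > 0))
  # deviant BB exceeds standard BB post-onset on the effect channel
  post <- tt >= 50 & tt < 300
  expect_gt(mean(es$data[es$labels == "deviant", 1, post]),
            mean(es$data[es$labels == "standard", 1, post]))
})

test_that("identical white-noise conditions yield no BB class difference", {
  rec <- rec_fixture(n_trains = 60, seed = 8,
                     effects = list(erp_amp = 0, erp_latency_ms = 180,
                                    bb_gain = 1))
  suppressMessages(out <- bb_extract(rec))
  es <- out$epochs
  tt <- epoch_times(es)
  post <- tt >= 0
  d <- rowMeans(es$data[es$labels == "deviant", 2, post])
  s <- rowMeans(es$data[es$labels == "standard", 2, post])
  se <- sqrt(var(d) / length(d) + var(s) / length(s))
  expect_lt(abs(mean(d) - mean(s)), 2.5 * se)
})

test_that("trial balancing subsamples the majority class deterministically", {
  es <- make_effect_epochs(n_trials = 100, seed = 3)
  # unbalance: drop 30 deviants
  keep <- c(which(es$labels == "standard"),
            which(es$labels == "deviant")[1:20])
  un <- epoch_subset(es, trials = sort(keep))
  bal <- balance_trials(un, seed = 5)
  expect_equal(as.integer(table(bal$labels)), c(20L, 20L))
  bal2 <- balance_trials(un, seed = 5)
  expect_identical(bal$data, bal2$data)
  # already balanced: identity
  expect_identical(balance_trials(es, seed = 1)$data, es$data)
  empty <- epoch_subset(es, trials = which(es$labels == "standard"))
  expect_error(balance_trials(empty), "both classes")
})

test_that("channel selection returns the injected channel as region argmax", {
  es <- make_effect_epochs(n_trials = 120, n_channels = 4,
                           effect_channels = 1, amp = 1.2, seed = 9)
  mm <- mi_map(es, n_perm = 300, seed = 1)
  sel <- suppressWarnings(select_channels(mm$series, es$regions))
  expect_true(1 %in% sel$significant)
  expect_equal(unname(sel$best["temporal"]), 1L)
  # all-null data: empty selection with a warning, not an error
  nul <- gen_null_epochs(60, 4, 20, seed = 10)
  mmn <- mi_map(nul, n_perm = 300, seed = 2)
  expect_warning(seln <- select_channels(mmn$series, nul$regions),
                 "no significant")
})

test_that("tied peak MI resolves to the lower channel index", {
  es <- make_effect_epochs(n_trials = 100, n_channels = 3, seed = 11)
  mk <- function(mi, sig) structure(list(mi = mi, raw = mi, threshold = 0.1,
                                         sig = sig, n_perm = 100,
                                         times_ms = seq(0, 90, 10),
                                         channel = NA),
                                    class = "mi_series")
  mis <- list(mk(rep(0.5, 10), rep(TRUE, 10)),
              mk(rep(0.5, 10), rep(TRUE, 10)),
              mk(rep(0.2, 10), rep(TRUE, 10)))
  sel <- select_channels(mis, rep("temporal", 3))
  expect_equal(unname(sel$best["temporal"]), 1L)
})
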