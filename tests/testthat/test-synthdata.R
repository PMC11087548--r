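test_that("gaussian generators carry their analytic truths and validate input", {
  expect_error(gaussian_coding_spec(1), "n_trials")
  expect_error(gaussian_coding_spec(10, rho = 1), "rho")

  g0 <- gen_gaussian_trials(gaussian_coding_spec(300, "null", seed = 1))
  expect_equal(unname(g0$analytic_truth), c(0, 0, 0))

  gs <- gen_gaussian_trials(gaussian_coding_spec(300, "synergistic",
                                                 rho = 0.8, seed = 2))
  expect_equal(unname(gs$analytic_truth["coI"]), 0.5 * log2(1 - 0.8^2))
  expect_equal(unname(gs$analytic_truth["coI"]), -0.7369656,
               tolerance = 1e-6)

  gi <- gen_gaussian_trials(gaussian_coding_spec(300, "informative-single",
                                                 delta = 1, seed = 3))
  expect_equal(unname(gi$analytic_truth["I_Y"]), 0)
  expect_equal(unname(gi$analytic_truth["coI"]), 0)
})

test_that("same seed gives bit-identical ensembles", {
  a <- gen_gaussian_trials(gaussian_coding_spec(100, "redundant", seed = 7))
  b <- gen_gaussian_trials(gaussian_coding_spec(100, "redundant", seed = 7))
  expect_identical(a$epochs$data, b$epochs$data)
  r1 <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 10,
                              seed = 5)
  r2 <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 10,
                              seed = 5)
  expect_identical(r1$record, r2$record)
  e1 <- gen_null_epochs(20, 3, 10, seed = 9)
  e2 <- gen_null_epochs(20, 3, 10, seed = 9)
  expect_identical(e1$data, e2$data)
})

test_that("a near-duplicated redundant pair has co-I close to I(X;S)", {
  g <- gen_gaussian_trials(gaussian_coding_spec(5000, "redundant",
                                                delta = 1.5, seed = 11),
                           noise_sd = 0.01)
  x <- g$epochs$data[, 1, 1]; y <- g$epochs$data[, 2, 1]
  s <- g$epochs$labels
  ix <- mi_mixed(x, s, floor = FALSE)
  ci <- coinformation(x, y, s)
  expect_gt(ci, 0)
  expect_equal(ci, ix, tolerance = 0.05)
})

test_that("roving grammar labels one deviant and one standard per train", {
  gr <- oddball_grammar("roving")
  expect_error(oddball_grammar("roving", tone_ms = 600, soa_ms = 500),
               "overlap")
  rec <- gen_oddball_recording(gr, n_trains = 60, seed = 2)
  ev <- rec$events
  expect_equal(sum(ev$status == "deviant", na.rm = TRUE), 60)
  expect_equal(sum(ev$status == "standard", na.rm = TRUE), 60)
  expect_true(all(ev$is_deviant == (ev$status == "deviant") |
                    is.na(ev$status) | !ev$is_deviant | ev$status == "deviant"))
  # adjacent trains differ in frequency
  ftrain <- tapply(ev$freq_hz, ev$train_id, unique)
  expect_true(all(diff(unlist(ftrain)) != 0))
  # tones within a train share one frequency
  expect_true(all(vapply(ftrain, length, 1L) == 1))
})

test_that("local/global blocks hold the 20/5 standard/deviant split after habituation", {
  gr <- oddball_grammar("local_global")
  rec <- gen_oddball_recording(gr, n_trains = 2, seed = 3)
  ev <- rec$events
  test_trains <- unique(ev$train_id[ev$phase == "test"])
  # 25 test trains per block
  expect_equal(length(test_trains), 50)
  hab <- unique(ev$train_id[ev$phase == "habituation"])
  expect_equal(length(hab), 40)          # 20 per block
  # per block: 5 deviant-pattern trains out of 25
  for (b in 1:2) {
    tr <- ev[ev$phase == "test" & ev$train_id > (b - 1) * 45 &
               ev$train_id <= b * 45, ]
    fifth <- tr[seq(5, nrow(tr), 5), ]
    expect_equal(sum(fifth$global_deviant), 5)
    expect_equal(sum(!fifth$global_deviant), 20)
  }
})

test_that("zero injected effects leave class means equal up to noise", {
  rec <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 100,
                               effects = list(erp_amp = 0,
                                              erp_latency_ms = 180,
                                              bb_gain = 1),
                               n_channels = 6, seed = 4)
  suppressMessages(es <- erp_extract(rec))
  tt <- epoch_times(es)
  post <- tt >= 100 & tt < 300
  d <- es$data[es$labels == "deviant", 1, post]
  s <- es$data[es$labels == "standard", 1, post]
  diffm <- mean(d) - mean(s)
  se <- sqrt(var(rowMeans(d)) / nrow(d) + var(rowMeans(s)) / nrow(s))
  expect_lt(abs(diffm), 3 * se)
})

test_that("null epochs are balanced, label-independent and reject odd counts", {
  expect_error(gen_null_epochs(99, 2, 5), "even")
  es <- gen_null_epochs(100, 20, 50, seed = 1)
  expect_equal(sum(es$labels == "deviant"), 50)
  mi <- mi_mixed(as.vector(es$data[, 1, 1]), es$labels)
  expect_lt(mi, 0.05)
})

test_that("label permutation destroys MI in generated data", {
  g <- gen_gaussian_trials(gaussian_coding_spec(400, "informative-single",
                                                delta = 2, seed = 13))
  x <- g$epochs$data[, 1, 1]
  s <- g$epochs$labels
  expect_gt(mi_mixed(x, s), 0.2)
  shuf <- withr::with_seed(14, vapply(1:100, function(i)
    mi_mixed(x, sample(s), floor = FALSE), 0))
  expect_lt(abs(mean(shuf)), 2 * sd(shuf) / sqrt(length(shuf)) + 0.003)
})

test_that("epoch_set serialization round-trips through CSV/JSON", {
  es <- gen_null_epochs(10, 3, 8, seed = 21)
  base <- file.path(tempdir(), "es_roundtrip")
  write_epochset(es, base)
  es2 <- read_epochset(base)
  expect_equal(es2$data, es$data)
  expect_identical(es2$labels, es$labels)
  expect_equal(es2$fs, es$fs)
})
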