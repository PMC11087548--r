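test_that("the co-information identity holds to machine precision", {
  withr::with_seed(1, {
    n <- 200
    s <- rep(c("standard", "deviant"), each = n / 2)
    for (i in 1:5) {
      x <- rnorm(n) + (s == "deviant") * runif(1, 0, 1)
      y <- 0.3 * x + rnorm(n)
      zx <- copula_normalize(x); zy <- copula_normalize(y)
      ix <- coinfoPE:::.mi_model_raw(matrix(zx), s)
      iy <- coinfoPE:::.mi_model_raw(matrix(zy), s)
      ij <- coinfoPE:::.mi_model_raw(cbind(zx, zy), s)
      expect_equal(coinformation(x, y, s), ix + iy - ij, tolerance = 1e-12)
    }
  })
})

test_that("co-I recovers independence, redundancy and synergy signs", {
  withr::with_seed(2, {
    n <- 1000
    s <- rep(c("standard", "deviant"), each = n / 2)
    # independent
    expect_lt(abs(coinformation(rnorm(n), rnorm(n), s)), 0.02)
    # near-duplicated signal: coI ~ +I(X;S). The jitter must stay above the
    # rank-spacing scale (~1/n): below it the joint covariance of the copula
    # scores is numerically degenerate, which is why the chart diagonal is
    # defined as the MI rather than computed as a co-I.
    x <- rnorm(n) + (s == "deviant")
    y <- x + rnorm(n, sd = 0.05)
    ci <- coinformation(x, y, s)
    expect_gt(ci, 0)
    expect_lt(abs(ci - mi_mixed(x, s, floor = FALSE)), 0.02)
  })
  # +-rho construction
  g <- gen_gaussian_trials(gaussian_coding_spec(2000, "synergistic",
                                                rho = 0.8, seed = 3))
  ci <- coinformation(g$epochs$data[, 1, 1], g$epochs$data[, 2, 1],
                      g$epochs$labels)
  expect_lt(ci, -0.5)
})

test_that("sign of mean co-I matches the generated structure across seeds", {
  n_ok_syn <- 0; n_ok_red <- 0; R <- 20
  for (i in seq_len(R)) {
    gs <- gen_gaussian_trials(gaussian_coding_spec(250, "synergistic",
                                                   rho = 0.8, seed = 400 + i))
    if (coinformation(gs$epochs$data[, 1, 1], gs$epochs$data[, 2, 1],
                      gs$epochs$labels) < 0) n_ok_syn <- n_ok_syn + 1
    gr <- gen_gaussian_trials(gaussian_coding_spec(250, "redundant",
                                                   delta = 1, seed = 500 + i))
    if (coinformation(gr$epochs$data[, 1, 1], gr$epochs$data[, 2, 1],
                      gr$epochs$labels) > 0) n_ok_red <- n_ok_red + 1
  }
  expect_gte(n_ok_syn, R - 1)
  expect_gte(n_ok_red, R - 1)
})

test_that("MI time series flags an injected effect at the right latency", {
  es <- make_effect_epochs(n_trials = 120, effect_channels = 1,
                           effect_times = 16:20, amp = 1.5, seed = 4)
  ms <- mi_timeseries(es, 1, n_perm = 500, seed = 1)
  expect_true(all(ms$sig[16:20]))
  expect_false(any(ms$sig[1:10]))
  expect_true(all(ms$mi >= 0))
  expect_true(all(ms$sig == (ms$raw > ms$threshold)))
  # determinism
  ms2 <- mi_timeseries(es, 1, n_perm = 500, seed = 1)
  expect_identical(ms$threshold, ms2$threshold)
  expect_warning(mi_timeseries(es, 1, n_perm = 50, seed = 1), "unstable")
})

test_that("temporal charts are symmetric with MI on the diagonal", {
  es <- make_effect_epochs(n_trials = 100, n_channels = 2, n_time = 16,
                           effect_times = 8:12, amp = 1, seed = 5)
  ch <- temporal_coi_chart(es, 1, n_perm = 300, seed = 1)
  expect_equal(ch$coi, t(ch$coi), tolerance = 1e-15)
  i1 <- es$labels == "deviant"
  Z <- coinfoPE:::.copula_cols(es$data[, 1, ])
  expect_equal(diag(ch$coi), coinfoPE:::.mi_cols_1d(Z, i1),
               tolerance = 1e-12)
  # chart cells match the scalar path
  expect_equal(ch$coi[3, 11],
               coinformation(es$data[, 1, 3], es$data[, 1, 11], es$labels),
               tolerance = 1e-12)
  # masks disjoint and sign-consistent
  expect_false(any(ch$sig_redundant & ch$sig_synergistic))
  expect_true(all(ch$coi[ch$sig_redundant] > 0))
  expect_true(all(ch$coi[ch$sig_synergistic] < 0))
})

test_that("an echo of an early code yields negative off-diagonal temporal co-I", {
  withr::with_seed(6, {
    n <- 400; nt <- 20
    s <- rep(c("standard", "deviant"), each = n / 2)
    shared <- rnorm(n)                       # trial-specific state noise
    dat <- array(rnorm(n * nt), c(n, 1, nt))
    # early code: signal + state noise; late echo: state noise only
    dat[, 1, 5] <- (s == "deviant") * 1.2 + shared + 0.3 * rnorm(n)
    dat[, 1, 15] <- shared + 0.3 * rnorm(n)
    es <- epoch_set(dat, fs = 100, window = c(-100, 100), labels = s)
  })
  ch <- temporal_coi_chart(es, 1, n_perm = 400, seed = 2)
  expect_lt(ch$coi[5, 15], -0.1)
  expect_true(ch$sig_synergistic[5, 15])
})

test_that("spatio-temporal charts link shared and split codes across regions", {
  withr::with_seed(7, {
    n <- 400; nt <- 12
    s <- rep(c("standard", "deviant"), each = n / 2)
    lat <- rnorm(n) + (s == "deviant") * 1
    dat <- array(rnorm(n * 2 * nt), c(n, 2, nt))
    dat[, 1, 6] <- lat + 0.5 * rnorm(n)       # temporal carries the latent
    dat[, 2, 8] <- lat + 0.5 * rnorm(n)       # frontal echoes it later
    es <- epoch_set(dat, fs = 100, window = c(-100, 20), labels = s,
                    regions = c("temporal", "frontal"))
  })
  ch <- spatiotemporal_coi_chart(es, 1, 2, n_perm = 400, seed = 3)
  expect_gt(ch$coi[6, 8], 0.05)
  expect_true(ch$sig_redundant[6, 8])
  # region B pure noise -> chart near zero
  withr::with_seed(8, {
    dat2 <- array(rnorm(300 * 2 * 10), c(300, 2, 10))
    s2 <- rep(c("standard", "deviant"), each = 150)
    dat2[, 1, 5] <- dat2[, 1, 5] + (s2 == "deviant")
    es2 <- epoch_set(dat2, fs = 100, window = c(-100, 0), labels = s2,
                     regions = c("temporal", "frontal"))
  })
  ch2 <- spatiotemporal_coi_chart(es2, 1, 2, n_perm = 300, seed = 4)
  expect_lt(max(abs(ch2$coi)), 0.1)
  # same channel delegates to the temporal chart
  ch3 <- spatiotemporal_coi_chart(es2, 1, 1, n_perm = 200, seed = 5)
  expect_true(ch3$symmetric)
})

test_that("aggregation averages, splits signs and bounds the proportion map", {
  es <- make_effect_epochs(n_trials = 80, n_channels = 2, n_time = 10,
                           effect_times = 5:8, seed = 9)
  ch <- temporal_coi_chart(es, 1, n_perm = 200, seed = 1)
  agg1 <- aggregate_charts(list(ch))
  expect_equal(agg1$mean, ch$coi)
  neg <- ch; neg$coi <- -ch$coi
  agg2 <- aggregate_charts(list(ch, neg))
  expect_equal(agg2$mean, matrix(0, 10, 10), tolerance = 1e-15)
  expect_equal(agg2$positive_mean,
               (pmax(ch$coi, 0) + pmax(-ch$coi, 0)) / 2)
  expect_true(all(agg2$prop_significant >= 0 & agg2$prop_significant <= 1))
  bad <- temporal_coi_chart(make_effect_epochs(n_trials = 80, n_time = 12,
                                               effect_times = 5:8,
                                               seed = 10),
                            1, n_perm = 200, seed = 1)
  expect_error(aggregate_charts(list(ch, bad)), "shape")
})

test_that("MI and co-I masks control the family-wise error rate under the null", {
  # MI: 60 null datasets, family over channels x time; the full-scale band
  # check (200 datasets, 1000 permutations) lives in the acceptance tests
  hits_mi <- vapply(1:60, function(i) {
    es <- gen_null_epochs(60, 4, 15, seed = 3000 + i)
    any(mi_map(es, n_perm = 300, seed = 4000 + i)$sig)
  }, TRUE)
  expect_lte(sum(hits_mi), qbinom(0.975, 60, 0.05))
  # co-I chart masks
  hits_coi <- vapply(1:40, function(i) {
    es <- gen_null_epochs(60, 1, 15, seed = 5000 + i)
    ch <- temporal_coi_chart(es, 1, n_perm = 300, seed = 6000 + i)
    any(ch$sig_redundant | ch$sig_synergistic)
  }, TRUE)
  expect_lte(sum(hits_coi), qbinom(0.975, 40, 0.05))
})

test_that("chart serialization writes coi, masks and metadata", {
  es <- make_effect_epochs(n_trials = 60, n_channels = 2, n_time = 8,
                           effect_times = 4:6, seed = 11)
  ch <- temporal_coi_chart(es, 1, n_perm = 200, seed = 1)
  base <- file.path(tempdir(), "chart_io")
  write_coi_chart(ch, base)
  expect_true(file.exists(paste0(base, "_coi.csv")))
  m <- as.matrix(utils::read.csv(paste0(base, "_coi.csv")))
  expect_equal(unname(m), unname(ch$coi), tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_perm, 200)
})
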