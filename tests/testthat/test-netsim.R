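test_that("architecture link tables implement the FC/FF/NN ablations", {
  fc <- network_config(architecture = "FC")$link_table
  ff <- network_config(architecture = "FF")$link_table
  nn <- network_config(architecture = "NN")$link_table
  # FC: reciprocal adjacent links, jumping links both ways, recurrents
  expect_equal(nrow(fc), 5 * 2 + 4 * 2 + 6)
  # FF: no feedback, no recurrent
  expect_true(all(ff$class %in% c("feedforward", "jumping_ff")))
  expect_true(all(ff$from < ff$to))
  # NN: adjacent links both directions + recurrents, no jumping
  expect_false(any(grepl("jumping", nn$class)))
  expect_true(all(abs(nn$from - nn$to) <= 1))
  expect_error(coinfoPE:::.link_table("XX"), "unknown architecture")
})

test_that("a full-size network has 7500 cells and only permitted projections", {
  cfg <- network_config(grid = 25, architecture = "FC", seed = 1)
  net <- build_network(cfg)
  expect_equal(net$n_cells, 7500)           # 625 exc + 625 inh per area x 6
  expect_equal(net$n_exc, 3750)
  # FF ablation: feedback + recurrent excitatory synapse count is zero
  ff <- build_network(network_config(grid = 10, architecture = "FF",
                                     seed = 2))
  npa <- 100
  blocks <- Matrix::summary(ff$W)
  from_area <- (blocks$j - 1) %/% npa + 1
  to_area <- (blocks$i - 1) %/% npa + 1
  expect_equal(sum(from_area >= to_area), 0)
})

test_that("connection probability falls off with grid distance", {
  cfg <- network_config(grid = 15, architecture = "FC", seed = 3)
  net <- build_network(cfg)
  g <- 15; npa <- g * g
  tri <- Matrix::summary(net$W)
  rec <- tri[tri$i <= npa & tri$j <= npa, ]   # A1 recurrent block
  pos <- function(idx) cbind((idx - 1) %% g, (idx - 1) %/% g)
  dxy <- abs(pos(rec$i) - pos(rec$j))
  dxy <- pmin(dxy, g - dxy)                   # toroidal
  d <- sqrt(rowSums(dxy^2))
  # empirical connection probability per distance bin: connections divided
  # by the number of available (source, offset) pairs at that distance
  breaks <- c(-0.5, 1.5, 2.5, 3.5, 6)
  r <- 6
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]   # recurrents skip self
  od <- sqrt(offs$dx^2 + offs$dy^2)
  avail <- table(cut(od, breaks)) * npa
  counts <- table(cut(d, breaks))
  phat <- as.numeric(counts) / as.numeric(avail)
  expect_true(all(diff(phat) < 0))
})

test_that("wiring and simulation are reproducible from seeds", {
  cfg <- network_config(grid = 8, seed = 11)
  n1 <- build_network(cfg); n2 <- build_network(cfg)
  expect_identical(Matrix::summary(n1$W), Matrix::summary(n2$W))
  p1 <- roving_protocol(n1, n_record = 5, seed = 4)
  p2 <- roving_protocol(n2, n_record = 5, seed = 4)
  expect_identical(p1$patterns, p2$patterns)
  e1 <- run_roving(n1, p1, seed = 5)
  e2 <- run_roving(n2, p2, seed = 5)
  expect_identical(e1$data, e2$data)
})

test_that("the resting state is a fixed point and dynamics stay bounded", {
  net <- build_network(network_config(grid = 8, seed = 6))
  st <- network_init(net)
  # adaptation is the slowest variable (tau_a = 60 steps); give it time
  for (i in 1:1500) st <- net_step(net, st, NULL, noise = FALSE)
  prev <- st
  st <- net_step(net, st, NULL, noise = FALSE)
  expect_lt(max(abs(st$v - prev$v)), 1e-5)    # settled at the fixed point
  expect_lt(max(st$o), 0.3)
  # sustained strong input saturates strictly below 1
  ext <- rep(2.5, net$n_exc)
  for (i in 1:200) st <- net_step(net, st, ext, noise = FALSE)
  expect_lt(max(st$o), 1)
  expect_gt(max(st$o), 0.9)
  # bounded with noise on over a long horizon
  st <- network_init(net)
  ok <- TRUE
  st <- withr::with_seed(7, {
    for (i in 1:3000) st <- net_step(net, st, NULL, noise = TRUE)
    st
  })
  expect_true(all(st$o >= 0 & st$o <= 1))
  expect_true(all(is.finite(st$v)))
})

test_that("repeated stimulation adapts and a deviant releases the response", {
  pr <- repetition_probe(network_config(grid = 15, seed = 8), seed = 1)
  r <- pr$response
  expect_lt(r[8], r[1])                        # SSA across 8 repetitions
  expect_gt(r[9], r[8])                        # deviant recovery
  # with adaptation off, deviant and 8th standard are indistinguishable
  diffs0 <- vapply(1:3, function(i) {
    p0 <- repetition_probe(network_config(grid = 15, k_adapt = 0,
                                          seed = 8 + i), seed = i)
    p0$response[9] - p0$response[8]
  }, 0)
  expect_lt(mean(abs(diffs0)), 0.25 * (r[9] - r[8]))
})

test_that("the roving run yields 50/50 labelled epochs with an A1 deviance effect", {
  cfg <- network_config(grid = 10, seed = 9)
  net <- build_network(cfg)
  prot <- roving_protocol(net, n_record = 20, seed = 10)
  es <- run_roving(net, prot, seed = 11)
  expect_equal(dim(es$data), c(40, 6, 45))
  expect_equal(sum(es$labels == "deviant"), 20)
  expect_identical(es$regions,
                   c("temporal", "temporal", "temporal",
                     "frontal", "frontal", "frontal"))
  tt <- epoch_times(es)
  early <- tt >= 0 & tt < 200
  d <- mean(es$data[es$labels == "deviant", 1, early])
  s <- mean(es$data[es$labels == "standard", 1, early])
  expect_gt(d, s)                              # release from adaptation
  # protocol exhaustion error
  short <- prot
  short$n_record <- 100
  expect_error(run_roving(net, short, seed = 1), "exhausted")
})

test_that("protocol patterns hold their invariants", {
  net <- build_network(network_config(grid = 25, seed = 12))
  prot <- roving_protocol(net, seed = 13)
  expect_equal(length(prot$patterns), 12)
  for (p in prot$patterns) {
    expect_equal(length(p), 31)                # ~5% of 625 cells
    expect_equal(length(unique(p)), 31)
  }
  sq <- prot$sequence
  expect_true(all(sq$pattern[-1] != sq$pattern[-nrow(sq)]))
  expect_true(all(sq$n_std >= 6 & sq$n_std <= 10))
  expect_equal(prot$soa, 50)                   # 10 + 20 + 20 steps
})

test_that("cohorts re-draw wiring per run and reproduce bit-identically", {
  cfg <- network_config(grid = 8, seed = 14)
  runs <- run_cohort(cfg, n_runs = 2, seed = 1, n_record = 4)
  expect_equal(length(runs), 2)
  expect_false(identical(runs[[1]]$data, runs[[2]]$data))
  runs2 <- run_cohort(cfg, n_runs = 2, seed = 1, n_record = 4)
  expect_identical(runs[[1]]$data, runs2[[1]]$data)
})

test_that("network configs round-trip through YAML", {
  cfg <- network_config(grid = 10, architecture = "NN", k_adapt = 2.5,
                        seed = 42)
  path <- file.path(tempdir(), "netcfg.yaml")
  write_network_config(cfg, path)
  cfg2 <- read_network_config(path)
  expect_equal(cfg2$k_adapt, 2.5)
  expect_identical(cfg2$architecture, "NN")
  expect_identical(cfg2$link_table, cfg$link_table)
})
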