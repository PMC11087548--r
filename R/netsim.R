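#' Brain-constrained six-area oddball network simulator
#'
#' Six cortical areas are modelled — three temporal (A1, AB, PB) and three
#' frontal (PF, PM, M1) — each a 25 x 25 grid of excitatory graded-response
#' leaky-integrator cells with neuronal adaptation ("fatigue") plus a matching
#' 25 x 25 inhibitory layer. Between- and within-area projections are sparse,
#' topographic and probabilistic: the probability of a synapse falls off as a
#' Gaussian of the (toroidal) grid distance, and weights are i.i.d. uniform on
#' `[0, w_max]`. Three architectures are supported: FC (fully connected:
#' reciprocal next-neighbour links within each lobe, long-distance PB-PF
#' links, higher-order "jumping" links between non-adjacent areas, and
#' recurrent within-area links), FF (all feedback and recurrent links cut),
#' and NN (adjacent-area links and recurrents only — no jumping links).
#' One simulation step corresponds to 10 ms, so the roving protocol's 50-step
#' SOA is ~500 ms and analysis epochs span steps -10..+34 around onset.
#'
#' @name netsim
NULL

.AREAS <- c("A1", "AB", "PB", "PF", "PM", "M1")

## Directed between-area link table. Adjacency is position in the
## A1-AB-PB-PF-PM-M1 chain (PB-PF is the long-distance temporo-frontal
## link); |i - j| == 2 links are the higher-order "jumping" projections.
.link_table <- function(architecture) {
  pairs <- rbind(cbind(1:5, 2:6),            # adjacent (incl. PB-PF)
                 cbind(1:4, 3:6))            # jumping
  fwd <- data.frame(from = pairs[, 1], to = pairs[, 2])
  bwd <- data.frame(from = pairs[, 2], to = pairs[, 1])
  adj <- abs(pairs[, 1] - pairs[, 2]) == 1
  fwd$class <- ifelse(adj, "feedforward", "jumping_ff")
  bwd$class <- ifelse(adj, "feedback", "jumping_fb")
  rec <- data.frame(from = 1:6, to = 1:6, class = "recurrent")
  tab <- rbind(fwd, bwd, rec)
  keep <- switch(architecture,
    FC = rep(TRUE, nrow(tab)),
    FF = tab$class %in% c("feedforward", "jumping_ff"),
    NN = tab$class %in% c("feedforward", "feedback", "recurrent"),
    stop("unknown architecture tag: ", architecture))
  tab[keep, , drop = FALSE]
}

#' Network configuration
#'
#' @param grid side of the per-area cell grid (25 in the full model: 625
#'   excitatory + 625 inhibitory cells per area).
#' @param architecture `"FC"`, `"FF"` or `"NN"`.
#' @param p0,sigma_d connection-probability falloff `p0 * exp(-d^2 /
#'   (2 sigma_d^2))` with toroidal grid distance `d`.
#' @param w_max synaptic weight upper bound (weights ~ U(0, w_max)).
#' @param w_between_gain multiplier on between-area synaptic weights (one of
#'   the three tuned parameters).
#' @param tau_m,tau_a,tau_i membrane, adaptation and inhibitory time
#'   constants in steps (1 step = 10 ms).
#' @param k_adapt adaptation gain (tuned parameter).
#' @param k_local_inh local lateral-inhibition gain (tuned parameter).
#' @param k_global_inh area-wide global-inhibition gain (on the area mean
#'   output).
#' @param inh_radius half-width of the square neighbourhood feeding each
#'   inhibitory cell.
#' @param noise_amp half-width of the uniform membrane noise.
#' @param slope,theta sigmoid slope and threshold of the output
#'   nonlinearity.
#' @param stim_amp external input delivered to stimulus-pattern cells.
#' @param seed wiring seed.
#' @return A `network_config` list.
#' @export
network_config <- function(grid = 25, architecture = c("FC", "FF", "NN"),
                           p0 = 0.35, sigma_d = 2.0, w_max = 0.1,
                           w_between_gain = 4,
                           tau_m = 5, tau_a = 60, tau_i = 2.5,
                           k_adapt = 3, k_local_inh = 2,
                           k_global_inh = 3,
                           inh_radius = 2, noise_amp = 0.15,
                           slope = 4, theta = 0.55, stim_amp = 2,
                           seed = 1) {
  architecture <- match.arg(architecture)
  cfg <- list(areas = .AREAS, grid = as.integer(grid),
              architecture = architecture,
              link_table = .link_table(architecture),
              p0 = p0, sigma_d = sigma_d, w_max = w_max,
              w_between_gain = w_between_gain,
              tau_m = tau_m, tau_a = tau_a, tau_i = tau_i,
              k_adapt = k_adapt, k_local_inh = k_local_inh,
              k_global_inh = k_global_inh, inh_radius = inh_radius,
              noise_amp = noise_amp, slope = slope, theta = theta,
              stim_amp = stim_amp, seed = as.integer(seed))
  class(cfg) <- "network_config"
  cfg
}

#' Read / write a network configuration as YAML
#' @param cfg a `network_config`; `path` a file path.
#' @export
write_network_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  out <- cfg[setdiff(names(cfg), "link_table")]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(network_config, v[setdiff(names(v), "areas")])
}

## Sample one topographic sparse projection between two g x g grids.
## Returns triplets (i = destination, j = source, w).  Offsets beyond
## 3*sigma are dropped; `self` = FALSE removes the zero offset (recurrent
## projections have no self-synapse).
.wire_pair <- function(g, p0, sigma, w_max, gain, self = TRUE) {
  r <- min(g %/% 2, ceiling(3 * sigma))
  src_x <- rep(0:(g - 1), times = g); src_y <- rep(0:(g - 1), each = g)
  ii <- list(); jj <- list(); ww <- list(); k <- 0
  for (dx in -r:r) for (dy in -r:r) {
    if (!self && dx == 0 && dy == 0) next
    p <- p0 * exp(-(dx * dx + dy * dy) / (2 * sigma^2))
    if (p < 1e-4) next
    sel <- which(stats::runif(g * g) < p)
    if (!length(sel)) next
    k <- k + 1
    dst <- ((src_x[sel] + dx) %% g) + g * ((src_y[sel] + dy) %% g) + 1L
    ii[[k]] <- dst; jj[[k]] <- sel
    ww[[k]] <- stats::runif(length(sel), 0, w_max) * gain
  }
  list(i = unlist(ii), j = unlist(jj), w = unlist(ww))
}

## Dense local neighbourhood kernel (mean over a (2r+1)^2 square, toroidal).
.neigh_kernel <- function(g, r) {
  src_x <- rep(0:(g - 1), times = g); src_y <- rep(0:(g - 1), each = g)
  n_off <- (2 * r + 1)^2
  ii <- integer(0); jj <- integer(0)
  for (dx in -r:r) for (dy in -r:r) {
    dst <- ((src_x + dx) %% g) + g * ((src_y + dy) %% g) + 1L
    ii <- c(ii, dst); jj <- c(jj, seq_len(g * g))
  }
  list(i = ii, j = jj, w = rep(1 / n_off, length(ii)))
}

#' Build a network from a configuration
#'
#' Draws all sparse projections (Bernoulli with Gaussian distance falloff,
#' toroidal grid distance) and uniform weights, deterministically from the
#' config seed.
#'
#' @param config a [network_config].
#' @return A `network` object: sparse excitatory weight matrix `W`
#'   (`W[i, j]` = synapse from cell j to cell i), inhibitory input kernel
#'   `K`, per-cell area index `area_of`, total cell count `n_cells`
#'   (excitatory + inhibitory), and the config.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  g <- config$grid; npa <- g * g; N <- 6L * npa
  with_seed(config$seed, {
    ii <- list(); jj <- list(); ww <- list()
    tab <- config$link_table
    for (k in seq_len(nrow(tab))) {
      gain <- if (tab$from[k] == tab$to[k]) 1 else config$w_between_gain
      tr <- .wire_pair(g, config$p0, config$sigma_d, config$w_max, gain,
                       self = tab$from[k] != tab$to[k])
      ii[[k]] <- tr$i + (tab$to[k] - 1L) * npa
      jj[[k]] <- tr$j + (tab$from[k] - 1L) * npa
      ww[[k]] <- tr$w
    }
    W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = unlist(ww), dims = c(N, N))
    ker <- .neigh_kernel(g, config$inh_radius)
    Ki <- lapply(0:5, function(a) ker$i + a * npa)
    Kj <- lapply(0:5, function(a) ker$j + a * npa)
    K <- Matrix::sparseMatrix(i = unlist(Ki), j = unlist(Kj),
                              x = rep(ker$w, 6), dims = c(N, N))
    Ma <- Matrix::sparseMatrix(i = rep(1:6, each = npa), j = seq_len(N),
                               x = 1 / npa, dims = c(6, N))
    structure(list(W = W, K = K, Ma = Ma,
                   area_of = rep(1:6, each = npa),
                   n_cells = 2L * N, n_exc = N, grid = g,
                   config = config),
              class = "network")
  })
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %s: 6 areas x %d+%d cells (%d total), %d synapses\n",
              x$config$architecture, x$grid^2, x$grid^2, x$n_cells,
              Matrix::nnzero(x$W)))
  invisible(x)
}

#' Initialize the network state at rest
#' @param net a `network`.
#' @return A `network_state` list: membrane potentials `v`, adaptation `a`,
#'   inhibitory potentials `vi`, outputs `o` (all zero), step counter `t`.
#' @export
network_init <- function(net) {
  N <- net$n_exc
  structure(list(v = numeric(N), a = numeric(N), vi = numeric(N),
                 o = numeric(N), t = 0L),
            class = "network_state")
}

#' Advance the network one synchronous step
#'
#' Update order: membrane potentials integrate synaptic + external input and
#' uniform noise; inhibitory potentials integrate the neighbourhood mean of
#' excitatory output; outputs pass the potential minus adaptation, local
#' inhibition and area-wide global inhibition through a sigmoid (so outputs
#' stay in (0, 1)); adaptation integrates toward `k_adapt * o`.
#'
#' @param net a `network`.
#' @param state a `network_state`.
#' @param ext external input vector (length `n_exc`) or NULL.
#' @param noise logical; add uniform membrane noise.
#' @return The updated `network_state`.
#' @export
net_step <- function(net, state, ext = NULL, noise = TRUE) {
  cfg <- net$config
  N <- net$n_exc
  o <- state$o
  input <- as.numeric(net$W %*% o)
  if (!is.null(ext)) input <- input + ext
  if (noise) input <- input + stats::runif(N, -cfg$noise_amp, cfg$noise_amp)
  state$v <- state$v + (-state$v + input) / cfg$tau_m
  state$vi <- state$vi + (-state$vi + as.numeric(net$K %*% o)) / cfg$tau_i
  amean <- as.numeric(net$Ma %*% o)
  drive <- state$v - state$a - cfg$k_local_inh * state$vi -
    cfg$k_global_inh * amean[net$area_of]
  state$o <- 1 / (1 + exp(-cfg$slope * (drive - cfg$theta)))
  state$a <- state$a + (-state$a + cfg$k_adapt * state$o) / cfg$tau_a
  state$t <- state$t + 1L
  if (any(!is.finite(state$o)) || any(!is.finite(state$v)))
    stop(sprintf("non-finite network state at step %d (max |v| = %g)",
                 state$t, max(abs(state$v))))
  state
}

## ---- roving protocol --------------------------------------------------------

#' Roving stimulation protocol for the simulator
#'
#' @param net a `network` (patterns live on its A1 grid).
#' @param n_patterns number of distinct stimulus patterns (default 12).
#' @param pattern_cells cells per pattern (default: ~5% of the A1 grid; 31
#'   at the full 25 x 25 size).
#' @param baseline,stim,iti trial phase durations in steps (10/20/20: SOA
#'   50 steps).
#' @param n_record standard and deviant trials to record (50 each).
#' @param std_range deviants are preceded by 6--10 identical standards.
#' @param seed protocol seed (patterns + train sequence).
#' @return A `roving_protocol` list; `patterns` is a list of A1 cell index
#'   vectors (31 unique cells each), `sequence` a data.frame of trains.
#' @export
roving_protocol <- function(net, n_patterns = 12, pattern_cells = NULL,
                            baseline = 10, stim = 20, iti = 20,
                            n_record = 50, std_range = c(6, 10), seed = 1) {
  g <- net$grid
  pattern_cells <- pattern_cells %||% max(1L, round(0.05 * g * g))
  with_seed(seed, {
    patterns <- lapply(seq_len(n_patterns), function(i)
      sample.int(g * g, pattern_cells))
    n_trains <- n_record + 1L
    pat <- integer(n_trains); pat[1] <- sample.int(n_patterns, 1)
    for (k in 2:n_trains)  # deviant pattern differs from preceding standard
      pat[k] <- sample(setdiff(seq_len(n_patterns), pat[k - 1]), 1)
    n_std <- sample(seq(std_range[1], std_range[2]), n_trains,
                    replace = TRUE)
    structure(list(patterns = patterns,
                   sequence = data.frame(train = seq_len(n_trains),
                                         pattern = pat, n_std = n_std),
                   baseline = baseline, stim = stim, iti = iti,
                   soa = baseline + stim + iti,
                   n_record = n_record, seed = seed),
              class = "roving_protocol")
  })
}

#' Run the roving oddball protocol and epoch the responses
#'
#' Presents the train sequence to area A1, recording each area's summed
#' excitatory firing rate at every step. The first tone of each train (k >=
#' 2) is the deviant; the immediately preceding tone (the last standard of
#' the previous train) is its matched standard. Epochs span steps -10..+34
#' around tone onset (-100..350 ms at the 10 ms/step mapping, 100 Hz).
#'
#' @param net a `network`.
#' @param protocol a [roving_protocol].
#' @param seed run seed (state noise).
#' @param warmup settle-in steps before the first train.
#' @return An [epoch_set] (`signal_kind = "rate"`, 100 Hz, 6 channels =
#'   areas, regions temporal/temporal/temporal/frontal/frontal/frontal) with
#'   `n_record` standard and `n_record` deviant trials.
#' @export
run_roving <- function(net, protocol, seed = 1, warmup = 100) {
  stopifnot(inherits(net, "network"), inherits(protocol, "roving_protocol"))
  cfg <- net$config; g <- net$grid; npa <- g * g
  seqs <- protocol$sequence
  soa <- protocol$soa
  n_trials_total <- sum(seqs$n_std) + nrow(seqs)  # trains: n_std + 1 lead tone
  # trial t of train k: first tone of the train is its DEV candidate
  total_steps <- warmup + n_trials_total * soa
  rates <- matrix(0, 6, total_steps)
  npa_sum <- npa  # area signal = sum of excitatory rates
  M <- net$Ma * npa_sum
  with_seed(seed, {
    state <- network_init(net)
    step_i <- 0L
    advance <- function(n, ext) {
      for (s in seq_len(n)) {
        state <<- net_step(net, state, ext)
        step_i <<- step_i + 1L
        rates[, step_i] <<- as.numeric(M %*% state$o)
      }
    }
    advance(warmup, NULL)
    onsets <- integer(0); labels <- character(0)
    for (k in seq_len(nrow(seqs))) {
      ext <- numeric(net$n_exc)
      ext[protocol$patterns[[seqs$pattern[k]]]] <- cfg$stim_amp
      n_tones <- seqs$n_std[k] + 1L          # lead (DEV candidate) + standards
      for (tone in seq_len(n_tones)) {
        onset_step <- step_i + protocol$baseline + 1L
        advance(protocol$baseline, NULL)
        advance(protocol$stim, ext)
        advance(protocol$iti, NULL)
        if (tone == 1L && k >= 2L) {
          onsets <- c(onsets, onset_step); labels <- c(labels, "deviant")
        } else if (tone == n_tones && k < nrow(seqs)) {
          onsets <- c(onsets, onset_step); labels <- c(labels, "standard")
        }
      }
    }
    n_rec <- protocol$n_record
    if (sum(labels == "deviant") < n_rec)
      stop("protocol exhausted before collecting the requested deviants")
    dat <- array(0, c(length(onsets), 6, 45))
    for (e in seq_along(onsets))
      dat[e, , ] <- rates[, (onsets[e] - 10):(onsets[e] + 34)]
    keep <- c(which(labels == "standard")[seq_len(n_rec)],
              which(labels == "deviant")[seq_len(n_rec)])
    keep <- sort(keep)
    epoch_set(dat[keep, , , drop = FALSE], fs = 100, window = c(-100, 350),
              labels = labels[keep],
              regions = c("temporal", "temporal", "temporal",
                          "frontal", "frontal", "frontal"),
              signal_kind = "rate")
  })
}

#' Run a cohort of independent simulations
#'
#' Each run re-draws the wiring and stimulus patterns from a distinct seed
#' (a run is the model correlate of a single subject).
#'
#' @param config prototype [network_config].
#' @param n_runs number of runs (default 3).
#' @param seed cohort seed; run k uses wiring/protocol seeds derived from it.
#' @param ... passed to [roving_protocol()].
#' @return List of [epoch_set]s, one per run.
#' @export
run_cohort <- function(config, n_runs = 3, seed = 1, ...) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r + seed
    net <- build_network(cfg)
    prot <- roving_protocol(net, seed = cfg$seed + 1L, ...)
    run_roving(net, prot, seed = cfg$seed + 2L)
  })
}

## ---- probes and tuning ------------------------------------------------------

#' Repetition/deviance probe of stimulus-specific adaptation
#'
#' Brings the network to its stimulated steady state with a warm-up train of
#' a different pattern (tone trains follow each other continuously in the
#' roving paradigm; no tone is ever presented from silence), then presents
#' the test pattern `n_rep` times followed by a new (deviant) pattern, and
#' returns the mean A1 summed rate during each stimulus period. The basis of
#' the simulated prediction error: with adaptation on, the response decays
#' across repetitions of the same pattern and recovers for the deviant.
#'
#' @param config a [network_config].
#' @param n_rep repetitions of the standard pattern (default 8).
#' @param n_warm warm-up presentations of a different pattern (default 6).
#' @param seed seed.
#' @return List with `response` (length `n_rep + 1`; the last entry is the
#'   deviant) and `labels`.
#' @export
repetition_probe <- function(config, n_rep = 8, n_warm = 6, seed = 1) {
  net <- build_network(config)
  prot <- roving_protocol(net, seed = seed)
  cfg <- net$config
  with_seed(seed + 7L, {
    state <- network_init(net)
    for (s in 1:100) state <- net_step(net, state, NULL)
    mk_ext <- function(p) {
      e <- numeric(net$n_exc); e[prot$patterns[[p]]] <- cfg$stim_amp; e
    }
    a1 <- which(net$area_of == 1)
    present <- function(ext) {
      for (s in seq_len(prot$baseline)) state <<- net_step(net, state, NULL)
      acc <- 0
      for (s in seq_len(prot$stim)) {
        state <<- net_step(net, state, ext)
        acc <- acc + sum(state$o[a1])
      }
      for (s in seq_len(prot$iti)) state <<- net_step(net, state, NULL)
      acc / prot$stim
    }
    for (r in seq_len(n_warm)) present(mk_ext(3L))
    resp <- numeric(n_rep + 1)
    for (r in seq_len(n_rep)) resp[r] <- present(mk_ext(1L))
    resp[n_rep + 1] <- present(mk_ext(2L))
    list(response = resp,
         labels = c(rep("standard", n_rep), "deviant"))
  })
}

#' Temporo-frontal synergy summary of simulated cohorts
#'
#' Applies the experimental analysis chain to each simulation run: MI map
#' with maximum statistics over all areas and timepoints, selection of areas
#' with significant MI, and a spatio-temporal co-I chart for every
#' significant temporal x frontal area pair. Counts significant synergistic
#' (negative co-I) and redundant (positive) cells per run.
#'
#' @param runs list of [epoch_set]s from [run_cohort()].
#' @param n_perm permutations for MI and chart statistics.
#' @param seed analysis seed.
#' @param decim chart decimation factor.
#' @return data.frame with one row per run: `n_charts`, `n_syn_cells`,
#'   `n_red_cells`, `any_synergy`.
#' @export
cohort_synergy <- function(runs, n_perm = 1000, seed = 1, decim = 1) {
  rows <- lapply(seq_along(runs), function(r) {
    es <- runs[[r]]
    mm <- mi_map(es, n_perm = n_perm, seed = seed)
    sel <- suppressWarnings(select_channels(mm$series, es$regions))
    tch <- intersect(sel$significant, which(es$regions == "temporal"))
    fch <- intersect(sel$significant, which(es$regions == "frontal"))
    nsyn <- 0L; nred <- 0L; ncharts <- 0L; nhits <- 0L
    for (a in tch) for (b in fch) {
      ch <- spatiotemporal_coi_chart(es, a, b, n_perm = n_perm,
                                     seed = seed, decim = decim)
      nsyn <- nsyn + sum(ch$sig_synergistic)
      nred <- nred + sum(ch$sig_redundant)
      ncharts <- ncharts + 1L
      if (any(ch$sig_synergistic)) nhits <- nhits + 1L
    }
    data.frame(run = r, n_charts = ncharts, n_syn_cells = nsyn,
               n_red_cells = nred, n_charts_with_synergy = nhits,
               any_synergy = nsyn > 0)
  })
  do.call(rbind, rows)
}

#' Grid search over the three tuned network parameters
#'
#' Evaluates an objective over a grid of adaptation strength, local
#' inhibition and between-area link strength — the three parameters the
#' model is calibrated by.
#'
#' @param config base [network_config].
#' @param k_adapt,k_local_inh,w_between_gain numeric vectors of candidate
#'   values.
#' @param objective function(config) -> numeric (default: the SSA contrast
#'   `deviant - 8th standard` from [repetition_probe()]).
#' @param seed seed passed to the objective.
#' @return data.frame of parameter combinations and objective values.
#' @export
tune_network <- function(config, k_adapt = config$k_adapt,
                         k_local_inh = config$k_local_inh,
                         w_between_gain = config$w_between_gain,
                         objective = NULL, seed = 1) {
  objective <- objective %||% function(cfg) {
    pr <- repetition_probe(cfg, seed = seed)
    pr$response[length(pr$response)] - pr$response[length(pr$response) - 1]
  }
  grid <- expand.grid(k_adapt = k_adapt, k_local_inh = k_local_inh,
                      w_between_gain = w_between_gain)
  grid$objective <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$k_adapt <- grid$k_adapt[i]
    cfg$k_local_inh <- grid$k_local_inh[i]
    cfg$w_between_gain <- grid$w_between_gain[i]
    objective(cfg)
  }, 0)
  grid
}
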