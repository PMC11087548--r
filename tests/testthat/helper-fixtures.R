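# Small builders shared across test files.

# two-class Gaussian epochs with an additive effect on given channels/times
make_effect_epochs <- function(n_trials = 100, n_channels = 4, n_time = 30,
                               effect_channels = 1, effect_times = 15:20,
                               amp = 1, fs = 500, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("standard", "deviant"), each = n_trials / 2)
    dat <- array(rnorm(n_trials * n_channels * n_time),
                 c(n_trials, n_channels, n_time))
    for (ch in effect_channels)
      dat[lab == "deviant", ch, effect_times] <-
        dat[lab == "deviant", ch, effect_times] + amp
    epoch_set(dat, fs = fs, window = c(-100, -100 + n_time * 1000 / fs),
              labels = lab,
              regions = rep(c("temporal", "frontal"),
                            c(ceiling(n_channels / 2),
                              floor(n_channels / 2))))
  })
}

# synergistic pair embedded as two channels at one timepoint
make_synergy_epochs <- function(n_per_class = 250, rho = 0.8, seed = 1) {
  gen_gaussian_trials(gaussian_coding_spec(n_per_class, "synergistic",
                                           rho = rho, seed = seed))$epochs
}
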