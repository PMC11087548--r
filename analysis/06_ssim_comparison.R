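#!/usr/bin/env Rscript
# Chart comparison machinery: converts two co-I charts to min-max-normalized
# images on a common scale and scores their structural similarity (SSIM,
# 11x11 Gaussian window), with a 1000-fold pixel-shuffle surrogate test.
# Here the simulated FC network chart is compared against the chart from the
# synthetic ERP recording (both purely synthetic; the machinery, not any
# particular printed value, is the point).

library(coinfoPE)

dir.create("results/compare", recursive = TRUE, showWarnings = FALSE)

# chart 1: temporal co-I of the best temporal channel, synthetic recording
rec <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 120,
                             n_channels = 8, seed = 101)
es <- balance_trials(erp_extract(rec), seed = 1)
mm <- mi_map(es, n_perm = 500, seed = 1)
sel <- suppressWarnings(select_channels(mm$series, es$regions))
chart_rec <- temporal_coi_chart(es, sel$best["temporal"], n_perm = 500,
                                seed = 1, decim = 5)

# chart 2: temporal co-I of the simulated A1 rate signal (FC network)
cfg <- network_config(grid = 25, architecture = "FC", seed = 5)
net <- build_network(cfg)
prot <- roving_protocol(net, seed = 6)
sim <- run_roving(net, prot, seed = 7)
chart_sim <- temporal_coi_chart(sim, 1, n_perm = 500, seed = 1)

res <- ssim_surrogate_test(chart_rec, chart_sim, n = 1000, seed = 1)
print(res)
write.csv(data.frame(ssim = res$ssim, p = res$p, n_surrogates = res$n),
          "results/compare/ssim_recording_vs_simulation.csv",
          row.names = FALSE)
write.csv(data.frame(surrogate = res$surrogate),
          "results/compare/ssim_surrogates.csv", row.names = FALSE)

# self-comparison sanity: a chart against itself scores 1
self <- ssim_surrogate_test(chart_rec, chart_rec, n = 200, seed = 2)
message(sprintf("self-SSIM %.3f (p = %.4f)", self$ssim, self$p))
message("wrote results/compare/")
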