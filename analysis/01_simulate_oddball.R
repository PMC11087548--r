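#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a roving-oddball recording (20 tone
# frequencies, trains of 3/5/11 64-ms tones at 503 ms SOA) and a
# local/global recording (5 x 50-ms tones at 150 ms SOA, 80/20
# standard/deviant blocks), both with injected ERP and broadband deviance
# effects. Writes the event tables and raw-record summaries under results/.

library(coinfoPE)

dir.create("results/simulate", recursive = TRUE, showWarnings = FALSE)

message("Roving oddball: 120 trains, 8 channels")
rov <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 120,
                             n_channels = 8, seed = 101)
write_events(rov$events, "results/simulate/roving_events.csv")
message(sprintf("  %d tone events, %d deviants (one per train)",
                nrow(rov$events), sum(rov$events$is_deviant)))

message("Local/global: 4 blocks, 8 channels")
lg <- gen_oddball_recording(oddball_grammar("local_global"), n_trains = 4,
                            n_channels = 8, seed = 102)
write_events(lg$events, "results/simulate/local_global_events.csv")
fifth <- lg$events[seq(5, nrow(lg$events), 5), ]
message(sprintf("  %d test trains, %d global deviants (20%% of test trains)",
                sum(fifth$phase == "test"),
                sum(fifth$global_deviant)))

summ <- data.frame(
  task = c("roving", "local_global"),
  n_events = c(nrow(rov$events), nrow(lg$events)),
  n_channels = 8,
  fs = c(rov$fs, lg$fs),
  duration_s = c(ncol(rov$record), ncol(lg$record)) / c(rov$fs, lg$fs))
write.csv(summ, "results/simulate/summary.csv", row.names = FALSE)
message("wrote results/simulate/")
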