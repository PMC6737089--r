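#!/usr/bin/env Rscript
# Stage 1: build the synthetic study data.
#
# Three artifacts, all seeded and regenerable:
#   (a) an ongoing-activity raster from a critical branching process
#       (sigma = 1, jittered lambda values so the threshold search has a
#       real grid to scan),
#   (b) a full tone session: critical branching dynamics with extra,
#       frequency-tuned drive during each stimulus (9 freqs x 3 levels x
#       5 reps, 4-6 s ISI),
#   (c) soma + neuropil fluorescence for a subset of neurons, for the
#       dF/F / neuropil-correction stage.
#
# Large rasters go to scratch/data/ (regenerated on demand); the protocol
# and a session summary go to results/.

suppressPackageStartupMessages(library(avalanchr))
seed <- 20260927
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("-- ongoing branching raster (256 neurons, 6e4 frames, sigma = 1)")
ongoing <- simulate_branching_raster(256, 6e4, branching_param = 1,
                                     drive_rate = 0.02, seed = seed,
                                     jitter = TRUE)
write_raster_csv(ongoing, "scratch/data/raster_ongoing.csv")
message(sprintf("   %d spikes, mean rate %.2f spikes/s",
                length(ongoing$lam@x),
                length(ongoing$lam@x) / 256 / 6e4 * 30))

message("-- tone session (160 neurons, 135 trials)")
protocol <- make_stimulus_protocol(seed = seed)
sess <- synth_session(160, protocol, branching_param = 1, drive_rate = 0.02,
                      stim_drive_per_level = c(0.05, 0.1, 0.2),
                      tuning_width = 0.5, seed = seed + 1)
write_raster_csv(sess$raster, "scratch/data/raster_session.csv")
write_protocol_csv(protocol, "results/protocol.csv")
saveRDS(sess$ground_truth, "scratch/data/ground_truth.rds")
message(sprintf("   %d frames, %d spikes", ncol(sess$raster$lam),
                length(sess$raster$lam@x)))

message("-- fluorescence for 24 neurons (8000 frames)")
sub <- spike_raster(sess$raster$lam[1:24, 1:8000], 30)
pairs <- synth_fluorescence(sub, kernel_tau = 0.5, np_contamination = 0.3,
                            noise_sd = 0.4, seed = seed + 2)
fmat <- t(vapply(pairs, function(p) p$f_soma, numeric(8000)))
nmat <- t(vapply(pairs, function(p) p$f_neuropil, numeric(8000)))
utils::write.csv(data.frame(neuron = rep(1:24, each = 8000),
                            frame = rep(1:8000, times = 24),
                            f_soma = as.vector(t(fmat)),
                            f_neuropil = as.vector(t(nmat))),
                 "scratch/data/fluorescence.csv", row.names = FALSE)
message("done: scratch/data/{raster_ongoing,raster_session,fluorescence}.csv")
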