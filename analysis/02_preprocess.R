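#!/usr/bin/env Rscript
# Stage 2: fluorescence -> neuropil-corrected dF/F, sound-responsiveness,
# and the ensemble-count-maximizing binarization threshold.
#
# Reads the stage-1 artifacts; writes results/responsiveness.csv and
# results/lambda_thr_curve.csv.

suppressPackageStartupMessages(library(avalanchr))
dir.create("results", showWarnings = FALSE)

message("-- dF/F with sliding sub-median baseline + neuropil correction (alpha = 0.9)")
fl <- utils::read.csv("scratch/data/fluorescence.csv")
neurons <- sort(unique(fl$neuron))
dff <- t(vapply(neurons, function(i) {
  g <- fl[fl$neuron == i, ]
  neuropil_correct(compute_dff(g$f_soma), compute_dff(g$f_neuropil),
                   alpha_np = 0.9)
}, numeric(sum(fl$neuron == neurons[1]))))
message(sprintf("   %d traces, dF/F range [%.2f, %.2f]",
                nrow(dff), min(dff), max(dff)))

message("-- ANOVA responsiveness (p < 0.01) against the stimulus protocol")
protocol <- read_protocol_csv("results/protocol.csv")
proto_sub <- protocol[protocol$onset_frame + protocol$duration_frames <=
                        ncol(dff), , drop = FALSE]
resp <- responsive_neurons(dff, proto_sub, p_crit = 0.01)
utils::write.csv(resp, "results/responsiveness.csv", row.names = FALSE)
message(sprintf("   %d / %d neurons sound-responsive",
                sum(resp$responsive), nrow(resp)))

message("-- lambda_thr search on the ongoing raster (40-quantile grid)")
ongoing <- read_raster_csv("scratch/data/raster_ongoing.csv")
opt <- optimize_lambda_thr(ongoing)
utils::write.csv(opt$curve, "results/lambda_thr_curve.csv", row.names = FALSE)
message(sprintf("   chosen lambda_thr = %.4f -> %d ensembles",
                opt$lambda_thr,
                max(opt$curve$n_ensembles)))
writeLines(format(opt$lambda_thr, digits = 10), "scratch/data/lambda_thr.txt")
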