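test_that("stimulus protocol reproduces the printed trial arithmetic", {
  p2p <- make_stimulus_protocol(3000, 48000, tones_per_octave = 2,
                                levels = c(40, 60, 80), reps = 5, seed = 1)
  expect_equal(length(attr(p2p, "freq_axis")), 9)
  expect_equal(nrow(p2p), 135)
  wf <- make_stimulus_protocol(3000, 48000, tones_per_octave = 1,
                               levels = c(40, 60, 80), reps = 5, seed = 1)
  expect_equal(length(attr(wf, "freq_axis")), 5)
  expect_equal(nrow(wf), 75)
  degen <- make_stimulus_protocol(8000, 8000, tones_per_octave = 1,
                                  levels = 60, reps = 1, seed = 1)
  expect_equal(nrow(degen), 1)
})

test_that("protocol trials are ordered, non-overlapping, log-spaced", {
  p <- make_stimulus_protocol(seed = 42)
  expect_true(all(diff(p$onset_frame) > 0))
  # trial i must end before trial i+1 starts
  expect_true(all(p$onset_frame[-1] >
                    (p$onset_frame + p$duration_frames - 1L)[-nrow(p)]))
  freqs <- attr(p, "freq_axis")
  expect_equal(freqs[1], 3000)
  expect_equal(freqs[length(freqs)], 48000)
  expect_equal(diff(log2(freqs)), rep(0.5, 8))
  # every condition appears exactly reps times
  expect_true(all(table(p$frequency_hz, p$level_db) == 5))
  # ISIs within range (4-6 s at 30 Hz)
  gaps <- p$onset_frame[-1] - (p$onset_frame + p$duration_frames)[-nrow(p)] + 1L
  expect_true(all(gaps >= 4 * 30 - 1 & gaps <= 6 * 30 + 1))
  expect_error(make_stimulus_protocol(freq_lo = -1), "positive")
  expect_error(make_stimulus_protocol(reps = 0), "reps")
})

test_that("generators are bit-identical under a fixed seed", {
  a <- make_stimulus_protocol(seed = 9); b <- make_stimulus_protocol(seed = 9)
  expect_identical(a, b)
  r1 <- simulate_branching_raster(50, 500, 1, 0.1, seed = 3)
  r2 <- simulate_branching_raster(50, 500, 1, 0.1, seed = 3)
  expect_identical(as.matrix(r1$lam), as.matrix(r2$lam))
  s1 <- sample_powerlaw_ensembles(-2, 100, 1, 100, seed = 4)
  s2 <- sample_powerlaw_ensembles(-2, 100, 1, 100, seed = 4)
  expect_identical(s1, s2)
})

test_that("branching raster degenerate regimes behave as forced", {
  r0 <- simulate_branching_raster(20, 1000, 1, drive_rate = 0, seed = 1)
  expect_equal(length(r0$lam@x), 0)
  # sigma = 0: cascades cannot propagate; with sparse drive no two events
  # land in adjacent frames and every extracted ensemble lasts 1 frame
  r1 <- simulate_branching_raster(20, 2000, branching_param = 0,
                                  drive_rate = 0.01, seed = 2)
  cat1 <- extract_ensembles(binarize_raster(r1, 0.5))
  expect_gt(nrow(cat1$ensembles), 0)
  expect_true(all(cat1$ensembles$duration == 1))
  # at higher drive, frames are independent, so busy periods are geometric:
  # mean duration = 1/P(silent frame) pinned by the Poisson drive alone
  r2 <- simulate_branching_raster(20, 2e4, branching_param = 0,
                                  drive_rate = 0.2, seed = 3)
  cat2 <- extract_ensembles(binarize_raster(r2, 0.5))
  mean_expected <- 1 / exp(-0.2)
  expect_lt(abs(mean(cat2$ensembles$duration) - mean_expected),
            3 * sd(cat2$ensembles$duration) / sqrt(nrow(cat2$ensembles)))
  expect_error(simulate_branching_raster(10, 10, -1, 0.1, seed = 1),
               "branching_param")
})

test_that("branching raster rate is calibrated to the drive", {
  # sigma = 0: spikes are pure Poisson drive; expected spikes/frame known
  r <- simulate_branching_raster(100, 2e4, 0, drive_rate = 0.5, seed = 11)
  n_spk <- length(r$lam@x)
  expected <- 0.5 * 2e4 * (1 - 0.5 / (2 * 100))  # tiny same-frame collision loss
  expect_lt(abs(n_spk - expected), 3 * sqrt(expected))
})

test_that("power-law sampler matches the exact normalized PMF", {
  expect_true(all(sample_powerlaw_ensembles(-50, 1000, 1, 100, seed = 1) == 1))
  expect_true(all(sample_powerlaw_ensembles(-2, 500, 7, 7, seed = 2) == 7))
  s <- sample_powerlaw_ensembles(-2, 1e5, 1, 100, seed = 3)
  p1_exact <- 1 / sum((1:100)^-2)
  p1_emp <- mean(s == 1)
  expect_lt(abs(p1_emp - p1_exact), 3 * sqrt(p1_exact * (1 - p1_exact) / 1e5))
  expect_error(sample_powerlaw_ensembles(-0.5, 10, 1, Inf, seed = 1),
               "normalizable")
})

test_that("sampler empirical PMF passes chi-square GOF across seeds", {
  support <- 1:100
  pmf <- support^-2 / sum(support^-2)
  for (seed in 1:10) {
    s <- sample_powerlaw_ensembles(-2, 1e5, 1, 100, seed = seed)
    # pool sparse tail so expected counts are >= ~5
    brk <- c(1:20, 30, 50, 100)
    obs <- sapply(seq_along(brk), function(k) {
      lo <- if (k == 1) 1 else brk[k - 1] + 1
      sum(s >= lo & s <= brk[k])
    })
    expc <- sapply(seq_along(brk), function(k) {
      lo <- if (k == 1) 1 else brk[k - 1] + 1
      sum(pmf[lo:brk[k]])
    })
    gof <- suppressWarnings(chisq.test(obs, p = expc))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("rendered rasters round-trip through ensemble extraction", {
  r1 <- render_raster_from_ensembles(1, 1, n_neurons = 5, seed = 1)
  expect_equal(length(r1$lam@x), 1)
  r2 <- render_raster_from_ensembles(6, 2, n_neurons = 3, seed = 1)
  expect_equal(as.vector(Matrix::colSums(r2$lam > 0)[2:3]), c(3, 3))
  expect_error(render_raster_from_ensembles(7, 2, n_neurons = 3, seed = 1),
               "infeasible")
  expect_error(render_raster_from_ensembles(1, 2, n_neurons = 3, seed = 1),
               "infeasible")
  n_neurons <- 12
  sizes <- sample_powerlaw_ensembles(-2, 1000, 1, 60, seed = 5)
  durations <- pmax(1, pmin(sizes, ceiling(sizes / sample(1:4, 1000, TRUE))))
  stopifnot(all(sizes <= durations * n_neurons))
  r <- render_raster_from_ensembles(sizes, durations, n_neurons, seed = 6)
  cat3 <- extract_ensembles(binarize_raster(r, 0.5))
  expect_equal(sort(cat3$ensembles$size), sort(sizes))
  expect_equal(sort(cat3$ensembles$duration), sort(durations))
  # multisets of (size, duration) pairs match exactly
  expect_equal(sort(paste(cat3$ensembles$size, cat3$ensembles$duration)),
               sort(paste(sizes, durations)))
})

test_that("tuned population carries a recoverable tuning signal", {
  proto <- small_protocol(reps = 2)
  # zero gain: evoked frames statistically identical to ongoing frames
  flat <- synth_tuned_population(60, proto, rate_ongoing = 2,
                                 gain_per_level = c(0, 0, 0), seed = 1)
  br <- binarize_raster(flat$raster, 0.5)
  stim_mask <- logical(ncol(br$active))
  for (tr in seq_len(nrow(proto)))
    stim_mask[proto$onset_frame[tr] + seq_len(proto$duration_frames[tr]) - 1] <- TRUE
  r_ev <- mean(firing_rate(br, which(stim_mask)))
  r_on <- mean(firing_rate(br, which(!stim_mask)))
  p_frame <- 2 / 30
  se <- sqrt(p_frame * (1 - p_frame) / (60 * sum(stim_mask))) * 30
  expect_lt(abs(r_ev - r_on), 3 * se)
  # high gain, near-zero noise: BF recovered within one frequency step
  hot <- synth_tuned_population(80, proto, rate_ongoing = 0.05,
                                tuning_width = 0.4,
                                gain_per_level = c(25, 25, 25), seed = 2)
  lam <- as.matrix(hot$raster$lam)
  rec <- sapply(seq_len(80), function(i)
    best_frequency(compute_rf(lam[i, ], proto)))
  err_oct <- abs(log2(rec / hot$ground_truth$bf_assignment))
  expect_gte(mean(err_oct <= 0.5), 0.95)
})

test_that("synthetic fluorescence has the constructed impulse and inverse", {
  empty <- raster_from_spikes(integer(0), integer(0), 1, 600)
  fp <- synth_fluorescence(empty, noise_sd = 0, seed = 1)[[1]]
  expect_true(all(abs(diff(fp$f_soma)) < 1e-12))
  expect_true(all(abs(compute_dff(fp$f_soma)) < 1e-12))
  # single spike: exponential transient with the requested decay
  one <- raster_from_spikes(1, 301, 1, 900)
  fp1 <- synth_fluorescence(one, kernel_tau = 0.5, np_contamination = 0,
                            noise_sd = 0, seed = 1)[[1]]
  f <- fp1$f_soma
  peak <- which.max(f)
  expect_equal(peak, 301)
  decay <- f[peak + 15] - 100  # one tau = 15 frames at 30 Hz
  expect_equal(decay / (f[peak] - 100), exp(-1), tolerance = 1e-6)
  expect_true(all(diff(f[peak:900]) <= 1e-12))
  # neuropil correction with alpha matched to the contamination recovers
  # the contamination-free dF/F
  r <- simulate_branching_raster(30, 3000, 0.5, 0.05, seed = 3)
  pair <- synth_fluorescence(r, np_contamination = 0.5, noise_sd = 0,
                             seed = 4)[[5]]
  clean <- synth_fluorescence(r, np_contamination = 0, noise_sd = 0,
                              seed = 4)[[5]]
  dff_corr <- neuropil_correct(compute_dff(pair$f_soma),
                               compute_dff(pair$f_neuropil), alpha_np = 0.5)
  expect_equal(dff_corr, as.numeric(compute_dff(clean$f_soma)),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_error(synth_fluorescence(r, np_contamination = 1.2), "np_contamination")
})
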