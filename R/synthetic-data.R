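#' Generate a pure-tone stimulus protocol
#'
#' Builds the randomized trial schedule used throughout the pipeline: tones
#' log-spaced from \code{freq_lo} to \code{freq_hi} at
#' \code{tones_per_octave} resolution, crossed with the sound levels,
#' repeated \code{reps} times, in a seeded random order with inter-stimulus
#' intervals drawn uniformly from \code{isi_range}.
#'
#' The default arguments reproduce the 2-photon tone set: 3-48 kHz at
#' 2 tones/octave (9 frequencies) x 3 levels (40/60/80 dB SPL) x 5 repeats
#' of 1-s stimuli with 4-6 s ISI, i.e. 135 trials; 1 tone/octave gives the
#' 75-trial wide-field variant.
#'
#' @param freq_lo,freq_hi frequency range in Hz; \code{freq_hi/freq_lo} must
#'   be \code{2^(k/tones_per_octave)} for integer k.
#' @param tones_per_octave tones per octave (frequency resolution).
#' @param levels sound levels in dB SPL.
#' @param reps repeats of each frequency x level combination.
#' @param stim_dur stimulus duration in seconds.
#' @param isi_range length-2 numeric, uniform inter-stimulus interval range
#'   in seconds.
#' @param frame_rate imaging frame rate in Hz.
#' @param seed integer seed; the trial order and ISIs are reproducible.
#' @return A data.frame of class \code{stim_protocol} with columns
#'   \code{trial, frequency_hz, level_db, onset_frame, duration_frames} and
#'   attributes \code{frame_rate}, \code{freq_axis}, \code{level_axis},
#'   \code{isi_range}.
#' @export
make_stimulus_protocol <- function(freq_lo = 3000, freq_hi = 48000,
                                   tones_per_octave = 2,
                                   levels = c(40, 60, 80), reps = 5,
                                   stim_dur = 1, isi_range = c(4, 6),
                                   frame_rate = 30, seed = 1) {
  if (freq_lo <= 0 || freq_hi <= 0) stop("frequencies must be positive")
  if (reps < 1) stop("reps must be >= 1")
  if (tones_per_octave < 1) stop("tones_per_octave must be >= 1")
  n_oct <- log2(freq_hi / freq_lo)
  k <- n_oct * tones_per_octave
  if (abs(k - round(k)) > 1e-8)
    stop("freq_hi/freq_lo must be a power of 2^(1/tones_per_octave)")
  freqs <- freq_lo * 2^(seq(0, n_oct, by = 1 / tones_per_octave))
  grid <- expand.grid(frequency_hz = freqs, level_db = levels,
                      rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  n_trials <- nrow(grid)
  dur_frames <- max(1L, round(stim_dur * frame_rate))
  withr::with_seed(seed, {
    ord <- sample.int(n_trials)
    isi_s <- stats::runif(n_trials, isi_range[1], isi_range[2])
  })
  grid <- grid[ord, , drop = FALSE]
  isi_frames <- pmax(1L, round(isi_s * frame_rate))
  # each trial: ISI (quiet) then the stimulus window
  onsets <- cumsum(isi_frames + dur_frames) - dur_frames + 1L
  proto <- data.frame(trial = seq_len(n_trials),
                      frequency_hz = grid$frequency_hz,
                      level_db = grid$level_db,
                      onset_frame = onsets,
                      duration_frames = dur_frames)
  structure(proto, class = c("stim_protocol", "data.frame"),
            frame_rate = frame_rate, freq_axis = freqs, level_axis = levels,
            isi_range = isi_range)
}

#' Total session length (frames) implied by a protocol, with trailing quiet
#' @param protocol a \code{stim_protocol}.
#' @param tail_s quiet period appended after the last stimulus, seconds.
#' @export
protocol_n_frames <- function(protocol, tail_s = 5) {
  fr <- attr(protocol, "frame_rate")
  last <- nrow(protocol)
  protocol$onset_frame[last] + protocol$duration_frames[last] - 1L +
    round(tail_s * fr)
}

#' Simulate a branching-process spike raster
#'
#' Canonical avalanche-generating model: independent external drive events
#' arrive as a Poisson process (\code{drive_rate} events/frame, each
#' activating one uniformly chosen neuron), and every neuron active in frame
#' t activates Poisson(\code{branching_param}) uniformly chosen neurons in
#' frame t+1. At \code{branching_param} = 1 (critical) the cascade size and
#' duration distributions are heavy-tailed; per-neuron temporal shuffling
#' destroys them.
#'
#' @param n_neurons,n_frames raster dimensions.
#' @param branching_param mean offspring count sigma (>= 0); 1 = critical.
#' @param drive_rate expected external drive events per frame (>= 0).
#' @param seed integer seed.
#' @param jitter if TRUE, spike lambda values are drawn uniform(0, 1] instead
#'   of 1, for threshold-search tests.
#' @return a sparse \code{spike_raster} (30 Hz).
#' @export
simulate_branching_raster <- function(n_neurons, n_frames, branching_param,
                                      drive_rate, seed, jitter = FALSE) {
  stopifnot(n_neurons >= 1, n_frames >= 1)
  if (branching_param < 0) stop("branching_param must be >= 0")
  if (drive_rate < 0) stop("drive_rate must be >= 0")
  withr::with_seed(seed, {
    spikes_i <- vector("list", n_frames)
    prev <- integer(0)
    for (t in seq_len(n_frames)) {
      n_off <- if (length(prev) && branching_param > 0)
        sum(stats::rpois(length(prev), branching_param)) else 0L
      n_drv <- stats::rpois(1L, drive_rate)
      n_new <- n_off + n_drv
      cur <- if (n_new > 0) unique(sample.int(n_neurons, n_new, replace = TRUE))
             else integer(0)
      spikes_i[[t]] <- cur
      prev <- cur
    }
    counts <- lengths(spikes_i)
    i <- unlist(spikes_i, use.names = FALSE)
    j <- rep.int(seq_len(n_frames), counts)
    vals <- if (jitter && length(i)) stats::runif(length(i)) else 1
    raster_from_spikes(i, j, n_neurons, n_frames, lam_values = vals,
                       frame_rate = 30)
  })
}

#' Sample ensemble sizes from a truncated discrete power law
#'
#' Exact inverse-CDF sampling from P(s) proportional to s^alpha on the
#' integer support \code{s_min..s_max}.
#'
#' @param alpha power-law slope (negative, e.g. -2.23).
#' @param n number of draws.
#' @param s_min,s_max integer support bounds.
#' @param seed integer seed.
#' @return integer vector of n sizes.
#' @export
sample_powerlaw_ensembles <- function(alpha, n, s_min = 1, s_max, seed) {
  stopifnot(n >= 1, s_min >= 1)
  if (!is.finite(s_max)) {
    if (alpha >= -1) stop("alpha >= -1 with unbounded s_max is not normalizable")
    stop("unbounded s_max not supported; pass a finite truncation")
  }
  if (s_max < s_min) stop("s_max must be >= s_min")
  support <- seq.int(s_min, s_max)
  pmf <- support^alpha
  cdf <- cumsum(pmf) / sum(pmf)
  cdf[length(cdf)] <- 1
  withr::with_seed(seed, u <- stats::runif(n))
  support[findInterval(u, cdf, left.open = TRUE) + 1L]
}

#' Render a raster realizing given ensemble sizes and durations
#'
#' Inverse of ensemble extraction: each (size, duration) pair becomes a
#' contiguous block of frames with at least one active neuron per frame and
#' exactly \code{size} active neuron-frames, blocks separated by one silent
#' frame, so that \code{extract_ensembles} recovers the input multiset
#' exactly.
#'
#' @param sizes,durations parallel integer vectors; feasibility requires
#'   duration <= size <= duration * n_neurons.
#' @param n_neurons number of neurons.
#' @param seed integer seed.
#' @param frame_rate frame rate in Hz.
#' @return a sparse \code{spike_raster}.
#' @export
render_raster_from_ensembles <- function(sizes, durations, n_neurons, seed,
                                         frame_rate = 30) {
  stopifnot(length(sizes) == length(durations), n_neurons >= 1)
  sizes <- as.integer(sizes); durations <- as.integer(durations)
  bad <- durations < 1 | sizes < durations | sizes > durations * n_neurons
  if (any(bad))
    stop(sprintf("infeasible (size, duration) pair at index %d",
                 which(bad)[1]))
  withr::with_seed(seed, {
    neuron <- integer(0); frame <- integer(0)
    t0 <- 2L  # leading silent frame
    for (e in seq_along(sizes)) {
      d <- durations[e]; s <- sizes[e]
      per_frame <- rep.int(1L, d)
      extra <- s - d
      if (extra > 0) {
        slots <- rep.int(seq_len(d), n_neurons - 1L)
        pick <- if (length(slots) == 1L) slots else sample(slots, extra)
        per_frame <- per_frame + tabulate(pick, d)
      }
      for (f in seq_len(d)) {
        who <- if (per_frame[f] == n_neurons) seq_len(n_neurons)
               else sample.int(n_neurons, per_frame[f])
        neuron <- c(neuron, who)
        frame <- c(frame, rep.int(t0 + f - 1L, per_frame[f]))
      }
      t0 <- t0 + d + 1L  # >= 1 silent frame between ensembles
    }
    raster_from_spikes(neuron, frame, n_neurons, n_frames = t0,
                       frame_rate = frame_rate)
  })
}

#' Synthesize a tone-tuned population raster
#'
#' Each neuron receives a best frequency (BF) drawn log-uniformly over the
#' protocol's frequency range and fires Bernoulli per frame at
#' \code{rate_ongoing}, plus an evoked rate during stimulus frames that is
#' Gaussian in log2 frequency around its BF with level-dependent gain.
#'
#' @param n_neurons population size.
#' @param protocol a \code{stim_protocol}.
#' @param rate_ongoing ongoing rate, spikes/s.
#' @param tuning_width Gaussian tuning SD in octaves.
#' @param gain_per_level evoked rate at BF (spikes/s) per sound level, in
#'   the order of the protocol's level axis.
#' @param seed integer seed.
#' @return list with elements \code{raster} (sparse \code{spike_raster}) and
#'   \code{ground_truth} (class \code{synth_ground_truth}: BF assignment,
#'   rates, gains, width, seed).
#' @export
synth_tuned_population <- function(n_neurons, protocol, rate_ongoing = 1.8,
                                   tuning_width = 0.5,
                                   gain_per_level = c(5, 10, 20), seed = 1) {
  levels <- attr(protocol, "level_axis")
  if (length(gain_per_level) != length(levels))
    stop("gain_per_level must have one entry per sound level")
  fr <- attr(protocol, "frame_rate")
  n_frames <- protocol_n_frames(protocol)
  freqs <- attr(protocol, "freq_axis")
  withr::with_seed(seed, {
    bf <- 2^stats::runif(n_neurons, log2(min(freqs)), log2(max(freqs)))
    p0 <- min(1, rate_ongoing / fr)
    base <- which(matrix(stats::runif(n_neurons * n_frames) < p0,
                         n_neurons, n_frames), arr.ind = TRUE, useNames = FALSE)
    neuron <- base[, 1]; frame <- base[, 2]
    for (tr in seq_len(nrow(protocol))) {
      gain <- gain_per_level[match(protocol$level_db[tr], levels)]
      if (gain <= 0) next
      doct <- log2(protocol$frequency_hz[tr] / bf)
      p_ev <- pmin(1, gain * exp(-doct^2 / (2 * tuning_width^2)) / fr)
      frames <- protocol$onset_frame[tr] +
        seq_len(protocol$duration_frames[tr]) - 1L
      ev <- which(matrix(stats::runif(n_neurons * length(frames)) <
                           rep(p_ev, times = length(frames)),
                         n_neurons, length(frames)),
                  arr.ind = TRUE, useNames = FALSE)
      if (nrow(ev)) {
        neuron <- c(neuron, ev[, 1])
        frame <- c(frame, frames[ev[, 2]])
      }
    }
    keep <- !duplicated(cbind(neuron, frame))
    raster <- raster_from_spikes(neuron[keep], frame[keep], n_neurons,
                                 n_frames, frame_rate = fr)
  })
  gt <- structure(list(bf_assignment = bf, per_neuron_rate = rate_ongoing,
                       tuning_width = tuning_width,
                       gain_per_level = gain_per_level,
                       branching_parameter = NA_real_,
                       generating_exponent = NA_real_, seed = seed),
                  class = "synth_ground_truth")
  list(raster = raster, ground_truth = gt)
}

#' Synthesize soma + neuropil fluorescence from a spike raster
#'
#' Soma trace = baseline x (1 + exponential-kernel convolution of the
#' neuron's spikes + np_contamination x shared neuropil signal) + noise.
#' The neuropil signal is the kernel-convolved mean population activity and
#' is returned per neuron scaled so that neuropil correction with alpha
#' equal to \code{np_contamination} removes it.
#'
#' @param raster a \code{spike_raster}.
#' @param kernel_tau calcium-indicator decay constant, seconds.
#' @param np_contamination fraction of the neuropil signal leaking into the
#'   soma trace, in [0, 1).
#' @param noise_sd Gaussian noise SD in baseline units (a.u.).
#' @param seed integer seed.
#' @param baseline,amp soma baseline (a.u.) and transient amplitude per
#'   spike (relative units).
#' @return list of per-neuron lists with elements \code{f_soma},
#'   \code{f_neuropil}, \code{neuron_id}; attribute \code{frame_rate}.
#' @export
synth_fluorescence <- function(raster, kernel_tau = 0.5,
                               np_contamination = 0.3, noise_sd = 0.5,
                               seed = 1, baseline = 100, amp = 0.5) {
  stopifnot(inherits(raster, "spike_raster"))
  if (np_contamination < 0 || np_contamination >= 1)
    stop("np_contamination must be in [0, 1)")
  fr <- raster$frame_rate
  n_neurons <- nrow(raster$lam); n_frames <- ncol(raster$lam)
  kern <- exp(-(seq_len(ceiling(8 * kernel_tau * fr)) - 1) / (kernel_tau * fr))
  conv_spikes <- function(x) {
    y <- stats::convolve(x, rev(kern), type = "open")
    y[seq_len(n_frames)]
  }
  lam <- raster$lam
  pop <- as.numeric(Matrix::colMeans(lam > 0))
  np_sig <- amp * conv_spikes(pop)
  withr::with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      row <- as.numeric(lam[i, ] > 0)
      soma_sig <- amp * conv_spikes(row)
      f_soma <- baseline * (1 + soma_sig + np_contamination * np_sig) +
        stats::rnorm(n_frames, sd = noise_sd)
      f_np <- baseline * (1 + np_sig) + stats::rnorm(n_frames, sd = noise_sd)
      structure(list(f_soma = f_soma, f_neuropil = f_np, neuron_id = i),
                frame_rate = fr)
    })
  })
}

#' Synthesize a full session: avalanche-structured ongoing + tuned evoked
#'
#' Runs the branching cascade of \code{\link{simulate_branching_raster}}
#' with a time-varying drive: a constant ongoing drive plus, during each
#' stimulus window, additional drive events routed preferentially to neurons
#' tuned (Gaussian in log2 frequency, SD \code{tuning_width}) to the trial's
#' frequency, with level-dependent gain. Cascades triggered during stimuli
#' inherit the critical branching dynamics, so both ongoing and evoked
#' ensembles are avalanche-structured while evoked ensemble size grows with
#' sound level.
#'
#' @param n_neurons population size.
#' @param protocol a \code{stim_protocol}.
#' @param branching_param cascade branching parameter sigma.
#' @param drive_rate ongoing drive events per frame.
#' @param stim_drive_per_level extra drive events per stimulus frame, one
#'   entry per sound level.
#' @param tuning_width octaves; width of the drive-routing tuning curve.
#' @param seed integer seed.
#' @return list(raster, ground_truth) as in
#'   \code{\link{synth_tuned_population}}.
#' @export
synth_session <- function(n_neurons, protocol, branching_param = 1,
                          drive_rate = 0.02,
                          stim_drive_per_level = c(0.05, 0.1, 0.2),
                          tuning_width = 0.5, seed = 1) {
  levels <- attr(protocol, "level_axis")
  if (length(stim_drive_per_level) != length(levels))
    stop("stim_drive_per_level must have one entry per sound level")
  fr <- attr(protocol, "frame_rate")
  n_frames <- protocol_n_frames(protocol)
  freqs <- attr(protocol, "freq_axis")
  # per-frame extra drive rate and the trial driving each frame
  extra <- numeric(n_frames); trial_of <- integer(n_frames)
  for (tr in seq_len(nrow(protocol))) {
    idx <- protocol$onset_frame[tr] + seq_len(protocol$duration_frames[tr]) - 1L
    extra[idx] <- stim_drive_per_level[match(protocol$level_db[tr], levels)]
    trial_of[idx] <- tr
  }
  withr::with_seed(seed, {
    bf <- 2^stats::runif(n_neurons, log2(min(freqs)), log2(max(freqs)))
    tune_w <- lapply(seq_len(nrow(protocol)), function(tr) {
      w <- exp(-log2(protocol$frequency_hz[tr] / bf)^2 / (2 * tuning_width^2))
      w / sum(w)
    })
    spikes_i <- vector("list", n_frames)
    prev <- integer(0)
    for (t in seq_len(n_frames)) {
      n_off <- if (length(prev) && branching_param > 0)
        sum(stats::rpois(length(prev), branching_param)) else 0L
      cur <- if (n_off > 0) sample.int(n_neurons, n_off, replace = TRUE)
             else integer(0)
      n_drv <- stats::rpois(1L, drive_rate)
      if (n_drv > 0) cur <- c(cur, sample.int(n_neurons, n_drv, replace = TRUE))
      if (extra[t] > 0) {
        n_ev <- stats::rpois(1L, extra[t])
        if (n_ev > 0)
          cur <- c(cur, sample.int(n_neurons, n_ev, replace = TRUE,
                                   prob = tune_w[[trial_of[t]]]))
      }
      cur <- unique(cur)
      spikes_i[[t]] <- cur
      prev <- cur
    }
    counts <- lengths(spikes_i)
    raster <- raster_from_spikes(unlist(spikes_i, use.names = FALSE),
                                 rep.int(seq_len(n_frames), counts),
                                 n_neurons, n_frames, frame_rate = fr)
  })
  gt <- structure(list(bf_assignment = bf, per_neuron_rate = NA_real_,
                       tuning_width = tuning_width,
                       gain_per_level = stim_drive_per_level,
                       branching_parameter = branching_param,
                       generating_exponent = NA_real_, seed = seed),
                  class = "synth_ground_truth")
  list(raster = raster, ground_truth = gt)
}
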