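# Independent brute-force oracles used across the suite. Each re-implements
# the target computation literally and naively, without sharing code with
# the package internals.

# Naive frame-walking ensemble extraction on a dense logical matrix:
# walks frames left to right, opening an ensemble at the first active frame
# and closing it at the next silent frame.
oracle_extract_ensembles <- function(active) {
  n_frames <- ncol(active)
  out <- list()
  open <- FALSE
  start <- NA_integer_
  sz <- 0L
  for (t in seq_len(n_frames)) {
    n_act <- sum(active[, t])
    if (n_act > 0) {
      if (!open) { open <- TRUE; start <- t; sz <- 0L }
      sz <- sz + n_act
    } else if (open) {
      out[[length(out) + 1L]] <- c(start = start, end = t - 1L, size = sz)
      open <- FALSE
    }
  }
  if (open) out[[length(out) + 1L]] <- c(start = start, end = n_frames, size = sz)
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      size = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# Literal per-frame re-implementation of the sliding sub-median baseline.
oracle_dff <- function(f, window_s = 10, percentile = 50, frame_rate = 30) {
  w <- max(1L, round(window_s * frame_rate))
  sapply(seq_along(f), function(t) {
    vals <- if (t == 1) f[1] else f[max(1, t - w):(t - 1)]
    q <- quantile(vals, percentile / 100, names = FALSE)
    below <- vals[vals < q]
    f0 <- if (length(below)) mean(below) else mean(vals)
    (f[t] - f0) / f0
  })
}

# Direct-summation center of mass of a receptive field in log2 frequency.
oracle_bf <- function(resp, freqs) {
  num <- 0; den <- 0
  for (fi in seq_along(freqs)) {
    w <- 0
    for (li in seq_len(nrow(resp))) w <- w + max(resp[li, fi], 0)
    num <- num + w * log2(freqs[fi])
    den <- den + w
  }
  2^(num / den)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments
# (untied samples, small n only).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Random sparse binary raster as a dense logical matrix.
random_active_matrix <- function(n_neurons, n_frames, p) {
  matrix(runif(n_neurons * n_frames) < p, n_neurons, n_frames)
}

# Small protocol used across tests (fast; 2 reps).
small_protocol <- function(reps = 2, seed = 7, isi_range = c(1, 1.5)) {
  make_stimulus_protocol(reps = reps, isi_range = isi_range, seed = seed)
}
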