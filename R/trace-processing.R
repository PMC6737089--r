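#' Convert a fluorescence trace to dF/F with a sliding sub-median baseline
#'
#' For each frame t the baseline F0(t) is the mean of the samples in the
#' preceding \code{window_s}-second window (300 frames at 30 Hz) whose value
#' lies strictly below that window's \code{percentile}-th percentile;
#' dF/F = (F - F0)/F0. The window is causal; frames earlier than one full
#' window use the partial available history (frame 1 uses itself). A window
#' whose below-percentile set is empty (constant window) falls back to the
#' window mean, so F0 stays defined for flat traces.
#'
#' @param f numeric fluorescence trace (strictly positive over the baseline
#'   support).
#' @param window_s baseline window length, seconds.
#' @param percentile baseline percentile (default 50 = sub-median).
#' @param frame_rate frame rate in Hz.
#' @return numeric dF/F trace, same length as \code{f}, with the baseline
#'   attached as attribute \code{"f0"}.
#' @export
compute_dff <- function(f, window_s = 10, percentile = 50, frame_rate = 30) {
  stopifnot(is.numeric(f), length(f) >= 1)
  w <- max(1L, round(window_s * frame_rate))
  n <- length(f)
  f0 <- numeric(n)
  for (t in seq_len(n)) {
    idx <- max(1L, t - w):(t - 1L)
    vals <- if (t == 1L) f[1L] else f[idx]
    q <- stats::quantile(vals, percentile / 100, names = FALSE)
    below <- vals[vals < q]
    f0[t] <- if (length(below)) mean(below) else mean(vals)
  }
  if (any(f0 == 0)) stop("degenerate baseline: F0 = 0 at some frame")
  structure((f - f0) / f0, f0 = f0)
}

#' Neuropil correction of dF/F traces
#'
#' Subtracts \code{alpha_np} times the neuropil dF/F from the soma dF/F,
#' pointwise (default alpha = 0.9).
#'
#' @param dff_soma,dff_np aligned numeric dF/F traces of equal length.
#' @param alpha_np contamination coefficient.
#' @return corrected numeric dF/F trace.
#' @export
neuropil_correct <- function(dff_soma, dff_np, alpha_np = 0.9) {
  if (length(dff_soma) != length(dff_np))
    stop("soma and neuropil traces must be aligned (equal length)")
  as.numeric(dff_soma) - alpha_np * as.numeric(dff_np)
}

#' Identify sound-responsive neurons by one-way ANOVA
#'
#' Per neuron, one-way ANOVA across groups = one pooled pre-stimulus
#' baseline group (per-trial mean dF/F over the \code{baseline_s} window
#' before onset) plus one group per frequency x level condition (per-trial
#' mean dF/F over the stimulus window). Neurons with p < \code{p_crit} are
#' flagged responsive; zero-variance neurons are not responsive.
#'
#' @param dff matrix (neurons x frames) of dF/F traces, or a list of traces.
#' @param protocol a \code{stim_protocol}.
#' @param p_crit significance criterion (default 0.01).
#' @param baseline_s pre-stimulus baseline window, seconds.
#' @return data.frame \code{neuron_id, p_value, responsive}.
#' @export
responsive_neurons <- function(dff, protocol, p_crit = 0.01, baseline_s = 1) {
  if (is.list(dff)) dff <- do.call(rbind, dff)
  fr <- attr(protocol, "frame_rate")
  nb <- max(1L, round(baseline_s * fr))
  n_frames <- ncol(dff)
  if (max(protocol$onset_frame + protocol$duration_frames - 1L) > n_frames)
    stop("protocol extends beyond the traces")
  cond <- interaction(protocol$frequency_hz, protocol$level_db, drop = TRUE)
  if (nlevels(cond) + 1L < 2L) stop("need at least 2 groups for ANOVA")
  win <- lapply(seq_len(nrow(protocol)), function(tr)
    protocol$onset_frame[tr] + seq_len(protocol$duration_frames[tr]) - 1L)
  base_win <- lapply(seq_len(nrow(protocol)), function(tr) {
    idx <- (protocol$onset_frame[tr] - nb):(protocol$onset_frame[tr] - 1L)
    idx[idx >= 1L]
  })
  groups <- factor(c(rep("baseline", nrow(protocol)), as.character(cond)),
                   levels = c("baseline", levels(cond)))
  p <- vapply(seq_len(nrow(dff)), function(i) {
    x <- dff[i, ]
    obs <- c(vapply(base_win, function(ix) mean(x[ix]), numeric(1)),
             vapply(win, function(ix) mean(x[ix]), numeric(1)))
    ok <- is.finite(obs)
    if (stats::var(obs[ok]) == 0 || nlevels(droplevels(groups[ok])) < 2)
      return(NA_real_)
    fit <- stats::aov(obs[ok] ~ droplevels(groups[ok]))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  data.frame(neuron_id = seq_len(nrow(dff)), p_value = p,
             responsive = !is.na(p) & p < p_crit)
}

#' Choose the binarization threshold that maximizes ensemble count
#'
#' Scans candidate lambda thresholds, counts the ensembles (maximal runs of
#' frames with >= 1 active neuron) the thresholded raster yields, and
#' returns the candidate with the most ensembles; ties are broken toward the
#' smallest such threshold (retains more activity). The full
#' threshold-vs-count curve is reported.
#'
#' @param raster a \code{spike_raster}.
#' @param candidate_grid ascending numeric thresholds; default 40 quantiles
#'   of the nonzero lambda values.
#' @return list with \code{lambda_thr}, \code{raster} (the chosen
#'   \code{binary_raster}), \code{curve} (data.frame threshold,
#'   n_ensembles), and \code{zero_ensembles} flag.
#' @export
optimize_lambda_thr <- function(raster, candidate_grid = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  lam <- raster$lam
  nz <- if (inherits(lam, "sparseMatrix")) lam@x else lam[lam > 0]
  if (is.null(candidate_grid)) {
    if (!length(nz)) stop("raster has no nonzero lambda values")
    candidate_grid <- unique(stats::quantile(nz, probs = seq(0.025, 1, length.out = 40),
                                             names = FALSE))
  }
  if (!length(candidate_grid)) stop("candidate_grid is empty")
  if (is.unsorted(candidate_grid)) stop("candidate_grid must be sorted ascending")
  counts <- vapply(candidate_grid, function(thr) {
    b <- binarize_raster(raster, thr)
    count_runs(frames_with_activity(b))
  }, numeric(1))
  best <- which.max(counts)  # first (= smallest) maximizer
  thr <- candidate_grid[best]
  list(lambda_thr = thr, raster = binarize_raster(raster, thr),
       curve = data.frame(threshold = candidate_grid, n_ensembles = counts),
       zero_ensembles = counts[best] == 0)
}
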