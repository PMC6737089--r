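#' Per-neuron firing rates from a binary raster
#'
#' rate = active frames / (masked time in seconds), per neuron.
#'
#' @param braster a \code{binary_raster}.
#' @param frames_mask optional integer vector (or logical vector over
#'   frames) restricting the computation, e.g. to stimulus windows.
#' @return numeric vector, spikes/s per neuron.
#' @export
firing_rate <- function(braster, frames_mask = NULL) {
  stopifnot(inherits(braster, "binary_raster"))
  act <- braster$active
  n_frames <- ncol(act)
  if (is.null(frames_mask)) frames_mask <- seq_len(n_frames)
  if (is.logical(frames_mask)) frames_mask <- which(frames_mask)
  if (!length(frames_mask)) stop("empty frames mask")
  counts <- Matrix::rowSums(act[, frames_mask, drop = FALSE])
  as.numeric(counts) / (length(frames_mask) / braster$frame_rate)
}

#' Coefficient of variation of inter-spike intervals
#'
#' ISIs are differences of consecutive active-frame indices times the frame
#' duration; CV = SD(ISI)/mean(ISI). Neurons with fewer than 3 spikes get
#' NA (at least 2 ISIs are needed).
#'
#' @param braster a \code{binary_raster}.
#' @return numeric vector of CVs (NA where undefined).
#' @export
cv_isi <- function(braster) {
  stopifnot(inherits(braster, "binary_raster"))
  dt <- 1 / braster$frame_rate
  cells <- active_cells(braster)
  spl <- split(cells[, "frame"], cells[, "neuron"])
  out <- rep(NA_real_, nrow(braster$active))
  for (nm in names(spl)) {
    fr <- sort(spl[[nm]])
    if (length(fr) >= 3) {
      isi <- diff(fr) * dt
      out[as.integer(nm)] <- stats::sd(isi) / mean(isi)
    }
  }
  out
}

#' Zero-lag pairwise correlation matrix of lambda traces
#'
#' Pearson correlation at lag zero between the continuous spike-probability
#' time series of every neuron pair, over the whole session.
#' Constant-lambda (zero-variance) neurons are excluded and flagged.
#'
#' @param raster a \code{spike_raster}.
#' @return symmetric correlation matrix with unit diagonal over the
#'   included neurons; attribute \code{"excluded"} lists zero-variance
#'   neuron indices.
#' @export
pairwise_xcorr <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  lam <- as.matrix(raster$lam)
  v <- apply(lam, 1, stats::var)
  excluded <- which(v == 0 | is.na(v))
  keep <- setdiff(seq_len(nrow(lam)), excluded)
  if (length(keep) < 2) stop("need at least 2 active (non-constant) neurons")
  cc <- stats::cor(t(lam[keep, , drop = FALSE]))
  dimnames(cc) <- list(keep, keep)
  attr(cc, "excluded") <- excluded
  cc
}

#' Mean off-diagonal correlation
#' @param cc a correlation matrix from \code{\link{pairwise_xcorr}}.
#' @export
mean_offdiag <- function(cc) mean(cc[upper.tri(cc)])

#' Two-sample rank-sum comparison
#'
#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided: exact for small
#' untied samples, normal approximation with tie correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list(statistic, p_value, method).
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}
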