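#' Single-neuron receptive field from a dF/F trace
#'
#' Mean dF/F over the stimulus window, per trial, averaged over the repeats
#' of each frequency x level condition. Negative means are permitted (they
#' are rectified only where a center-of-mass is taken).
#'
#' @param dff numeric dF/F (or any per-frame response) trace.
#' @param protocol a \code{stim_protocol}; every condition must have at
#'   least one trial, and all trials must fit within the trace.
#' @return object of class \code{receptive_field}: list(response
#'   [levels x frequencies], freq_axis, level_axis).
#' @export
compute_rf <- function(dff, protocol) {
  fr <- attr(protocol, "frame_rate")
  freqs <- attr(protocol, "freq_axis"); levels <- attr(protocol, "level_axis")
  if (max(protocol$onset_frame + protocol$duration_frames - 1L) > length(dff))
    stop("protocol extends beyond the trace")
  per_trial <- vapply(seq_len(nrow(protocol)), function(tr)
    mean(dff[protocol$onset_frame[tr] +
               seq_len(protocol$duration_frames[tr]) - 1L]),
    numeric(1))
  resp <- matrix(NA_real_, length(levels), length(freqs),
                 dimnames = list(level = levels, freq = signif(freqs, 6)))
  for (li in seq_along(levels)) for (fi in seq_along(freqs)) {
    sel <- protocol$level_db == levels[li] &
      abs(log2(protocol$frequency_hz / freqs[fi])) < 1e-9
    if (!any(sel)) stop("condition with zero trials")
    resp[li, fi] <- mean(per_trial[sel])
  }
  structure(list(response = resp, freq_axis = freqs, level_axis = levels),
            class = "receptive_field")
}

#' Best frequency as the receptive-field center of mass
#'
#' Responses are summed over levels per frequency, rectified (negative
#' weights set to zero by default), and the BF is the weighted geometric
#' mean frequency: exp2 of the weighted mean of log2 frequency.
#'
#' @param rf a \code{receptive_field}, or a levels x frequencies matrix
#'   (then \code{freq_axis} must be given).
#' @param freq_axis frequencies in Hz (for matrix input).
#' @param rectify rectify negative responses before weighting (default
#'   TRUE); with FALSE, signed responses are used.
#' @return BF in Hz.
#' @export
best_frequency <- function(rf, freq_axis = NULL, rectify = TRUE) {
  if (inherits(rf, "receptive_field")) {
    resp <- rf$response; freq_axis <- rf$freq_axis
  } else resp <- rf
  w <- colSums(if (rectify) pmax(resp, 0) else resp)
  if (all(w <= 0) || sum(w) <= 0) stop("undefined BF: no positive response")
  2^(sum(w * log2(freq_axis)) / sum(w))
}

#' Ensemble receptive field and tuning-diversity metrics
#'
#' The compound RF of an ensemble is the average of its member neurons'
#' RFs weighted by the number of frames each member was active; IQR_BF is
#' the interquartile range of the member BFs in octaves (log2 Hz), each
#' member counted once, unweighted; bandwidth is computed on the compound
#' RF.
#'
#' @param weights named numeric vector: frames-active count per member
#'   neuron (names = neuron ids).
#' @param rfs list of \code{receptive_field}s indexed by neuron id.
#' @return object of class \code{ensemble_rf}: list(response, freq_axis,
#'   level_axis, weights, iqr_bf, bandwidth).
#' @export
ensemble_rf <- function(weights, rfs) {
  ids <- names(weights)
  if (is.null(ids)) stop("weights must be named by neuron id")
  if (any(!(ids %in% names(rfs))))
    stop("member neuron lacks a receptive field")
  mats <- lapply(rfs[ids], function(r) r$response)
  resp <- Reduce(`+`, Map(`*`, mats, as.numeric(weights))) / sum(weights)
  bfs <- vapply(rfs[ids], best_frequency, numeric(1))
  iqr_bf <- if (length(bfs) > 1) stats::IQR(log2(bfs)) else 0
  rf0 <- rfs[[ids[1]]]
  bw <- tryCatch(rf_bandwidth(resp, rf0$freq_axis), error = function(e) NA_real_)
  structure(list(response = resp, freq_axis = rf0$freq_axis,
                 level_axis = rf0$level_axis, weights = weights,
                 iqr_bf = iqr_bf, bandwidth = bw),
            class = "ensemble_rf")
}

#' Receptive-field bandwidth in octaves
#'
#' At the level row containing the global RF peak (or a requested level),
#' the bandwidth is the log2 span of the contiguous frequency run around
#' the peak where the response is at least \code{threshold} x peak, with
#' the crossing points linearly interpolated in log2 frequency. An RF
#' supported on a single frequency has bandwidth 0 (attribute
#' \code{point_support} set).
#'
#' @param rf a \code{receptive_field}, \code{ensemble_rf}, or a levels x
#'   frequencies response matrix.
#' @param freq_axis frequencies in Hz (for matrix input).
#' @param level \code{"best"} (row of the global peak) or a level value.
#' @param threshold fraction of the peak (default 0.5 = half-max).
#' @return bandwidth in octaves.
#' @export
rf_bandwidth <- function(rf, freq_axis = NULL, level = "best",
                         threshold = 0.5) {
  if (inherits(rf, "receptive_field") || inherits(rf, "ensemble_rf")) {
    resp <- rf$response; freq_axis <- rf$freq_axis
    level_axis <- rf$level_axis
  } else {
    resp <- rf
    if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1)
    level_axis <- seq_len(nrow(resp))
  }
  row <- if (identical(level, "best")) {
    which(resp == max(resp), arr.ind = TRUE)[1, 1]
  } else match(level, level_axis)
  y <- resp[row, ]
  if (max(y) <= 0) stop("undefined bandwidth: no positive response at level")
  lx <- log2(freq_axis)
  peak <- which.max(y)
  half <- threshold * y[peak]
  lo <- peak
  while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
  hi <- peak
  while (hi < length(y) && y[hi + 1] >= half) hi <- hi + 1
  if (lo == peak && hi == peak) {
    # the half-max run is the peak alone: point support, no crossings
    bw <- 0
    attr(bw, "point_support") <- TRUE
    return(bw)
  }
  left <- if (lo > 1) {
    # interpolate the crossing between lo-1 (below) and lo (above)
    lx[lo] - (lx[lo] - lx[lo - 1]) * (y[lo] - half) / (y[lo] - y[lo - 1])
  } else lx[lo]
  right <- if (hi < length(y)) {
    lx[hi] + (lx[hi + 1] - lx[hi]) * (y[hi] - half) / (y[hi] - y[hi + 1])
  } else lx[hi]
  right - left
}

#' Per-ensemble tuning table for all evoked ensembles
#'
#' @param catalog a classified \code{ensemble_catalog}.
#' @param rfs named list of \code{receptive_field}s per neuron (names =
#'   neuron ids as character).
#' @return data.frame \code{ensemble_id, size, duration, level_db, iqr_bf,
#'   bandwidth} for the evoked ensembles whose members all have RFs.
#' @export
ensemble_tuning_table <- function(catalog, rfs) {
  ens <- catalog$ensembles
  ev <- ens[!is.na(ens$evoked) & ens$evoked, , drop = FALSE]
  rows <- lapply(ev$ensemble_id, function(eid) {
    m <- catalog$members[catalog$members$ensemble_id == eid, , drop = FALSE]
    w <- stats::setNames(m$frames_active, as.character(m$neuron))
    erf <- ensemble_rf(w, rfs)
    data.frame(ensemble_id = eid,
               size = ev$size[ev$ensemble_id == eid],
               duration = ev$duration[ev$ensemble_id == eid],
               level_db = ev$level_db[ev$ensemble_id == eid],
               iqr_bf = erf$iqr_bf, bandwidth = as.numeric(erf$bandwidth))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ensemble_id = integer(0), size = integer(0),
                      duration = integer(0), level_db = numeric(0),
                      iqr_bf = numeric(0), bandwidth = numeric(0))
  out
}

#' Tuning metric versus ensemble scale
#'
#' Bins a tuning metric (IQR_BF or bandwidth) by log-spaced bins of
#' ensemble size or duration and reports per-bin mean, SD and n, plus the
#' Spearman correlation across ensembles.
#'
#' @param tuning_tbl output of \code{\link{ensemble_tuning_table}}.
#' @param metric \code{"iqr_bf"} or \code{"bandwidth"}.
#' @param axis \code{"size"} or \code{"duration"}.
#' @param bins_per_decade log-bin resolution of the scale axis.
#' @return data.frame \code{bin_lo, bin_hi, n, mean, sd} with attributes
#'   \code{rho} and \code{p} (Spearman, across ensembles).
#' @export
tuning_vs_scale <- function(tuning_tbl, metric = c("iqr_bf", "bandwidth"),
                            axis = c("size", "duration"),
                            bins_per_decade = 5) {
  metric <- match.arg(metric); axis <- match.arg(axis)
  x <- tuning_tbl[[axis]]; y <- tuning_tbl[[metric]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no finite metric/axis pairs")
  pdfb <- log_bin_pdf(x, bins_per_decade)
  edges <- pdfb$bin_edges
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    yy <- y[idx == b]
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L], n = length(yy),
               mean = if (length(yy)) mean(yy) else NA_real_,
               sd = if (length(yy) > 1) stats::sd(yy) else
                 if (length(yy) == 1) 0 else NA_real_)
  })
  out <- do.call(rbind, rows)
  ct <- if (length(unique(x)) > 2 && stats::sd(y) > 0)
    suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  else NULL
  attr(out, "rho") <- if (is.null(ct)) NA_real_ else unname(ct$estimate)
  attr(out, "p") <- if (is.null(ct)) NA_real_ else ct$p.value
  out
}
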