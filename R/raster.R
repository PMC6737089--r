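#' Spike-probability raster
#'
#' Container for a neurons-by-frames matrix of per-frame spike probabilities
#' (lambda), the continuous output of calcium-trace deconvolution, recorded at
#' a fixed frame rate. The matrix may be a base dense matrix or a
#' \pkg{Matrix} sparse matrix; all downstream operations accept either.
#'
#' @param lam numeric matrix or sparse \code{Matrix}, neurons x frames, with
#'   non-negative entries.
#' @param frame_rate imaging frame rate in Hz (frame duration = 1/frame_rate).
#' @return An object of class \code{spike_raster}: a list with elements
#'   \code{lam} and \code{frame_rate}.
#' @export
spike_raster <- function(lam, frame_rate = 30) {
  stopifnot(length(dim(lam)) == 2L, is.numeric(frame_rate), frame_rate > 0)
  if (length(lam) > 0) {
    mn <- if (inherits(lam, "sparseMatrix")) {
      if (methods::.hasSlot(lam, "x")) min(0, lam@x, Inf) else 0
    } else min(lam)
    if (is.finite(mn) && mn < 0) stop("spike probabilities must be non-negative")
  }
  structure(list(lam = lam, frame_rate = frame_rate), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d frames @ %g Hz (%s)\n",
              nrow(x$lam), ncol(x$lam), x$frame_rate,
              if (inherits(x$lam, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Binary (thresholded) raster
#'
#' @param active logical matrix or sparse pattern matrix, neurons x frames.
#' @param frame_rate frame rate in Hz.
#' @param lambda_thr threshold that produced the raster (NA if constructed
#'   directly).
#' @return object of class \code{binary_raster}.
#' @export
binary_raster <- function(active, frame_rate = 30, lambda_thr = NA_real_) {
  stopifnot(length(dim(active)) == 2L)
  structure(list(active = active, frame_rate = frame_rate,
                 lambda_thr = lambda_thr),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("<binary_raster> %d neurons x %d frames @ %g Hz, lambda_thr = %s\n",
              nrow(x$active), ncol(x$active), x$frame_rate,
              format(x$lambda_thr)))
  invisible(x)
}

#' Threshold a spike-probability raster
#'
#' Marks a neuron active in a frame when its lambda is at or above
#' \code{lambda_thr}. For sparse rasters the threshold must be positive
#' (implicit zeros are never active).
#'
#' @param raster a \code{spike_raster}.
#' @param lambda_thr scalar threshold.
#' @return a \code{binary_raster}.
#' @export
binarize_raster <- function(raster, lambda_thr) {
  stopifnot(inherits(raster, "spike_raster"), is.numeric(lambda_thr),
            length(lambda_thr) == 1L)
  lam <- raster$lam
  if (inherits(lam, "sparseMatrix")) {
    if (lambda_thr <= 0)
      stop("sparse rasters require a positive lambda_thr")
    tm <- as(lam, "TsparseMatrix")
    xv <- if (methods::.hasSlot(tm, "x")) tm@x else rep(1, length(tm@i))
    keep <- xv >= lambda_thr
    act <- Matrix::sparseMatrix(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                                dims = dim(lam))
  } else {
    act <- lam >= lambda_thr
  }
  binary_raster(act, raster$frame_rate, lambda_thr)
}

# (neuron, frame) indices of active cells of a binary raster, as a 2-col matrix
active_cells <- function(braster) {
  act <- braster$active
  if (inherits(act, "sparseMatrix")) {
    tm <- as(act, "TsparseMatrix")
    cbind(neuron = tm@i + 1L, frame = tm@j + 1L)
  } else {
    idx <- which(act, arr.ind = TRUE, useNames = FALSE)
    colnames(idx) <- c("neuron", "frame")
    idx
  }
}

# logical vector: does frame t contain >= 1 active neuron
frames_with_activity <- function(braster) {
  n_frames <- ncol(braster$active)
  cells <- active_cells(braster)
  out <- logical(n_frames)
  out[unique(cells[, "frame"])] <- TRUE
  out
}

# number of maximal runs of TRUE in a logical vector
count_runs <- function(active_frames) {
  if (!any(active_frames)) return(0L)
  r <- rle(active_frames)
  sum(r$values)
}

#' Build a sparse spike raster from spike coordinates
#'
#' @param neuron,frame parallel integer vectors of spike coordinates.
#' @param lam_values lambda values at the spikes (default 1).
#' @param n_neurons,n_frames raster dimensions.
#' @param frame_rate frame rate in Hz.
#' @return a sparse \code{spike_raster}.
#' @export
raster_from_spikes <- function(neuron, frame, n_neurons, n_frames,
                               lam_values = 1, frame_rate = 30) {
  stopifnot(length(neuron) == length(frame))
  lam <- Matrix::sparseMatrix(i = neuron, j = frame,
                              x = rep_len(as.numeric(lam_values), length(neuron)),
                              dims = c(n_neurons, n_frames))
  spike_raster(lam, frame_rate)
}
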