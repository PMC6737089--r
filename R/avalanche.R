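#' Extract neuronal ensembles (avalanches) from a binary raster
#'
#' An ensemble is a maximal run of contiguous frames each containing at
#' least one active neuron, bounded by silent frames. Ensemble size is the
#' total count of active neuron-frames in the run (each neuron counted once
#' per frame it is active); duration is the number of frames spanned.
#'
#' @param braster a \code{binary_raster}.
#' @param provenance optional list recorded in the catalog (raster id,
#'   shuffle flag/seed).
#' @return An object of class \code{ensemble_catalog}: list with
#'   \code{ensembles} (data.frame \code{ensemble_id, start_frame, end_frame,
#'   size, duration, truncated, evoked, stimulus_id, level_db}),
#'   \code{members} (data.frame \code{ensemble_id, neuron, frames_active}),
#'   and metadata (\code{n_neurons, n_frames, frame_rate, lambda_thr,
#'   provenance}).
#' @export
extract_ensembles <- function(braster, provenance = list()) {
  stopifnot(inherits(braster, "binary_raster"))
  n_neurons <- nrow(braster$active); n_frames <- ncol(braster$active)
  cells <- active_cells(braster)
  af <- logical(n_frames)
  af[cells[, "frame"]] <- TRUE
  r <- rle(af)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  k <- length(starts)
  if (k == 0L) {
    ens <- data.frame(ensemble_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), size = integer(0),
                      duration = integer(0), truncated = logical(0),
                      evoked = logical(0), stimulus_id = integer(0),
                      level_db = numeric(0))
    mem <- data.frame(ensemble_id = integer(0), neuron = integer(0),
                      frames_active = integer(0))
  } else {
    run_id <- findInterval(cells[, "frame"], starts)
    size <- tabulate(run_id, k)
    ens <- data.frame(ensemble_id = seq_len(k), start_frame = starts,
                      end_frame = ends, size = size,
                      duration = ends - starts + 1L,
                      truncated = ends == n_frames &
                        seq_len(k) == k & af[n_frames],
                      evoked = NA, stimulus_id = NA_integer_,
                      level_db = NA_real_)
    dt <- data.table::data.table(ensemble_id = run_id, neuron = cells[, "neuron"])
    mem <- as.data.frame(dt[, list(frames_active = .N),
                            by = c("ensemble_id", "neuron")])
    mem <- mem[order(mem$ensemble_id, mem$neuron), , drop = FALSE]
    rownames(mem) <- NULL
  }
  structure(list(ensembles = ens, members = mem, n_neurons = n_neurons,
                 n_frames = n_frames, frame_rate = braster$frame_rate,
                 lambda_thr = braster$lambda_thr, provenance = provenance),
            class = "ensemble_catalog")
}

#' @export
print.ensemble_catalog <- function(x, ...) {
  cat(sprintf("<ensemble_catalog> %d ensembles from %d neurons x %d frames (lambda_thr = %s)\n",
              nrow(x$ensembles), x$n_neurons, x$n_frames, format(x$lambda_thr)))
  invisible(x)
}

#' Per-neuron temporal shuffle null raster
#'
#' Each neuron independently has its spike-probability values randomly
#' permuted in time, preserving its per-neuron activity counts exactly but
#' destroying inter-neuron temporal correlations. The shuffle is repeated
#' \code{n_repeats} times; each repeat is thresholded at \code{lambda_thr}
#' and the shuffled raster producing the maximum number of ensembles is
#' returned.
#'
#' @param raster a \code{spike_raster}.
#' @param lambda_thr threshold applied when counting ensembles (and for the
#'   downstream analysis of the returned raster).
#' @param n_repeats number of independent shuffles (default 10).
#' @param seed integer seed.
#' @return a \code{spike_raster} with attribute \code{"shuffle"} = list
#'   (n_repeats, chosen, n_ensembles, seed).
#' @export
shuffle_raster <- function(raster, lambda_thr, n_repeats = 10, seed = 1) {
  stopifnot(inherits(raster, "spike_raster"), n_repeats >= 1)
  lam <- raster$lam
  n_frames <- ncol(lam)
  sparse <- inherits(lam, "sparseMatrix")
  if (sparse) {
    tm <- as(lam, "TsparseMatrix")
    i <- tm@i + 1L
    spl <- split(seq_along(i), i)
  }
  withr::with_seed(seed, {
    best <- NULL; best_count <- -1L; best_rep <- NA_integer_
    counts <- integer(n_repeats)
    for (r in seq_len(n_repeats)) {
      if (sparse) {
        newj <- integer(length(i))
        # permuting all values of a mostly-zero row == placing its
        # nonzeros on distinct uniformly chosen frames
        for (s in spl)
          newj[s] <- sample.int(n_frames, length(s))
        shuf <- Matrix::sparseMatrix(i = i, j = newj, x = tm@x,
                                     dims = dim(lam))
      } else {
        shuf <- t(apply(lam, 1, function(row) row[sample.int(n_frames)]))
      }
      sr <- spike_raster(shuf, raster$frame_rate)
      counts[r] <- count_runs(frames_with_activity(binarize_raster(sr, lambda_thr)))
      if (counts[r] > best_count) {
        best <- sr; best_count <- counts[r]; best_rep <- r
      }
    }
  })
  attr(best, "shuffle") <- list(n_repeats = n_repeats, chosen = best_rep,
                                n_ensembles = counts, seed = seed)
  best
}

#' Classify ensembles as evoked or ongoing
#'
#' An ensemble is evoked iff it was initiated during a stimulus window: its
#' start frame lies within some trial's [onset, onset + duration) span. An
#' evoked ensemble keeps that label even if it continues past stimulus
#' offset; an ensemble already running at onset remains ongoing.
#'
#' @param catalog an \code{ensemble_catalog}.
#' @param protocol a \code{stim_protocol} (trials must not overlap).
#' @return the catalog with \code{evoked}, \code{stimulus_id} and
#'   \code{level_db} filled in.
#' @export
classify_evoked <- function(catalog, protocol) {
  stopifnot(inherits(catalog, "ensemble_catalog"))
  ens <- catalog$ensembles
  if (nrow(protocol) == 0) {
    ens$evoked <- rep(FALSE, nrow(ens))
    catalog$ensembles <- ens
    return(catalog)
  }
  on <- protocol$onset_frame
  off <- on + protocol$duration_frames  # exclusive
  o <- order(on)
  if (any(off[o][-length(o)] > on[o][-1]))
    stop("protocol integrity: overlapping trials")
  idx <- findInterval(ens$start_frame, on[o])
  trial <- ifelse(idx >= 1 & ens$start_frame < off[o][pmax(idx, 1L)],
                  protocol$trial[o][pmax(idx, 1L)], NA_integer_)
  ens$evoked <- !is.na(trial)
  ens$stimulus_id <- trial
  ens$level_db <- protocol$level_db[match(trial, protocol$trial)]
  catalog$ensembles <- ens
  catalog
}

#' Summarize evoked ensemble size and duration by sound level
#'
#' @param catalog a classified \code{ensemble_catalog}.
#' @param protocol the \code{stim_protocol} (supplies the level axis so
#'   levels with zero ensembles appear with n = 0).
#' @return data.frame \code{level_db, n, mean_size, sd_size, mean_duration,
#'   sd_duration} with attributes \code{rho_size}, \code{rho_duration}
#'   (Spearman correlations of level vs size/duration across evoked
#'   ensembles, with p-values).
#' @export
summarize_by_level <- function(catalog, protocol) {
  ens <- catalog$ensembles
  if (all(is.na(ens$evoked))) stop("catalog is not classified; run classify_evoked")
  ev <- ens[!is.na(ens$evoked) & ens$evoked, , drop = FALSE]
  levels <- attr(protocol, "level_axis")
  rows <- lapply(levels, function(L) {
    g <- ev[ev$level_db == L, , drop = FALSE]
    if (nrow(g) == 0)
      data.frame(level_db = L, n = 0L, mean_size = NA_real_, sd_size = NA_real_,
                 mean_duration = NA_real_, sd_duration = NA_real_)
    else
      data.frame(level_db = L, n = nrow(g), mean_size = mean(g$size),
                 sd_size = stats::sd(g$size), mean_duration = mean(g$duration),
                 sd_duration = stats::sd(g$duration))
  })
  out <- do.call(rbind, rows)
  spearman <- function(y) {
    if (nrow(ev) < 3 || length(unique(ev$level_db)) < 2)
      return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(ev$level_db, y, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  attr(out, "rho_size") <- spearman(ev$size)
  attr(out, "rho_duration") <- spearman(ev$duration)
  out
}
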