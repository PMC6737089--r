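#' Write / read a stimulus protocol as CSV
#'
#' Columns \code{trial, frequency_hz, level_db, onset_frame,
#' duration_frames}; the frame rate is stored in a \code{# frame_rate=}
#' comment header.
#'
#' @param protocol a \code{stim_protocol}.
#' @param path output file.
#' @export
write_protocol_csv <- function(protocol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g", attr(protocol, "frame_rate")), con)
  utils::write.csv(as.data.frame(protocol), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fr <- as.numeric(sub("# frame_rate=", "", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  freqs <- sort(unique(df$frequency_hz))
  levels <- sort(unique(df$level_db))
  structure(df, class = c("stim_protocol", "data.frame"),
            frame_rate = fr, freq_axis = freqs, level_axis = levels,
            isi_range = NA)
}

#' Write / read a spike raster as sparse triplet CSV
#'
#' Plain-text container: a comment header with dimensions and frame rate,
#' then columns \code{neuron, frame, lambda} for the nonzero entries.
#'
#' @param raster a \code{spike_raster}.
#' @param path output file.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  lam <- raster$lam
  if (!inherits(lam, "sparseMatrix"))
    lam <- methods::as(methods::as(lam, "CsparseMatrix"), "generalMatrix")
  tm <- as(lam, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d n_frames=%d frame_rate=%g",
                     nrow(lam), ncol(lam), raster$frame_rate), con)
  utils::write.csv(data.frame(neuron = tm@i + 1L, frame = tm@j + 1L,
                              lambda = tm@x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "n_neurons=(\\d+) n_frames=(\\d+) frame_rate=([0-9.]+)", hdr))[[1]]
  if (length(m) != 4) stop("malformed raster header")
  df <- utils::read.csv(path, comment.char = "#")
  raster_from_spikes(df$neuron, df$frame,
                     n_neurons = as.integer(m[2]),
                     n_frames = as.integer(m[3]),
                     lam_values = df$lambda,
                     frame_rate = as.numeric(m[4]))
}

#' Write an ensemble catalog as CSV
#' @param catalog an \code{ensemble_catalog}.
#' @param path output file.
#' @export
write_catalog_csv <- function(catalog, path) {
  utils::write.csv(catalog$ensembles, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a power-law fit (or any fit list) as JSON
#' @param fit a \code{powerlaw_fit}.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  keep <- c("alpha_hat", "llr", "loglik_pl", "loglik_exp", "p_value",
            "ks_distance", "x_min", "x_max", "n", "method", "degenerate")
  jsonlite::write_json(fit[intersect(keep, names(fit))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
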