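#' Default pipeline configuration
#'
#' All constants of the analysis surface here rather than being hard-coded:
#' neuropil coefficient 0.9, 10-s sub-median baseline, ANOVA p < 0.01,
#' 10 shuffle repeats, KS slope grid, collapse grid -0.5..0.5 step 0.001.
#'
#' @param synthetic list of synthetic-session parameters (or NULL when
#'   loading from files via \code{input}).
#' @param seed master seed for the run.
#' @return a nested config list.
#' @export
default_config <- function(synthetic = list(n_neurons = 128,
                                            branching_param = 1,
                                            drive_rate = 0.02,
                                            stim_drive_per_level = c(0.05, 0.1, 0.2),
                                            tuning_width = 0.5,
                                            tones_per_octave = 2,
                                            reps = 5),
                           seed = 1) {
  list(
    input = NULL,                      # list(raster_csv=, protocol_csv=)
    synthetic = synthetic,
    lambda_thr = NULL,                 # NULL = optimize over the grid
    n_thr_candidates = 40,
    shuffle_repeats = 10,
    alpha_np = 0.9,
    baseline_window_s = 10,
    anova_p_crit = 0.01,
    fit = list(x_min = 1, alpha_grid = c(-4, -1.01, 0.01)),
    collapse = list(b_min = -0.5, b_max = 0.5, b_step = 0.001),
    tuning = TRUE,
    seed = seed
  )
}

#' Validate a pipeline configuration
#'
#' @param config a config list (see \code{\link{default_config}}) or a path
#'   to a YAML file holding one.
#' @return character vector of violations; empty iff the config is
#'   runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character(0)
  has_in <- !is.null(config$input); has_syn <- !is.null(config$synthetic)
  if (has_in && has_syn)
    v <- c(v, "input and synthetic are mutually exclusive: provide exactly one")
  if (!has_in && !has_syn)
    v <- c(v, "one of input or synthetic must be present")
  cl <- config$collapse
  if (!is.null(cl) && (cl$b_min < -0.5 || cl$b_max > 0.5))
    v <- c(v, "collapse grid must lie within [-0.5, 0.5]")
  ft <- config$fit
  if (!is.null(ft) && !is.null(ft$alpha_grid) &&
      (ft$alpha_grid[1] > -4 || ft$alpha_grid[2] < -1.01))
    v <- c(v, "fit$alpha_grid must span at least [-4, -1.01]")
  if (!is.null(config$shuffle_repeats) && config$shuffle_repeats < 1)
    v <- c(v, "shuffle_repeats must be >= 1")
  if (is.null(config$seed)) v <- c(v, "seed is required")
  v
}

#' Run the avalanche pipeline end to end
#'
#' Generates (or loads) a session, optimizes the binarization threshold,
#' extracts ensembles and the per-neuron shuffle null, classifies evoked
#' ensembles, fits power-law vs exponential models to size and duration for
#' ongoing / evoked / shuffled catalogs, runs the sound-level scaling
#' collapse, and (optionally) the ensemble tuning metrics and population
#' statistics. Identical config + seed gives an identical report.
#'
#' @param config config list or YAML path (see \code{\link{default_config}}).
#' @param outdir optional directory; when given, CSV/JSON artifacts and the
#'   report are written there.
#' @return a report list (per-stage parameters and results).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config:\n  - ", paste(viol, collapse = "\n  - "))
  seed <- config$seed
  report <- list(config = config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- data -----------------------------------------------------------
  protocol <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    stage("simulate", {
      protocol <- make_stimulus_protocol(
        tones_per_octave = syn$tones_per_octave %||% 2,
        reps = syn$reps %||% 5, seed = seed)
      sess <- synth_session(
        n_neurons = syn$n_neurons, protocol = protocol,
        branching_param = syn$branching_param,
        drive_rate = syn$drive_rate,
        stim_drive_per_level = syn$stim_drive_per_level,
        tuning_width = syn$tuning_width, seed = seed + 1)
      raster <- sess$raster
      ground_truth <- sess$ground_truth
    })
    report$simulate <- list(n_neurons = syn$n_neurons,
                            n_frames = ncol(raster$lam),
                            n_trials = nrow(protocol))
  } else {
    stage("load", {
      raster <- read_raster_csv(config$input$raster_csv)
      if (!is.null(config$input$protocol_csv))
        protocol <- read_protocol_csv(config$input$protocol_csv)
      ground_truth <- NULL
    })
  }

  # --- threshold ------------------------------------------------------
  stage("threshold", {
    if (is.null(config$lambda_thr)) {
      nz <- if (inherits(raster$lam, "sparseMatrix")) raster$lam@x else
        raster$lam[raster$lam > 0]
      grid <- unique(stats::quantile(
        nz, probs = seq(0.025, 1, length.out = config$n_thr_candidates),
        names = FALSE))
      opt <- optimize_lambda_thr(raster, grid)
    } else {
      opt <- list(lambda_thr = config$lambda_thr,
                  raster = binarize_raster(raster, config$lambda_thr),
                  curve = NULL, zero_ensembles = FALSE)
    }
  })
  report$threshold <- list(lambda_thr = opt$lambda_thr,
                           zero_ensembles = opt$zero_ensembles)

  # --- ensembles + shuffle null --------------------------------------
  stage("avalanches", {
    catalog <- extract_ensembles(opt$raster,
                                 provenance = list(shuffled = FALSE))
    shuf <- shuffle_raster(raster, opt$lambda_thr,
                           n_repeats = config$shuffle_repeats,
                           seed = seed + 2)
    catalog_sh <- extract_ensembles(
      binarize_raster(shuf, opt$lambda_thr),
      provenance = list(shuffled = TRUE, seed = seed + 2))
    if (!is.null(protocol)) {
      catalog <- classify_evoked(catalog, protocol)
      catalog_sh <- classify_evoked(catalog_sh, protocol)
    }
  })
  report$avalanches <- list(n_ensembles = nrow(catalog$ensembles),
                            n_ensembles_shuffled = nrow(catalog_sh$ensembles))

  # --- power-law fits -------------------------------------------------
  x_min <- config$fit$x_min %||% 1
  ag <- config$fit$alpha_grid
  alpha_grid <- seq(ag[1], ag[2], by = ag[3])
  fit_block <- function(ens) {
    if (nrow(ens) < 2) return(NULL)
    lapply(list(size = ens$size, duration = ens$duration), function(v) {
      mle <- fit_models_mle(v, x_min = x_min)
      ks <- fit_alpha_ks(v, alpha_grid, x_min = x_min)
      list(alpha_ks = ks$alpha_hat, alpha_mle = mle$alpha_hat,
           llr = mle$llr, p_value = mle$p_value,
           ks_distance = ks$ks_distance, n = mle$n,
           degenerate = isTRUE(mle$degenerate))
    })
  }
  stage("fit", {
    ens <- catalog$ensembles
    if (!is.null(protocol)) {
      ongoing <- ens[!ens$evoked, , drop = FALSE]
      evoked <- ens[ens$evoked, , drop = FALSE]
    } else {
      ongoing <- ens; evoked <- ens[0, , drop = FALSE]
    }
    report$fits <- list(
      ongoing = fit_block(ongoing),
      evoked = if (nrow(evoked)) fit_block(evoked) else NULL,
      shuffled = fit_block(catalog_sh$ensembles))
  })

  # --- scaling collapse ----------------------------------------------
  if (!is.null(protocol)) stage("collapse", {
    ev <- catalog$ensembles
    ev <- ev[!is.na(ev$evoked) & ev$evoked, , drop = FALSE]
    by_level <- split(ev$size, ev$level_db)
    by_level <- by_level[vapply(by_level, length, integer(1)) >= 50]
    if (length(by_level) >= 2 && !is.null(report$fits$evoked)) {
      cl <- config$collapse
      cs <- collapse_scan(by_level, alpha = report$fits$evoked$size$alpha_ks,
                          b_grid = seq(cl$b_min, cl$b_max, by = cl$b_step))
      report$collapse <- list(b_hat = cs$b_hat,
                              degenerate = cs$degenerate)
    }
    report$by_level <- summarize_by_level(catalog, protocol)
  })

  # --- tuning ---------------------------------------------------------
  if (isTRUE(config$tuning) && !is.null(protocol)) stage("tuning", {
    lam <- as.matrix(raster$lam)
    rfs <- lapply(seq_len(nrow(lam)), function(i) compute_rf(lam[i, ], protocol))
    names(rfs) <- as.character(seq_len(nrow(lam)))
    tt <- ensemble_tuning_table(catalog, rfs)
    if (nrow(tt) >= 10) {
      ti <- tuning_vs_scale(tt, "iqr_bf", "size")
      report$tuning <- list(n_ensembles = nrow(tt),
                            rho_iqr_vs_size = attr(ti, "rho"),
                            p_iqr_vs_size = attr(ti, "p"))
    }
  })

  # --- population stats ----------------------------------------------
  stage("stats", {
    br <- opt$raster
    rates <- firing_rate(br)
    cvs <- cv_isi(br)
    report$population <- list(mean_rate_hz = mean(rates),
                              mean_cv_isi = mean(cvs, na.rm = TRUE))
  })

  # --- artifacts ------------------------------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_catalog_csv(catalog, file.path(outdir, "ensembles.csv"))
    write_catalog_csv(catalog_sh, file.path(outdir, "ensembles_shuffled.csv"))
    if (!is.null(protocol))
      write_protocol_csv(protocol, file.path(outdir, "protocol.csv"))
    rep_out <- report
    rep_out$by_level <- if (!is.null(report$by_level))
      as.data.frame(report$by_level) else NULL
    jsonlite::write_json(rep_out, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
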