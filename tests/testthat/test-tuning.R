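test_that("single-neuron RF averages the stimulus windows per condition", {
  proto <- small_protocol(reps = 2)
  n_frames <- protocol_n_frames(proto)
  rf0 <- compute_rf(rep(0, n_frames), proto)
  expect_true(all(rf0$response == 0))
  # trace = 1 only during the trials of one condition -> indicator RF
  target <- proto[proto$frequency_hz == attr(proto, "freq_axis")[3] &
                    proto$level_db == 60, ]
  tr <- rep(0, n_frames)
  for (k in seq_len(nrow(target)))
    tr[target$onset_frame[k] + seq_len(target$duration_frames[k]) - 1] <- 1
  rf1 <- compute_rf(tr, proto)
  expect_equal(rf1$response["60", 3], 1)
  expect_equal(sum(rf1$response), 1)
})

test_that("best frequency is the rectified log2 center of mass", {
  proto <- small_protocol(reps = 1)
  freqs <- attr(proto, "freq_axis")
  resp <- matrix(0, 3, 9)
  resp[2, which(abs(freqs - 12000) < 1)] <- 1
  rf <- structure(list(response = resp, freq_axis = freqs,
                       level_axis = c(40, 60, 80)),
                  class = "receptive_field")
  expect_equal(best_frequency(rf), 12000)
  # equal mass at 6 and 24 kHz -> log midpoint 12 kHz
  resp2 <- matrix(0, 3, 9)
  resp2[1, which(abs(freqs - 6000) < 1)] <- 1
  resp2[1, which(abs(freqs - 24000) < 1)] <- 1
  expect_equal(best_frequency(resp2, freqs), 12000, tolerance = 1e-9)
  # random RFs match the direct-summation oracle
  set.seed(21)
  for (k in 1:100) {
    m <- matrix(rnorm(27), 3, 9)
    if (all(m <= 0)) next
    expect_equal(best_frequency(m, freqs), oracle_bf(m, freqs),
                 tolerance = 1e-12)
  }
  expect_error(best_frequency(matrix(-1, 3, 9), freqs), "undefined BF")
})

test_that("ensemble RF is the activity-weighted convex combination", {
  proto <- small_protocol(reps = 1)
  freqs <- attr(proto, "freq_axis")
  mk_rf <- function(center, width = 0.5, amp = 1) {
    resp <- matrix(rep(amp * exp(-log2(freqs / center)^2 / (2 * width^2)),
                       each = 3), 3, 9)
    structure(list(response = resp, freq_axis = freqs,
                   level_axis = c(40, 60, 80)), class = "receptive_field")
  }
  rfs <- list("1" = mk_rf(6000), "2" = mk_rf(24000), "3" = mk_rf(6000, amp = 2))
  # single member: RF equals the member's, IQR_BF = 0
  e1 <- ensemble_rf(c("1" = 3), rfs)
  expect_equal(e1$response, rfs[["1"]]$response)
  expect_equal(e1$iqr_bf, 0)
  # equal weights: plain average
  e2 <- ensemble_rf(c("1" = 2, "2" = 2), rfs)
  expect_equal(e2$response, (rfs[["1"]]$response + rfs[["2"]]$response) / 2)
  # identical BFs, different shapes: IQR_BF = 0 but bandwidth > 0
  e3 <- ensemble_rf(c("1" = 1, "3" = 4), rfs)
  expect_equal(e3$iqr_bf, 0)
  expect_gt(e3$bandwidth, 0)
  # convex combination: entries bounded by member min/max
  set.seed(22)
  rnd <- list("1" = mk_rf(4000, 0.7), "2" = mk_rf(30000, 0.3))
  w <- c("1" = 5, "2" = 2)
  er <- ensemble_rf(w, rnd)
  lo <- pmin(rnd[["1"]]$response, rnd[["2"]]$response)
  hi <- pmax(rnd[["1"]]$response, rnd[["2"]]$response)
  expect_true(all(er$response >= lo - 1e-12 & er$response <= hi + 1e-12))
  # IQR_BF invariant under relabeling and uniform scaling of all RFs
  rfs_scaled <- lapply(rnd, function(r) {
    r$response <- 7 * r$response; r })
  expect_equal(ensemble_rf(w, rnd)$iqr_bf,
               ensemble_rf(w, rfs_scaled)$iqr_bf)
  expect_equal(ensemble_rf(c("2" = 2, "1" = 5), rnd)$iqr_bf, er$iqr_bf)
  expect_error(ensemble_rf(c("9" = 1), rfs), "lacks")
})

test_that("bandwidth matches closed forms and flags point support", {
  freqs <- 1000 * 2^seq(0, 4, by = 0.05)
  # Gaussian in log2 f, sigma = 0.5 octaves -> FWHM = 2 sigma sqrt(2 ln 2)
  y <- exp(-log2(freqs / 4000)^2 / (2 * 0.5^2))
  bw <- rf_bandwidth(matrix(y, 1), freqs)
  expect_equal(as.numeric(bw), 2 * 0.5 * sqrt(2 * log(2)), tolerance = 0.01)
  # rectangle occupying exactly 2 octaves
  yr <- as.numeric(freqs >= 2000 & freqs <= 8000 + 1)
  # restrict the axis to the rectangle so the span is the support itself
  sel <- yr == 1
  expect_equal(as.numeric(rf_bandwidth(matrix(yr[sel], 1), freqs[sel])), 2,
               tolerance = 1e-9)
  # indicator RF: zero bandwidth with point-support flag
  yi <- rep(0, length(freqs)); yi[20] <- 1
  bwi <- rf_bandwidth(matrix(yi, 1), freqs)
  expect_equal(as.numeric(bwi), 0)
  expect_true(isTRUE(attr(bwi, "point_support")))
  expect_error(rf_bandwidth(matrix(-1, 1, 5), freqs[1:5]), "undefined bandwidth")
})

test_that("bandwidth of identically tuned members equals the single-member bandwidth", {
  proto <- small_protocol(reps = 1)
  freqs <- attr(proto, "freq_axis")
  resp <- matrix(rep(exp(-log2(freqs / 12000)^2 / 0.5), each = 3), 3, 9)
  rf <- structure(list(response = resp, freq_axis = freqs,
                       level_axis = c(40, 60, 80)), class = "receptive_field")
  rfs <- list("1" = rf, "2" = rf, "3" = rf)
  single <- rf_bandwidth(rf)
  comp <- ensemble_rf(c("1" = 4, "2" = 1, "3" = 7), rfs)
  expect_equal(as.numeric(comp$bandwidth), as.numeric(single),
               tolerance = 1e-12)
})

test_that("IQR_BF grows with ensemble size for log-uniform BFs", {
  proto <- small_protocol(reps = 1)
  freqs <- attr(proto, "freq_axis")
  withr::with_seed(23, {
    n_neurons <- 100
    bfs <- 2^runif(n_neurons, log2(3000), log2(48000))
    rfs <- lapply(bfs, function(b) {
      resp <- matrix(rep(exp(-log2(freqs / b)^2 / (2 * 0.25^2)), each = 3), 3, 9)
      structure(list(response = resp, freq_axis = freqs,
                     level_axis = c(40, 60, 80)), class = "receptive_field")
    })
    names(rfs) <- as.character(seq_len(n_neurons))
    # ensembles = random subsets whose size spans two decades
    sizes <- round(10^runif(300, 0.3, 2))
    tbl <- do.call(rbind, lapply(seq_along(sizes), function(e) {
      members <- sample.int(n_neurons, min(sizes[e], n_neurons))
      w <- setNames(rep(1, length(members)), as.character(members))
      er <- ensemble_rf(w, rfs)
      data.frame(ensemble_id = e, size = sizes[e], duration = 1,
                 level_db = 60, iqr_bf = er$iqr_bf,
                 bandwidth = as.numeric(er$bandwidth))
    }))
  })
  ts <- tuning_vs_scale(tbl, "iqr_bf", "size")
  expect_gt(attr(ts, "rho"), 0)
  expect_lt(attr(ts, "p"), 0.01)
  occupied <- ts[ts$n > 0, ]
  expect_gt(nrow(occupied), 3)
  # all neurons share one BF -> IQR_BF identically zero, SD 0 in every bin
  rfs1 <- rfs
  for (i in seq_along(rfs1)) rfs1[[i]] <- rfs[["1"]]
  tbl0 <- tbl
  tbl0$iqr_bf <- 0
  ts0 <- tuning_vs_scale(tbl0, "iqr_bf", "size")
  expect_true(all(ts0$mean[ts0$n > 0] == 0))
  expect_true(all(ts0$sd[ts0$n > 0] == 0))
})

test_that("catalog-level tuning table wires members to RFs", {
  proto <- small_protocol(reps = 2)
  hot <- synth_tuned_population(30, proto, rate_ongoing = 1,
                                tuning_width = 0.4,
                                gain_per_level = c(10, 15, 20), seed = 24)
  lam <- as.matrix(hot$raster$lam)
  rfs <- lapply(seq_len(30), function(i) compute_rf(lam[i, ], proto))
  names(rfs) <- as.character(1:30)
  catl <- classify_evoked(
    extract_ensembles(binarize_raster(hot$raster, 0.5)), proto)
  tt <- ensemble_tuning_table(catl, rfs)
  expect_true(all(c("iqr_bf", "bandwidth", "size", "level_db") %in% names(tt)))
  expect_equal(nrow(tt), sum(catl$ensembles$evoked))
  expect_true(all(tt$iqr_bf >= 0, na.rm = TRUE))
})
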