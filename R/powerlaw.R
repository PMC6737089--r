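#' Logarithmically binned probability density
#'
#' Geometric bin edges from the minimum to the maximum value at
#' \code{bins_per_decade} bins per decade; density in each bin is
#' count / (n x bin width), so density integrates to 1 over the binned
#' range. Empty interior bins are retained with density 0.
#'
#' @param values positive numeric values (sizes or durations).
#' @param bins_per_decade bins per factor of 10.
#' @return object of class \code{binned_pdf}: list(bin_edges, centers
#'   (geometric midpoints), densities, counts, n_samples).
#' @export
log_bin_pdf <- function(values, bins_per_decade = 10) {
  if (length(values) < 1) stop("need at least one value")
  if (any(values <= 0)) stop("values must be positive")
  lo <- min(values); hi <- max(values)
  step <- 1 / bins_per_decade
  n_bins <- max(1L, ceiling((log10(hi) - log10(lo)) / step - 1e-12))
  edges <- 10^(log10(lo) + step * seq.int(0, n_bins))
  edges[length(edges)] <- max(edges[length(edges)], hi * (1 + 1e-12))
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, n_bins)
  widths <- diff(edges)
  structure(list(bin_edges = edges,
                 centers = sqrt(edges[-length(edges)] * edges[-1]),
                 densities = counts / (length(values) * widths),
                 counts = counts, n_samples = length(values)),
            class = "binned_pdf")
}

# zeta-normalized discrete power-law log-pmf at integer s >= x_min,
# slope alpha < -1 (a = -alpha): P(s) = s^-a / (zeta(a) - sum_{1..x_min-1} s^-a)
pl_log_z <- function(a, x_min) {
  z <- pracma::zeta(a)
  if (x_min > 1) z <- z - sum(seq_len(x_min - 1)^(-a))
  log(z)
}

#' Discrete power-law log-likelihood
#'
#' Sum of log zeta-normalized probability masses s^alpha / Z(alpha, x_min)
#' over the sample.
#'
#' @param values integer values >= x_min.
#' @param alpha slope (negative, < -1).
#' @param x_min lower support bound.
#' @return scalar log-likelihood.
#' @export
pl_loglik <- function(values, alpha, x_min = 1) {
  a <- -alpha
  if (a <= 1) stop("alpha must be < -1")
  sum(-a * log(values)) - length(values) * pl_log_z(a, x_min)
}

# discrete exponential (geometric on x_min, x_min+1, ...) log-likelihood at
# its closed-form MLE; returns list(loglik, q)
geom_mle <- function(values, x_min = 1) {
  m <- mean(values)
  q <- (m - x_min) / (m - x_min + 1)
  if (q <= 0) {  # all values equal x_min
    return(list(loglik = 0, q = 0,
                pointwise = rep(0, length(values))))
  }
  pw <- log(1 - q) + (values - x_min) * log(q)
  list(loglik = sum(pw), q = q, pointwise = pw)
}

# theoretical discrete power-law CDF evaluated at x_min..s_hi (unbounded
# support, zeta normalization)
pl_cdf_upto <- function(a, x_min, s_hi) {
  s <- seq.int(x_min, s_hi)
  cumsum(exp(-a * log(s))) / exp(pl_log_z(a, x_min))
}

#' Power-law slope by Kolmogorov-Smirnov minimization
#'
#' Scans \code{alpha_grid} and returns the slope whose discrete power-law
#' CDF minimizes the KS distance to the empirical CDF of the values at or
#' above \code{x_min}.
#'
#' @param values integer sizes or durations.
#' @param alpha_grid candidate slopes (default -4 to -1.01, step 0.01).
#' @param x_min lower cutoff (default 1, the minimum observable size).
#' @return object of class \code{powerlaw_fit} with \code{alpha_hat},
#'   \code{ks_distance}, \code{x_min}, \code{n}, \code{method = "ks"} and
#'   the full \code{ks_curve}.
#' @export
fit_alpha_ks <- function(values, alpha_grid = seq(-4, -1.01, by = 0.01),
                         x_min = 1) {
  values <- values[values >= x_min]
  if (!length(values)) stop("no values at or above x_min (empty tail)")
  if (length(values) < 50)
    warning("fewer than 50 values; slope estimate will be noisy")
  s_hi <- max(values)
  ecdf_v <- cumsum(tabulate(values - x_min + 1L, s_hi - x_min + 1L)) /
    length(values)
  logs <- log(seq.int(x_min, s_hi))
  ks <- vapply(alpha_grid, function(alpha) {
    a <- -alpha
    tcdf <- cumsum(exp(-a * logs)) / exp(pl_log_z(a, x_min))
    max(abs(ecdf_v - tcdf))
  }, numeric(1))
  best <- which.min(ks)
  structure(list(alpha_hat = alpha_grid[best], ks_distance = ks[best],
                 x_min = x_min, x_max = s_hi, n = length(values),
                 method = "ks",
                 ks_curve = data.frame(alpha = alpha_grid, ks = ks)),
            class = "powerlaw_fit")
}

#' Power law vs exponential model selection by maximum likelihood
#'
#' Fits a zeta-normalized discrete power law (numerical MLE) and a discrete
#' exponential / geometric (closed-form MLE) to the values, and reports the
#' log-likelihood ratio LLR = loglik_pl - loglik_exp (positive favors the
#' power law) with a Vuong-style normalized two-sided significance.
#'
#' @param values integer sizes or durations (>= x_min, n >= 2).
#' @param x_min lower support bound.
#' @param alpha_bounds search interval for the (negative) slope.
#' @return object of class \code{powerlaw_fit}: \code{alpha_hat},
#'   \code{loglik_pl}, \code{loglik_exp}, \code{llr}, \code{p_value},
#'   \code{ks_distance} (at the MLE slope), \code{x_min}, \code{n}; or, for
#'   a degenerate sample (all values equal), the same object with
#'   \code{degenerate = TRUE} and NA fit fields.
#' @export
fit_models_mle <- function(values, x_min = 1, alpha_bounds = c(-8, -1.001)) {
  values <- values[values >= x_min]
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) == 1L) {
    return(structure(list(alpha_hat = NA_real_, loglik_pl = NA_real_,
                          loglik_exp = NA_real_, llr = NA_real_,
                          p_value = NA_real_, ks_distance = NA_real_,
                          x_min = x_min, x_max = max(values),
                          n = length(values), method = "mle",
                          degenerate = TRUE),
                     class = "powerlaw_fit"))
  }
  opt <- stats::optimize(function(alpha) pl_loglik(values, alpha, x_min),
                         interval = alpha_bounds, maximum = TRUE, tol = 1e-6)
  alpha_hat <- opt$maximum
  a <- -alpha_hat
  pw_pl <- -a * log(values) - pl_log_z(a, x_min)
  ge <- geom_mle(values, x_min)
  d <- pw_pl - ge$pointwise
  llr <- sum(d)
  n <- length(values)
  p <- if (stats::sd(d) == 0) NA_real_ else
    2 * stats::pnorm(-abs(llr) / (stats::sd(d) * sqrt(n)))
  s_hi <- max(values)
  ecdf_v <- cumsum(tabulate(values - x_min + 1L, s_hi - x_min + 1L)) / n
  ks <- max(abs(ecdf_v - pl_cdf_upto(a, x_min, s_hi)))
  structure(list(alpha_hat = alpha_hat, loglik_pl = sum(pw_pl),
                 loglik_exp = ge$loglik, llr = llr, p_value = p,
                 ks_distance = ks, x_min = x_min, x_max = s_hi, n = n,
                 method = "mle", degenerate = FALSE),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<powerlaw_fit> degenerate sample (all values equal); LLR undefined\n")
    return(invisible(x))
  }
  cat(sprintf("<powerlaw_fit:%s> alpha_hat = %.3f, n = %d, x_min = %d",
              x$method, x$alpha_hat, x$n, x$x_min))
  if (!is.null(x$llr))
    cat(sprintf(", LLR = %.1f (p = %.3g)", x$llr, x$p_value))
  cat(sprintf(", KS = %.4f\n", x$ks_distance))
  invisible(x)
}

#' Scaling-collapse scan across sound levels
#'
#' For each candidate scaling factor b, every level's log-binned density
#' P(s) is transformed to x = s * L^b, y = P(s) * s^|alpha| (L = sound
#' level), curves are linearly interpolated in log x onto the common
#' overlapping support, and the collapse error is the mean over level pairs
#' of the weighted mean squared difference of log y after removing each
#' pair's mean offset. Offset removal: a pure rescaling of s shifts the
#' unnormalized density vertically by a constant, so curve shape, not
#' absolute height, is what must collapse. Weighting: each comparison point
#' is weighted by the (interpolated) harmonic mean of the two bins' counts,
#' i.e. by its sampling precision, so well-estimated parts of the
#' distributions dominate over one-count tail bins. Returns the b
#' minimizing the error (ties broken toward |b| = 0).
#'
#' @param values_by_level named list, one vector of sizes per sound level;
#'   names are the numeric levels (dB SPL).
#' @param alpha the fitted slope of the pooled distribution (negative).
#' @param b_grid candidate scaling factors (default -0.5..0.5, step 0.001).
#' @param bins_per_decade log-binning resolution.
#' @param n_interp interpolation points across the common support.
#' @return object of class \code{collapse_result}: \code{b_hat},
#'   \code{errors} (per grid point), \code{grid}, \code{per_level_curves},
#'   \code{degenerate} flag (single level).
#' @export
collapse_scan <- function(values_by_level, alpha,
                          b_grid = seq(-0.5, 0.5, by = 0.001),
                          bins_per_decade = 10, n_interp = 100) {
  L <- as.numeric(names(values_by_level))
  if (any(is.na(L))) stop("names of values_by_level must be numeric levels")
  curves <- lapply(values_by_level, function(v) {
    pdf <- log_bin_pdf(v, bins_per_decade)
    keep <- pdf$densities > 0
    list(lx = log(pdf$centers[keep]),
         ly = log(pdf$densities[keep]) - alpha * log(pdf$centers[keep]),
         counts = pdf$counts[keep])
  })
  if (length(curves) < 2) {
    return(structure(list(b_hat = 0, grid = b_grid,
                          errors = rep(NA_real_, length(b_grid)),
                          per_level_curves = curves, degenerate = TRUE),
                     class = "collapse_result"))
  }
  ns <- vapply(values_by_level, length, integer(1))
  if (any(ns < 50))
    warning("fewer than 50 values at some level; collapse will be noisy")
  pairs <- utils::combn(length(curves), 2)
  errors <- vapply(b_grid, function(b) {
    shift <- b * log(L)
    tot <- 0
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      xi <- curves[[i]]$lx + shift[i]; xj <- curves[[j]]$lx + shift[j]
      lo <- max(min(xi), min(xj)); hi <- min(max(xi), max(xj))
      if (hi <= lo) return(Inf)
      gx <- seq(lo, hi, length.out = n_interp)
      yi <- stats::approx(xi, curves[[i]]$ly, gx)$y
      yj <- stats::approx(xj, curves[[j]]$ly, gx)$y
      ci <- stats::approx(xi, curves[[i]]$counts, gx)$y
      cj <- stats::approx(xj, curves[[j]]$counts, gx)$y
      w <- 1 / (1 / ci + 1 / cj)
      d <- yi - yj
      dc <- d - sum(w * d) / sum(w)
      tot <- tot + sum(w * dc^2) / sum(w)
    }
    tot / ncol(pairs)
  }, numeric(1))
  minerr <- min(errors)
  cand <- which(errors <= minerr + 1e-15)
  b_hat <- b_grid[cand[which.min(abs(b_grid[cand]))]]
  structure(list(b_hat = b_hat, grid = b_grid, errors = errors,
                 per_level_curves = curves, degenerate = FALSE),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("<collapse_result> b_hat = %.3f%s\n", x$b_hat,
              if (isTRUE(x$degenerate)) " (degenerate: single level)" else ""))
  invisible(x)
}
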