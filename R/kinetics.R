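# Kinetic extraction from Delta E traces: onset and plateau (end-point)
# detection, pseudo-first- and second-order rate fitting, and mutual
# information against offline measurements.

# Centered boxcar smoothing followed by a centered finite-difference rate.
# Returns the smoothed series and its time derivative (Delta E per second).
smoothed_rate <- function(t, y, window) {
  n <- length(y)
  if (window < 2) abort("`window` must be >= 2 samples.")
  if (window > n) abort("`window` is longer than the trace.")
  half <- window %/% 2
  ys <- vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  rate <- numeric(n)
  if (n >= 3) {
    rate[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  rate[1] <- (ys[2] - ys[1]) / (t[2] - t[1])
  rate[n] <- (ys[n] - ys[n - 1]) / (t[n] - t[n - 1])
  list(smoothed = ys, rate = rate)
}

#' Smoothed rate of change of a time series
#'
#' Boxcar smoothing followed by centered finite differences — the rate
#' estimator used by [detect_onset()] and [detect_plateau()], exposed for
#' direct use (e.g. locating the time of maximum color-change rate).
#'
#' @param t Sample times (seconds).
#' @param y Sample values.
#' @param window Boxcar width in samples (>= 2).
#' @return A tibble with columns `t`, `smoothed`, `rate`.
#' @export
rate_of_change <- function(t, y, window = 5) {
  sr <- smoothed_rate(t, y, window)
  tibble(t = t, smoothed = sr$smoothed, rate = sr$rate)
}

single_roi <- function(trace, what) {
  if (length(unique(trace$roi)) != 1) {
    abort(sprintf("`%s` expects a single-ROI trace; filter or split first.", what))
  }
  trace
}

#' Detect the reaction plateau (end-point) of a Delta E trace
#'
#' The trace is boxcar-smoothed and differentiated with centered finite
#' differences. The plateau time is the earliest time `t*` at which the
#' absolute rate of Delta E change stays below `eps` for `min_run`
#' consecutive windows of `window` samples each, AND the Delta E at `t*`
#' has already reached `min_excursion`. The excursion guard prevents the
#' flat pre-reaction baseline from being flagged as an end-point; its
#' default of 3 Delta E units sits just above the ~2-unit perceptual and
#' instrumental noise floor.
#'
#' @param trace A single-ROI `color_trace`.
#' @param window Smoothing window in samples (>= 2).
#' @param eps Rate threshold in Delta E per second (> 0).
#' @param min_run Number of consecutive `window`-sample stretches the rate
#'   must stay below `eps`.
#' @param min_excursion Minimum Delta E at the candidate plateau.
#' @return The plateau time in seconds, or `NA_real_` if no plateau is
#'   reached.
#' @export
detect_plateau <- function(trace, window = 5, eps, min_run = 3, min_excursion = 3) {
  trace <- single_roi(trace, "detect_plateau")
  if (eps <= 0) abort("`eps` must be > 0.")
  sr <- smoothed_rate(trace$t, trace$delta_e, window)
  below <- abs(sr$rate) < eps
  need <- min_run * window
  n <- length(below)
  run <- rle_run_from(below)
  for (i in seq_len(n)) {
    if (below[i] && run[i] >= need && trace$delta_e[i] >= min_excursion) {
      return(trace$t[i])
    }
  }
  NA_real_
}

# run[i] = length of the TRUE run starting at i (0 if x[i] is FALSE)
rle_run_from <- function(x) {
  n <- length(x)
  run <- integer(n)
  acc <- 0L
  for (i in rev(seq_len(n))) {
    acc <- if (x[i]) acc + 1L else 0L
    run[i] <- acc
  }
  run
}

#' Detect the reaction onset of a Delta E trace
#'
#' Earliest time at which the smoothed rate of Delta E change first
#' exceeds `eps`; `NA_real_` if it never does (e.g. a constant trace).
#'
#' @inheritParams detect_plateau
#' @return Onset time in seconds, or `NA_real_`.
#' @export
detect_onset <- function(trace, window = 5, eps) {
  trace <- single_roi(trace, "detect_onset")
  if (eps <= 0) abort("`eps` must be > 0.")
  sr <- smoothed_rate(trace$t, trace$delta_e, window)
  hit <- which(sr$rate > eps)
  if (length(hit) == 0) return(NA_real_)
  trace$t[hit[1]]
}

#' Fit a rate law to a Delta E trace
#'
#' Least-squares fit of `delta_e(t)` to a pseudo-first-order saturation
#' curve `A * (1 - exp(-k * t))` or a second-order curve
#' `A * k * t / (1 + k * t)`. In the second-order model the initial
#' concentration is fixed to 1, so `k` absorbs the concentration scale:
#' only the product of rate constant and concentration is identifiable
#' from a unitless color trace. The initializer is deterministic: `A0` is
#' the maximum Delta E and `k0` comes from the time to half-maximum.
#' Non-convergence is reported in the returned object (`converged =
#' FALSE`), never raised as an error.
#'
#' @param trace A single-ROI `color_trace` with >= 10 samples and a
#'   non-degenerate Delta E excursion.
#' @param model `"first_order"` or `"second_order"`.
#' @return A `rate_fit` object; see [tidy.rate_fit()] and
#'   [glance.rate_fit()].
#' @export
fit_rate <- function(trace, model = c("first_order", "second_order")) {
  model <- match.arg(model)
  trace <- single_roi(trace, "fit_rate")
  t <- trace$t - trace$t[1]
  y <- trace$delta_e
  if (length(y) < 10) abort("Need >= 10 samples to fit a rate law.")
  if (max(y) - min(y) <= 0) abort("Delta E excursion is degenerate (constant trace).")
  A0 <- max(y)
  i_half <- which(y >= A0 / 2)[1]
  t_half <- max(t[i_half], t[2])
  k0 <- if (model == "first_order") log(2) / t_half else 1 / t_half
  form <- if (model == "first_order") {
    y ~ A * (1 - exp(-k * tt))
  } else {
    y ~ A * (k * tt) / (1 + k * tt)
  }
  dat <- data.frame(tt = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(model = model, k = NA_real_, amplitude = NA_real_,
                rss = NA_real_, converged = FALSE,
                message = conditionMessage(fit),
                n = length(y), roi = trace$roi[1], data = dat, fit = NULL)
  } else {
    cf <- stats::coef(fit)
    out <- list(model = model, k = unname(cf["k"]), amplitude = unname(cf["A"]),
                rss = sum(stats::residuals(fit)^2), converged = TRUE,
                message = NULL,
                n = length(y), roi = trace$roi[1], data = dat, fit = fit)
  }
  structure(out, class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: %s, ROI '%s'>\n", x$model, x$roi))
  if (x$converged) {
    cat(sprintf("  k = %.6g, amplitude = %.4g Delta E, rss = %.4g (n = %d)\n",
                x$k, x$amplitude, x$rss, x$n))
  } else {
    cat("  did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' Tidy a rate fit into one row per parameter
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.rate_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("amplitude", "k"),
                  estimate = NA_real_, std.error = NA_real_))
  }
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("amplitude", "k"),
    estimate = c(sm["A", "Estimate"], sm["k", "Estimate"]),
    std.error = c(sm["A", "Std. Error"], sm["k", "Std. Error"])
  )
}

#' One-row summary of a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A tibble with columns `roi`, `model`, `k`, `amplitude`, `rss`,
#'   `converged`, `nobs`.
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(roi = x$roi, model = x$model, k = x$k, amplitude = x$amplitude,
         rss = x$rss, converged = x$converged, nobs = x$n)
}

#' Per-ROI kinetic summary
#'
#' Runs onset detection, plateau detection and rate fitting on each ROI of
#' a trace and gathers the results in one tidy table.
#'
#' @param trace A `color_trace` (possibly multi-ROI).
#' @param model Rate-law model passed to [fit_rate()].
#' @param window,eps_onset,eps_plateau,min_run,min_excursion Detection
#'   parameters; see [detect_onset()] and [detect_plateau()].
#' @return A tibble with one row per ROI: `roi`, `onset_time`,
#'   `plateau_time`, `model`, `k`, `amplitude`, `rss`, `converged`.
#' @export
kinetic_summary <- function(trace, model = "first_order", window = 5,
                            eps_onset = 0.1, eps_plateau = 0.05,
                            min_run = 3, min_excursion = 3) {
  df <- trace
  class(df) <- c("tbl_df", "tbl", "data.frame")
  purrr::map_dfr(split(df, df$roi), function(tr) {
    fit <- tryCatch(fit_rate(tr, model), error = function(e) NULL)
    tibble(
      roi = tr$roi[1],
      onset_time = detect_onset(tr, window, eps_onset),
      plateau_time = detect_plateau(tr, window, eps_plateau, min_run, min_excursion),
      model = model,
      k = if (is.null(fit)) NA_real_ else fit$k,
      amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
      rss = if (is.null(fit)) NA_real_ else fit$rss,
      converged = if (is.null(fit)) FALSE else fit$converged
    )
  })
}

#' Mutual information between two sample vectors
#'
#' Histogram plug-in estimator on an equal-width `bins x bins` grid:
#' \deqn{I = \sum_{ij} p_{ij} \ln\!\left(\frac{p_{ij}}{p_i q_j}\right)}
#' with `0 * ln 0 = 0`. Captures both linear and nonlinear dependence;
#' reported in nats. The plug-in estimator is biased upward at small
#' sample sizes, so use generous `n` relative to `bins^2`.
#'
#' @param x,y Numeric vectors of equal length (>= 20).
#' @param bins Number of equal-width bins per axis (>= 2).
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 16) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 20) abort("Need at least 20 samples.")
  if (bins < 2) abort("`bins` must be >= 2.")
  bx <- bin_index(x, bins)
  by <- bin_index(y, bins)
  counts <- matrix(tabulate((bx - 1L) * bins + by, nbins = bins * bins),
                   nrow = bins)
  p <- counts / sum(counts)
  px <- colSums(p)  # marginal of x (column index = bx)
  py <- rowSums(p)
  mi <- 0
  nz <- which(p > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]
    mi <- mi + p[i, j] * log(p[i, j] / (px[j] * py[i]))
  }
  max(mi, 0)
}

bin_index <- function(x, bins) {
  rg <- range(x)
  if (rg[1] == rg[2]) return(rep(1L, length(x)))
  idx <- floor((x - rg[1]) / (rg[2] - rg[1]) * bins) + 1L
  pmin(as.integer(idx), bins)
}
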