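# Time-lapse patch-density kinetics ------------------------------------------

#' Patch-density time series (median and IQR per frame)
#'
#' Per frame, the median and interquartile range of the per-cell patch
#' density. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7). Frames with zero cells are dropped with a
#' warning.
#'
#' @param metrics_by_frame list of per-frame metric data frames (each with a
#'   `patch_density_per_um` column, e.g. from [quantify_field()]), or a
#'   single data frame with a `time_min` column.
#' @param times_min frame times in minutes (ignored for the single-data-frame
#'   form); strictly increasing.
#' @param value column to summarize (default `"patch_density_per_um"`).
#' @return an `mcc_decay_curve` data frame: time_min, median, q1, q3,
#'   n_cells.
#' @export
patch_density_timeseries <- function(metrics_by_frame, times_min = NULL,
                                     value = "patch_density_per_um") {
  if (is.data.frame(metrics_by_frame)) {
    check_that("time_min" %in% names(metrics_by_frame),
               "single-data-frame input needs a time_min column")
    times_min <- sort(unique(metrics_by_frame$time_min))
    metrics_by_frame <- lapply(times_min, function(t)
      metrics_by_frame[metrics_by_frame$time_min == t, , drop = FALSE])
  }
  check_that(length(metrics_by_frame) >= 2, "need at least 2 frames")
  check_that(length(times_min) == length(metrics_by_frame),
             "times_min must match the number of frames")
  check_that(all(diff(times_min) > 0), "times must be strictly increasing")
  rows <- lapply(seq_along(times_min), function(i) {
    v <- metrics_by_frame[[i]][[value]]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning(sprintf("frame at t = %g min has zero cells; dropped", times_min[i]))
      return(NULL)
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(time_min = times_min[i], median = q[2], q1 = q[1], q3 = q[3],
               n_cells = length(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mcc_decay_curve", class(out))
  out
}

#' Half-decay time of a patch-density curve
#'
#' `method = "crossing"` (default): the first time the median curve reaches
#' half of its frame-0 value, linearly interpolated between the bracketing
#' frames. `method = "expfit"`: least-squares fit of
#' `d0 * 2^(-t / T)` to the medians, returning `T`.
#'
#' @param curve an `mcc_decay_curve` (>= 3 frames).
#' @param method `"crossing"` or `"expfit"`.
#' @return half-decay time in minutes, or `NA_real_` (attribute `reason`)
#'   when the curve never reaches half (crossing) or the fit fails. A gross
#'   mid-series increase (> 20% above the initial value) triggers a warning
#'   but still returns a value.
#' @export
half_decay_time <- function(curve, method = c("crossing", "expfit")) {
  method <- match.arg(method)
  check_that(inherits(curve, "mcc_decay_curve") || is.data.frame(curve),
             "curve must be an mcc_decay_curve")
  check_that(nrow(curve) >= 3, "need at least 3 frames")
  t <- curve$time_min; d <- curve$median
  d0 <- d[1]
  if (any(d[-1] > 1.2 * d0))
    warning("half_decay_time: curve rises more than 20% above its initial value")
  if (method == "crossing") {
    half <- d0 / 2
    below <- which(d <= half)
    if (!length(below))
      return(structure(NA_real_, reason = "curve never reaches half of d0"))
    i <- below[1]
    if (i == 1) return(0)
    # linear interpolation between the bracketing frames
    f <- (d[i - 1] - half) / (d[i - 1] - d[i])
    t[i - 1] + f * (t[i] - t[i - 1])
  } else {
    if (d0 <= 0 || all(d <= 0))
      return(structure(NA_real_, reason = "non-positive curve"))
    # log-linear start value, then least squares on the original scale
    pos <- d > 0
    sl <- stats::coef(stats::lm(log2(d[pos]) ~ t[pos]))[2]
    T0 <- if (is.finite(sl) && sl < 0) -1 / sl else max(t)
    obj <- function(p) sum((d - p[1] * 2^(-t / p[2]))^2)
    fit <- tryCatch(stats::optim(c(d0, T0), obj, method = "L-BFGS-B",
                                 lower = c(1e-12, 1e-6)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$par[2]))
      return(structure(NA_real_, reason = "exponential fit failed"))
    fit$par[2]
  }
}
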