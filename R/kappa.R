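# Information-transfer constant estimation. For a voltage series V(t) and a
# time interval dt, the per-instant constant is
#     kappa(t; dt) = ln|V(t + dt) - V(t)| / ln(dt),   dt in seconds,
# the exponent a local power law |dV| ~ dt^kappa would need to produce the
# observed increment. Instants with V(t) = V(t + dt) are excluded (log of
# zero); dt = 1 s is rejected (ln 1 = 0 in the denominator).

#' Per-instant information-transfer constants for one segment
#'
#' Computes `kappa = ln|V(t + dt) - V(t)| / ln(dt)` (natural log, `dt` in
#' seconds) at every instant `t = 1 .. n - lag`, where
#' `lag = round(dt * fs)`. Instants where the voltage difference is exactly
#' zero are excluded from the values and counted in `n_excluded`; recordings
#' are integer-quantized, so exact ties are common at short lags.
#'
#' Note that kappa depends on the voltage unit: rescaling the signal by a
#' factor `a` shifts every kappa by `ln(a)/ln(dt)`.
#'
#' @param seg A [voltage_segment()].
#' @param delta_t_s Time interval in seconds. Must not be 1 (the log of the
#'   interval would vanish) and must correspond to a whole number of samples
#'   to within a relative error of 1e-6 unless `allow_lag_rounding = TRUE`.
#' @param allow_lag_rounding Accept a `delta_t_s` that is not a whole
#'   number of samples, rounding the lag to the nearest sample.
#' @return An object of class `kappa_series` with fields `delta_t_s`,
#'   `lag_samples`, `values`, `n_total`, `n_excluded`, `subject_id`,
#'   `state`, `segment_id`, `units`.
#' @examples
#' ramp <- voltage_segment((0:14999) / 250, fs = 250)
#' ks <- kappa_series(ramp, 0.004)
#' mean(ks$values)  # exactly 1: |dV| = dt so the logs cancel
#' @export
kappa_series <- function(seg, delta_t_s, allow_lag_rounding = FALSE) {
  stopifnot(inherits(seg, "voltage_segment"))
  if (!is.numeric(delta_t_s) || length(delta_t_s) != 1L || delta_t_s <= 0)
    stop_param("delta_t_s must be a single positive number")
  if (delta_t_s == 1)
    stop_param("delta_t_s = 1 s is not allowed: log(delta_t) = 0 undefined")
  lag_exact <- delta_t_s * seg$fs
  lag <- as.integer(round(lag_exact))
  if (lag < 1L)
    stop_param("delta_t_s = %g s rounds to a zero-sample lag at fs = %g Hz",
               delta_t_s, seg$fs)
  if (!allow_lag_rounding && abs(lag - lag_exact) > 1e-6 * lag_exact)
    stop_param(paste0("delta_t_s = %g s is not a whole number of samples at ",
                      "fs = %g Hz (use allow_lag_rounding to override)"),
               delta_t_s, seg$fs)
  n <- length(seg$samples)
  if (lag >= n)
    stop_param("lag (%d samples) must be shorter than the segment (%d)",
               lag, n)
  dv <- seg$samples[(1L + lag):n] - seg$samples[1L:(n - lag)]
  zero <- dv == 0
  values <- log(abs(dv[!zero])) / log(delta_t_s)
  structure(
    list(delta_t_s = delta_t_s, lag_samples = lag, values = values,
         n_total = n - lag, n_excluded = sum(zero),
         subject_id = seg$subject_id, state = seg$state,
         segment_id = seg$segment_id, units = seg$units),
    class = "kappa_series")
}

#' @export
print.kappa_series <- function(x, ...) {
  cat(sprintf(
    "<kappa_series> %s/%s/%s dt=%g s (lag %d): %d values, %d excluded\n",
    x$subject_id, x$state, x$segment_id, x$delta_t_s, x$lag_samples,
    length(x$values), x$n_excluded))
  invisible(x)
}

#' Summarize a kappa series for one segment
#'
#' Reduces a [kappa_series()] to its arithmetic mean and the fraction of
#' values below a low-information-transfer threshold. The mean is taken
#' over the retained values only — excluded zero-difference instants do not
#' enter the denominator, so an excluded datum is not silently counted as
#' kappa = 0; `n_excluded` is reported alongside.
#'
#' @param ks A [kappa_series()].
#' @param low_threshold Kappa values below this count as low information
#'   transfer (default 0.2).
#' @return An object of class `segment_summary` (a one-row data.frame) with
#'   columns `subject_id`, `state`, `segment_id`, `delta_t_s`, `kappa_avg`,
#'   `low_it_fraction`, `n_values`, `n_excluded`, `units`.
#' @export
kappa_summary <- function(ks, low_threshold = 0.2) {
  stopifnot(inherits(ks, "kappa_series"))
  if (length(ks$values) == 0L)
    stop_degenerate(
      "degenerate segment %s/%s/%s: all %d instants excluded at dt=%g s",
      ks$subject_id, ks$state, ks$segment_id, ks$n_total, ks$delta_t_s)
  out <- data.frame(
    subject_id = ks$subject_id, state = ks$state, segment_id = ks$segment_id,
    delta_t_s = ks$delta_t_s,
    kappa_avg = mean(ks$values),
    low_it_fraction = mean(ks$values < low_threshold),
    n_values = length(ks$values), n_excluded = ks$n_excluded,
    units = ks$units, stringsAsFactors = FALSE)
  class(out) <- c("segment_summary", "data.frame")
  out
}

#' Default time-interval grid (seconds)
#'
#' The decade grid of time intervals at which segments are summarized:
#' 0.004 s (the 250 Hz sampling interval), 0.04 s, 0.4 s and 4 s.
#' @return Numeric vector of intervals in seconds.
#' @export
default_delta_ts <- function() c(0.004, 0.04, 0.4, 4)

#' Multi-scale segment summaries
#'
#' Runs [kappa_series()] and [kappa_summary()] at each requested time
#' interval and row-binds the results.
#'
#' @param seg A [voltage_segment()].
#' @param delta_ts Time intervals in seconds (default [default_delta_ts()]).
#' @param low_threshold Passed to [kappa_summary()].
#' @param allow_lag_rounding Passed to [kappa_series()].
#' @return A data.frame with one row per interval.
#' @export
multiscale_summaries <- function(seg, delta_ts = default_delta_ts(),
                                 low_threshold = 0.2,
                                 allow_lag_rounding = FALSE) {
  rows <- lapply(delta_ts, function(dt) {
    tryCatch(
      kappa_summary(kappa_series(seg, dt,
                                 allow_lag_rounding = allow_lag_rounding),
                    low_threshold = low_threshold),
      error = function(e) {
        stop(errorCondition(
          sprintf("at delta_t_s = %g s: %s", dt, conditionMessage(e)),
          class = class(e)))
      })
  })
  do.call(rbind, rows)
}

#' Hurst exponent from the increment scaling of a segment
#'
#' For a self-similar signal with increment variance proportional to
#' `dt^(2H)`, the mean of `ln|V(t + dt) - V(t)|` grows linearly in
#' `ln(dt)` with slope H. This regresses the mean log absolute increment on
#' `ln(dt)` over a grid of time intervals (a log-log structure-function
#' fit at order zero) and returns the slope.
#'
#' @param seg A [voltage_segment()].
#' @param delta_ts Time intervals in seconds (default [default_delta_ts()]).
#' @return Estimated Hurst exponent (slope of the regression).
#' @export
estimate_hurst <- function(seg, delta_ts = default_delta_ts()) {
  mean_log_abs <- vapply(delta_ts, function(dt) {
    ks <- kappa_series(seg, dt)
    if (length(ks$values) == 0L)
      stop_degenerate("all increments zero at dt = %g s", dt)
    mean(ks$values) * log(dt)
  }, numeric(1L))
  unname(stats::coef(stats::lm(mean_log_abs ~ log(delta_ts)))[2L])
}

#' Append segment summaries to a TSV file
#'
#' @param summaries A data.frame of [kappa_summary()] rows.
#' @param path Output TSV path; the header is written only when the file
#'   does not yet exist.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summaries, path) {
  fresh <- !file.exists(path)
  df <- as.data.frame(summaries)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = fresh, quote = FALSE, append = !fresh))
  invisible(path)
}

#' Read a segment-summary TSV
#' @param path TSV written by [write_summary_tsv()].
#' @return A data.frame.
#' @export
read_summary_tsv <- function(path) {
  if (!file.exists(path))
    stop_io("summary TSV does not exist: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
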