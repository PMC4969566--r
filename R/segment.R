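#' Construct a labeled voltage segment
#'
#' A `voltage_segment` holds one stretch of single-channel voltage samples
#' \eqn{V(t)} together with its sampling rate and bookkeeping metadata
#' (subject, state of consciousness, segment id, start time). All
#' downstream kappa estimation operates on this container.
#'
#' Because the information-transfer constant involves the logarithm of a
#' dimensional voltage difference, kappa values depend on the recording
#' unit; the unit label is therefore carried along verbatim and never
#' rescaled.
#'
#' @param samples Numeric vector of voltage readings in native physical
#'   units. Must be finite and of length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param units Free-text unit label (e.g. `"mV"`, `"uV"`).
#' @param subject_id,state,segment_id Text metadata labels.
#' @param t0 Segment start time in seconds within its recording.
#' @return An object of class `voltage_segment`.
#' @examples
#' seg <- voltage_segment(sin(seq(0, 2 * pi, length.out = 500)), fs = 250)
#' seg
#' @export
voltage_segment <- function(samples, fs, units = "mV", subject_id = "s01",
                            state = "unknown", segment_id = "seg001",
                            t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop_param("voltage segment needs at least 2 samples, got %d",
               length(samples))
  if (!all(is.finite(samples)))
    stop_param("voltage segment contains %d non-finite sample(s)",
               sum(!is.finite(samples)))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_param("sampling rate must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs), units = as.character(units),
         subject_id = as.character(subject_id), state = as.character(state),
         segment_id = as.character(segment_id), t0 = as.numeric(t0)),
    class = "voltage_segment"
  )
}

#' @export
print.voltage_segment <- function(x, ...) {
  cat(sprintf(
    "<voltage_segment> %s/%s/%s: %d samples @ %g Hz (%.6g s) in %s, t0=%g s\n",
    x$subject_id, x$state, x$segment_id, length(x$samples), x$fs,
    length(x$samples) / x$fs, x$units, x$t0))
  invisible(x)
}

#' @export
length.voltage_segment <- function(x) length(x$samples)

#' Duration of a voltage segment in seconds
#' @param seg A `voltage_segment`.
#' @return Duration in seconds.
#' @export
segment_duration <- function(seg) length(seg$samples) / seg$fs

#' Construct a stage annotation
#'
#' A hypnogram-style annotation: a set of non-overlapping half-open
#' intervals `[start_s, end_s)`, each carrying a stage label
#' (e.g. `"waking"`, `"stage2"`, `"stage3"`).
#'
#' @param start_s,end_s Numeric vectors of interval boundaries in seconds.
#' @param stage Character vector of stage labels, one per interval.
#' @return An object of class `stage_annotation` (a data.frame).
#' @export
stage_annotation <- function(start_s, end_s, stage) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  stage <- as.character(stage)
  n <- length(start_s)
  if (length(end_s) != n || length(stage) != n)
    stop_param("start_s, end_s and stage must have equal length")
  if (n == 0L)
    stop_param("empty stage annotation")
  if (any(end_s <= start_s))
    stop_param("annotation intervals must satisfy end_s > start_s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; stage <- stage[o]
  if (n > 1L && any(start_s[-1L] < end_s[-n] - 1e-9))
    stop_param("annotation intervals overlap")
  structure(data.frame(start_s = start_s, end_s = end_s, stage = stage,
                       stringsAsFactors = FALSE),
            class = c("stage_annotation", "data.frame"))
}
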