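# Recording I/O: EDF/EDF+ (the polysomnography standard) and a minimal
# two-column CSV dialect, plus hypnogram-style TSV annotations and epoch
# segmentation.

#' Read a voltage recording from EDF/EDF+ or CSV
#'
#' For EDF the sampling rate and physical unit come from the file header and
#' samples are returned in physical units (digital-to-physical scaling per
#' signal). For CSV (`time_s,voltage` with header) the sampling rate is
#' inferred from the median time step, which must be uniform to within one
#' part in 1e4.
#'
#' @param path Path to an `.edf` or `.csv` file.
#' @param channel For EDF: channel label (text) or 1-based index. Ignored
#'   for CSV.
#' @param subject_id,state Metadata labels attached to the returned segment.
#' @param units Unit label for CSV input (EDF carries its own).
#' @return A full-length [voltage_segment()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time_s = (0:499) / 250, voltage = rnorm(500)),
#'           f, row.names = FALSE)
#' rec <- read_recording(f)
#' rec$fs
#' @export
read_recording <- function(path, channel = 1L, subject_id = "s01",
                           state = "unknown", units = "mV") {
  if (!file.exists(path))
    stop_io("input file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("edf", "rec")) {
    read_edf_channel(path, channel, subject_id = subject_id, state = state)
  } else if (ext %in% c("csv", "txt")) {
    read_csv_recording(path, subject_id = subject_id, state = state,
                       units = units)
  } else {
    stop_io("unsupported recording format '%s' (expected .edf or .csv): %s",
            ext, path)
  }
}

read_csv_recording <- function(path, subject_id, state, units) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_io("unreadable CSV %s: %s",
                                             path, conditionMessage(e)))
  if (!all(c("time_s", "voltage") %in% names(df)))
    stop_io("CSV %s must have header 'time_s,voltage'", path)
  tt <- as.numeric(df$time_s)
  v <- as.numeric(df$voltage)
  if (length(v) < 2L)
    stop_io("CSV %s has fewer than 2 samples", path)
  if (!all(is.finite(v)))
    stop_io("CSV %s contains non-finite voltage values", path)
  dt <- diff(tt)
  med <- stats::median(dt)
  if (med <= 0 || any(abs(dt - med) > 1e-4 * med))
    stop_io("non-uniform time base in %s (median step %g s)", path, med)
  fs <- 1 / med
  # snap to an integer rate when the time column was printed at finite
  # precision (e.g. 0.004 s -> 250 Hz)
  if (abs(fs - round(fs)) < 1e-4 * fs) fs <- round(fs)
  voltage_segment(v, fs = fs, units = units, subject_id = subject_id,
                  state = state, segment_id = basename(path), t0 = tt[1L])
}

#' Read a stage annotation TSV
#'
#' Expects three tab-separated columns `start_s`, `end_s`, `stage` (header
#' optional); intervals are half-open `[start_s, end_s)`.
#'
#' @param path Path to the TSV file.
#' @return A [stage_annotation()].
#' @export
read_stage_annotation <- function(path) {
  if (!file.exists(path))
    stop_io("annotation file does not exist: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("start", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop_io("annotation TSV %s needs 3 columns (start_s, end_s, stage)", path)
  stage_annotation(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a stage annotation TSV
#' @param ann A [stage_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split a recording into fixed-length labeled epochs
#'
#' Each annotated interval is tiled with non-overlapping epochs of exactly
#' `epoch_s * fs` samples starting at the interval start; trailing partial
#' epochs are dropped. Each epoch inherits the interval's stage label and
#' receives a sequential segment id.
#'
#' @param rec A full-length [voltage_segment()].
#' @param ann A [stage_annotation()] covered by `rec`.
#' @param epoch_s Epoch length in seconds (default 60, one-minute tracings).
#' @return A list of [voltage_segment()]s (possibly empty, with a warning,
#'   if no interval fits a whole epoch).
#' @export
segment_recording <- function(rec, ann, epoch_s = 60) {
  stopifnot(inherits(rec, "voltage_segment"))
  if (!inherits(ann, "stage_annotation"))
    stop_param("ann must be a stage_annotation")
  if (epoch_s <= 0)
    stop_param("epoch_s must be positive")
  fs <- rec$fs
  n_epoch <- as.integer(round(epoch_s * fs))
  rec_end <- rec$t0 + length(rec$samples) / fs
  if (any(ann$start_s < rec$t0 - 1e-9) || any(ann$end_s > rec_end + 1e-9))
    stop_param("annotation extends beyond the recording [%g, %g] s",
               rec$t0, rec_end)
  out <- list()
  idx <- 0L
  for (i in seq_len(nrow(ann))) {
    k <- floor((ann$end_s[i] - ann$start_s[i]) / epoch_s + 1e-9)
    if (k < 1L) next
    start_sample <- as.integer(round((ann$start_s[i] - rec$t0) * fs)) + 1L
    for (j in seq_len(k)) {
      idx <- idx + 1L
      a <- start_sample + (j - 1L) * n_epoch
      seg <- voltage_segment(
        rec$samples[a:(a + n_epoch - 1L)], fs = fs, units = rec$units,
        subject_id = rec$subject_id, state = ann$stage[i],
        segment_id = sprintf("seg%03d", idx),
        t0 = ann$start_s[i] + (j - 1L) * epoch_s)
      out[[idx]] <- seg
    }
  }
  if (idx == 0L)
    warning("no annotated interval fits a whole epoch of ", epoch_s, " s; ",
            "returning an empty segment list")
  out
}
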