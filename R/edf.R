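# Minimal EDF/EDF+ support. The format is a fixed-width ASCII header (256
# bytes global + 256 bytes per signal) followed by data records of 16-bit
# little-endian integers, with per-signal linear digital-to-physical
# scaling. Only continuous single-frequency reading and a fixture-grade
# writer are provided; annotation signals ("EDF Annotations") are skipped
# when picking channels by index.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

# Field layout of the per-signal header block (each field stored for all ns
# signals consecutively): label 16, transducer 80, unit 8, phys_min 8,
# phys_max 8, dig_min 8, dig_max 8, prefilter 80, samples_per_record 8,
# reserved 32.
edf_signal_fields <- function(sig_raw, ns) {
  widths <- c(label = 16L, transducer = 80L, unit = 8L, phys_min = 8L,
              phys_max = 8L, dig_min = 8L, dig_max = 8L, prefilter = 80L,
              spr = 8L, reserved = 32L)
  out <- list()
  pos <- 1L
  for (nm in names(widths)) {
    w <- widths[[nm]]
    out[[nm]] <- vapply(seq_len(ns), function(i) {
      from <- pos + (i - 1L) * w
      trimws(substr(sig_raw, from, from + w - 1L))
    }, character(1L))
    pos <- pos + ns * w
  }
  out
}

read_edf_channel <- function(path, channel, subject_id = "s01",
                             state = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr_raw, type = "bytes") < 256L)
    stop_io("truncated EDF header in %s", path)
  fld <- function(from, len) trimws(substr(hdr_raw, from, from + len - 1L))
  n_records <- as.integer(fld(237, 8))
  record_s <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || is.na(record_s))
    stop_io("invalid EDF header in %s", path)
  sig_raw <- readChar(con, 256L * ns, useBytes = TRUE)
  sig <- edf_signal_fields(sig_raw, ns)
  spr <- as.integer(sig$spr)
  data_labels <- sig$label != "EDF Annotations"
  if (is.character(channel)) {
    ch <- match(channel, sig$label)
    if (is.na(ch))
      stop_io("channel '%s' not found in %s (available: %s)", channel, path,
              paste(sig$label[data_labels], collapse = ", "))
  } else {
    ch <- which(data_labels)[as.integer(channel)]
    if (is.na(ch))
      stop_io("channel index %d out of range in %s", channel, path)
  }
  pm <- as.numeric(sig$phys_min[ch]); pM <- as.numeric(sig$phys_max[ch])
  dm <- as.numeric(sig$dig_min[ch]);  dM <- as.numeric(sig$dig_max[ch])
  if (dM <= dm) stop_io("invalid digital range for channel %d in %s", ch, path)
  gain <- (pM - pm) / (dM - dm)
  rec_len <- sum(spr)
  digital <- matrix(NA_integer_, nrow = spr[ch], ncol = n_records)
  offsets <- c(0L, cumsum(spr))[ch]
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2L,
                   signed = TRUE, endian = "little")
    if (length(rec) < rec_len)
      stop_io("truncated data record %d in %s", r, path)
    digital[, r] <- rec[(offsets + 1L):(offsets + spr[ch])]
  }
  phys <- pm + (as.vector(digital) - dm) * gain
  fs <- spr[ch] / record_s
  voltage_segment(phys, fs = fs,
                  units = if (nzchar(sig$unit[ch])) sig$unit[ch] else "mV",
                  subject_id = subject_id, state = state,
                  segment_id = basename(path), t0 = 0)
}

#' Write a single-channel EDF file (fixture-grade)
#'
#' Writes a valid EDF file with one data signal, one-second data records,
#' and physical scaling spanning the sample range. Intended for building
#' test fixtures and small exports; samples are quantized to the format's
#' 16-bit integer resolution.
#'
#' @param seg A [voltage_segment()] whose sampling rate is a whole number
#'   and whose duration is a whole number of seconds.
#' @param path Output path.
#' @param label Channel label stored in the header (<= 16 chars).
#' @return `path`, invisibly.
#' @export
write_edf <- function(seg, path, label = "EEG") {
  stopifnot(inherits(seg, "voltage_segment"))
  fs <- seg$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_param("EDF writer requires an integer sampling rate, got %g", fs)
  fs <- as.integer(round(fs))
  n <- length(seg$samples)
  n_records <- n %/% fs
  if (n_records < 1L)
    stop_param("segment shorter than one 1-second data record")
  if (n %% fs != 0L)
    warning("truncating ", n %% fs, " samples that do not fill a record")
  x <- seg$samples[seq_len(n_records * fs)]
  pm <- min(x); pM <- max(x)
  if (pM <= pm) pM <- pm + 1  # constant signal: avoid zero gain
  dm <- -32768; dM <- 32767
  digital <- as.integer(round((x - pm) / (pM - pm) * (dM - dm) + dm))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                         # version
    edf_pad(seg$subject_id, 80),             # patient id
    edf_pad(paste("Startdate 01-JAN-2000", seg$segment_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * 2L, 8),                   # header bytes (1 signal)
    edf_pad("", 44),
    edf_pad(n_records, 8),
    edf_num(1, 8),                           # record duration 1 s
    edf_pad(1L, 4))
  sig <- paste0(
    edf_pad(label, 16), edf_pad("", 80), edf_pad(seg$units, 8),
    edf_num(pm, 8), edf_num(pM, 8), edf_num(dm, 8), edf_num(dM, 8),
    edf_pad("", 80), edf_pad(fs, 8), edf_pad("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(path)
}
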