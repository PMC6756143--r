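#' Construct a single-lead ECG recording
#'
#' The elementary container of the package: a vector of ECG samples (in
#' signal units, typically millivolts) with its sampling rate and an
#' identifier. PhysioNet-style apnea recordings are sampled at 100 Hz.
#'
#' @param record_id character identifier of the recording.
#' @param samples numeric vector of ECG samples.
#' @param fs sampling rate in Hz (default 100).
#' @return An object of class `ecg_recording` with fields `record_id`,
#'   `samples`, `fs` and a computed `duration_s`.
#' @export
#' @examples
#' rec <- ecg_recording("demo", sin(seq(0, 2 * pi, length.out = 600)), fs = 100)
#' rec$duration_s
ecg_recording <- function(record_id, samples, fs = 100) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_validation("'samples' must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_validation("'fs' must be a single positive number")
  }
  structure(
    list(record_id = as.character(record_id),
         samples = as.numeric(samples),
         fs = as.numeric(fs),
         duration_s = length(samples) / fs),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %s: %d samples @ %g Hz (%.1f min)\n",
              x$record_id, length(x$samples), x$fs, x$duration_s / 60))
  invisible(x)
}

#' Construct a per-minute apnea/normal label sequence
#'
#' One label per whole minute of a recording, `"A"` (an apnea/hypopnea event
#' occurred within the minute) or `"N"` (normal), mirroring the expert
#' annotation convention of the PhysioNet Apnea-ECG benchmark.
#'
#' @param record_id character identifier.
#' @param labels character vector over `c("A", "N")`.
#' @return An object of class `minute_labels`.
#' @export
minute_labels <- function(record_id, labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    stop_validation("'labels' must be non-empty")
  }
  if (!all(labels %in% c(APNEA, NORMAL))) {
    stop_validation("labels must be 'A' (apnea) or 'N' (normal)")
  }
  structure(list(record_id = as.character(record_id), labels = labels),
            class = "minute_labels")
}

#' @export
print.minute_labels <- function(x, ...) {
  cat(sprintf("<minute_labels> %s: %d minutes, %d apnea (%.1f%%)\n",
              x$record_id, length(x$labels), sum(x$labels == APNEA),
              100 * mean(x$labels == APNEA)))
  invisible(x)
}

#' Construct apnea event annotations
#'
#' Continuous event-interval annotations (UCD style): one row per
#' apnea/hypopnea event with its onset and duration in seconds from the
#' start of the recording.
#'
#' @param onset_s numeric vector of event onsets in seconds (>= 0).
#' @param duration_s numeric vector of event durations in seconds (> 0).
#' @return A data.frame of class `apnea_events` with columns `onset_s`,
#'   `duration_s`.
#' @export
apnea_events <- function(onset_s = numeric(), duration_s = numeric()) {
  if (length(onset_s) != length(duration_s)) {
    stop_validation("onset_s and duration_s must have equal length")
  }
  if (any(onset_s < 0)) stop_validation("event onsets must be >= 0")
  if (any(duration_s <= 0)) stop_validation("event durations must be > 0")
  structure(data.frame(onset_s = as.numeric(onset_s),
                       duration_s = as.numeric(duration_s)),
            class = c("apnea_events", "data.frame"))
}

#' Convert event-interval annotations to per-minute labels
#'
#' Minute `m` covers the half-open interval `[60m, 60(m+1))` seconds
#' (0-based). A minute is labeled apnea when at least one single event
#' overlaps it for `min_overlap_s` seconds or more — the "5 or more
#' consecutive seconds" rule used when converting continuously annotated
#' recordings (event start + duration) to minute-by-minute labels. Two
#' disjoint shorter events within one minute do not add up: the rule is
#' applied per event.
#'
#' @param events an [apnea_events] data.frame (or any data.frame with
#'   `onset_s`, `duration_s` columns).
#' @param duration_s total recording duration in seconds.
#' @param min_overlap_s minimum single-event overlap (seconds) for a minute
#'   to count as apnea; default 5.
#' @param record_id identifier stored on the result.
#' @return A [minute_labels] object with `floor(duration_s / 60)` labels.
#' @export
#' @examples
#' ev <- apnea_events(onset_s = 62, duration_s = 8)
#' events_to_minute_labels(ev, duration_s = 180)$labels  # "N" "A" "N"
events_to_minute_labels <- function(events, duration_s, min_overlap_s = 5,
                                    record_id = "record") {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_validation("'duration_s' must be positive")
  }
  n_min <- floor(duration_s / 60)
  if (n_min < 1L) stop_validation("recording shorter than one minute")
  if (nrow(events) > 0 &&
      (any(events$onset_s < 0) || any(events$duration_s <= 0))) {
    stop_validation("events must have onset_s >= 0 and duration_s > 0")
  }
  labels <- rep(NORMAL, n_min)
  if (nrow(events) > 0) {
    for (m in seq_len(n_min) - 1L) {
      lo <- 60 * m
      hi <- 60 * (m + 1)
      overlap <- pmin(events$onset_s + events$duration_s, hi) -
        pmax(events$onset_s, lo)
      if (any(overlap >= min_overlap_s)) labels[m + 1L] <- APNEA
    }
  }
  minute_labels(record_id, labels)
}

#' Assign a recording severity class from its per-minute labels
#'
#' Recordings are graded by the apnea-hypopnea index `AHI = 60/T * n`
#' (`T` = number of annotated minutes, `n` = number of apnea minutes) and
#' the absolute apnea-minute count: class A (severe) when `AHI >= 10` and
#' `n >= 100`; class B (borderline) when not A, `AHI >= 5` and `n >= 5`;
#' class C (normal) otherwise (`AHI < 5` for all benchmark-length
#' recordings). The three rules partition every `(T, n)` pair.
#'
#' @param labels a [minute_labels] object.
#' @return A single character, `"A"`, `"B"` or `"C"`, with attribute `ahi`.
#' @export
assign_recording_class <- function(labels) {
  if (!inherits(labels, "minute_labels")) {
    stop_validation("'labels' must be a minute_labels object")
  }
  t_min <- length(labels$labels)
  n <- sum(labels$labels == APNEA)
  ahi <- 60 / t_min * n
  cls <- if (ahi >= 10 && n >= 100) "A" else if (ahi >= 5 && n >= 5) "B" else "C"
  structure(cls, ahi = ahi, n_apnea = n)
}

# ---------------------------------------------------------------------------
# File I/O: plain-text dialect, WFDB header/signal pairs, label/event files.

#' Read a single-lead ECG recording from disk
#'
#' Accepts either a WFDB header+signal pair (`<record>.hea` + `<record>.dat`,
#' signal formats 16 and 212) or the package's plain-text dialect: a small
#' `#`-prefixed header (`record_id`, `fs`) followed by one sample per line.
#' For WFDB input the first channel is returned unless `channel` names
#' another; stored gain and baseline are applied so samples come back in
#' physical units.
#'
#' @param path path to the text file, or to the `.hea` file (with or without
#'   extension) of a WFDB record.
#' @param channel 1-based channel index for multi-channel WFDB records.
#' @return An [ecg_recording].
#' @export
read_recording <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (file.exists(hea)) {
    return(read_wfdb_recording(hea, channel))
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read recording: file '%s' not found", path),
         call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  record_id <- get_field("record_id",
                         default = sub("\\.[^.]*$", "", basename(path)))
  fs <- as.numeric(get_field("fs", default = "100"))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  samples <- as.numeric(body)
  if (length(samples) == 0 || anyNA(samples)) {
    stop(sprintf("cannot read recording: no parseable samples in '%s'", path),
         call. = FALSE)
  }
  ecg_recording(record_id, samples, fs)
}

#' Write a recording in the plain-text dialect
#'
#' @param rec an [ecg_recording].
#' @param path output file path.
#' @param digits significant digits for the samples.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id: %s", rec$record_id),
               sprintf("# fs: %g", rec$fs),
               formatC(rec$samples, digits = digits, format = "g")), con)
  invisible(path)
}

# Minimal WFDB reader: header line "<name> <nsig> <fs> [<nsamp>]", one line
# per signal. Supports the two formats used by the apnea benchmarks (16 =
# int16 little-endian, 212 = packed 12-bit pairs).
read_wfdb_recording <- function(hea_path, channel = 1L) {
  if (!file.exists(hea_path)) {
    stop(sprintf("cannot read recording: header '%s' not found", hea_path),
         call. = FALSE)
  }
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- top[1]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1) {
    stop(sprintf("cannot read recording: '%s' declares zero channels",
                 hea_path), call. = FALSE)
  }
  if (channel > n_sig) {
    stop_validation(sprintf("channel %d requested but record has %d",
                            channel, n_sig))
  }
  sig <- strsplit(trimws(lines[1 + channel]), "\\s+")[[1]]
  dat_path <- file.path(dirname(hea_path), sig[1])
  fmt <- as.integer(sub("x.*$", "", sig[2]))
  gain_field <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_field)))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_field)) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
  } else if (length(sig) >= 5) as.numeric(sig[5]) else 0
  if (is.na(baseline)) baseline <- 0
  if (!file.exists(dat_path)) {
    stop(sprintf("cannot read recording: signal file '%s' not found",
                 dat_path), call. = FALSE)
  }
  raw_n <- file.size(dat_path)
  adc <- if (fmt == 16) {
    vals <- readBin(dat_path, "integer", n = raw_n %/% 2L, size = 2L,
                    endian = "little", signed = TRUE)
    mat <- matrix(vals, nrow = n_sig)
    mat[channel, ]
  } else if (fmt == 212) {
    bytes <- as.integer(readBin(dat_path, "raw", n = raw_n))
    n_pairs <- length(bytes) %/% 3L
    b1 <- bytes[seq(1, by = 3, length.out = n_pairs)]
    b2 <- bytes[seq(2, by = 3, length.out = n_pairs)]
    b3 <- bytes[seq(3, by = 3, length.out = n_pairs)]
    v1 <- bitwAnd(b2, 15L) * 256L + b1
    v2 <- bitwAnd(b2, 240L) * 16L + b3
    v1 <- ifelse(v1 > 2047L, v1 - 4096L, v1)
    v2 <- ifelse(v2 > 2047L, v2 - 4096L, v2)
    all_vals <- as.vector(rbind(v1, v2))
    mat <- matrix(all_vals[seq_len((length(all_vals) %/% n_sig) * n_sig)],
                  nrow = n_sig)
    mat[channel, ]
  } else {
    stop(sprintf("cannot read recording: WFDB format %d not supported", fmt),
         call. = FALSE)
  }
  if (!is.na(n_samp) && n_samp > 0 && n_samp <= length(adc)) {
    adc <- adc[seq_len(n_samp)]
  }
  ecg_recording(record_id, (adc - baseline) / gain, fs)
}

#' Write a recording as a WFDB header+signal pair (format 16)
#'
#' @param rec an [ecg_recording].
#' @param dir output directory.
#' @param gain ADC units per physical unit (default 200/mV).
#' @return The header path, invisibly.
#' @export
write_recording_wfdb <- function(rec, dir, gain = 200) {
  adc <- as.integer(round(rec$samples * gain))
  adc <- pmax(pmin(adc, 32767L), -32768L)
  dat <- paste0(rec$record_id, ".dat")
  hea <- file.path(dir, paste0(rec$record_id, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", rec$record_id, rec$fs, length(adc)),
               sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 ECG", dat, gain,
                       adc[1], sum(adc) %% 65536L)),
             hea)
  writeBin(adc, file.path(dir, dat), size = 2L, endian = "little")
  invisible(hea)
}

#' Read / write per-minute label files
#'
#' Label files store one character per minute (`A`/`N`), one line, matching
#' the per-minute expert annotation convention.
#'
#' @param path file path.
#' @param record_id identifier for the returned object.
#' @return [read_minute_labels()] returns a [minute_labels].
#' @export
read_minute_labels <- function(path, record_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read labels: file '%s' not found", path),
         call. = FALSE)
  }
  txt <- paste(readLines(path), collapse = "")
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  minute_labels(record_id, strsplit(gsub("\\s", "", txt), "")[[1]])
}

#' @rdname read_minute_labels
#' @param labels a [minute_labels] object to write.
#' @export
write_minute_labels <- function(labels, path) {
  writeLines(paste(labels$labels, collapse = ""), path)
  invisible(path)
}

#' Read / write event-interval annotation files
#'
#' Two-column whitespace-separated text: onset seconds, duration seconds.
#'
#' @param path file path.
#' @return [read_apnea_events()] returns an [apnea_events] data.frame.
#' @export
read_apnea_events <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read events: file '%s' not found", path),
         call. = FALSE)
  }
  df <- tryCatch(read.table(path, header = FALSE,
                            col.names = c("onset_s", "duration_s")),
                 error = function(e) data.frame(onset_s = numeric(),
                                                duration_s = numeric()))
  apnea_events(df$onset_s, df$duration_s)
}

#' @rdname read_apnea_events
#' @param events an [apnea_events] data.frame to write.
#' @export
write_apnea_events <- function(events, path) {
  write.table(events[, c("onset_s", "duration_s")], path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
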