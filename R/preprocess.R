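#' Compute RR intervals and R-peak amplitudes from detected peaks
#'
#' Each RR interval is the distance between consecutive R-peaks; the series
#' is anchored at the later peak of each pair (the interval is only known
#' once its second peak occurs), and the amplitude attached to interval `i`
#' is the raw signal value at that later peak.
#'
#' @param peaks an `r_peaks` object with at least two peaks.
#' @return An object of class `rr_series`: data.frame with columns
#'   `times_s`, `rr_s`, `ampl` (length = number of peaks - 1).
#' @export
#' @examples
#' pk <- structure(list(record_id = "x", peak_times_s = c(1, 2, 3.1),
#'                      peak_amplitudes = c(1, 1.1, 0.9)), class = "r_peaks")
#' compute_rr_and_amplitude(pk)$rr_s  # 1.0 1.1
compute_rr_and_amplitude <- function(peaks) {
  t <- peaks$peak_times_s
  if (length(t) < 2) {
    stop_validation("need at least 2 peaks to form RR intervals")
  }
  structure(data.frame(times_s = t[-1],
                       rr_s = diff(t),
                       ampl = peaks$peak_amplitudes[-1]),
            class = c("rr_series", "data.frame"),
            record_id = peaks$record_id)
}

#' Remove physiologically implausible RR intervals with a local median rule
#'
#' An RR value deviating from the median of its centered window by more than
#' `tolerance` times that median is replaced by the median (length is
#' preserved; amplitudes are untouched). This targets spurious or missed
#' detections, which produce intervals far outside the local rhythm. The
#' rule is idempotent on its own output for isolated outliers and leaves
#' series shorter than the window unchanged.
#'
#' @param rr an `rr_series` (or data.frame with `rr_s`).
#' @param window odd window length, >= 3 (default 5).
#' @param tolerance allowed fractional deviation from the local median
#'   (default 0.2).
#' @return The filtered `rr_series`, with attribute `n_corrected`.
#' @export
median_filter_rr <- function(rr, window = 5L, tolerance = 0.2) {
  if (window < 3L || window %% 2L == 0L) {
    stop_validation("'window' must be an odd integer >= 3")
  }
  v <- rr$rr_s
  n <- length(v)
  if (n < window) {
    attr(rr, "n_corrected") <- 0L
    return(rr)
  }
  half <- (window - 1L) %/% 2L
  one_pass <- function(v) {
    out <- v
    for (i in seq_len(n)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      med <- median(v[lo:hi])
      if (is.finite(med) && med > 0 && abs(v[i] - med) > tolerance * med) {
        out[i] <- med
      }
    }
    out
  }
  # iterate to a fixed point so runs of adjacent outliers are fully
  # absorbed and the operation is idempotent
  out <- v
  for (iter in 1:25) {
    nxt <- one_pass(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  rr$rr_s <- out
  attr(rr, "n_corrected") <- sum(out != v)
  rr
}

#' Resample an RR/amplitude series onto a uniform grid by cubic splines
#'
#' Natural cubic-spline interpolation of both channels onto the grid
#' `t_start_s + k / rate_hz`, `k = 0 ... rate_hz * (t_end_s - t_start_s) - 1`.
#' At 3 Hz a 5-minute span yields exactly 900 points per channel. Grid times
#' outside the support range are held at the nearest support value (no
#' extrapolation), which also implements boundary padding for windows
#' clamped at the edges of a recording.
#'
#' @param series an `rr_series` covering (at least part of) the span.
#' @param t_start_s,t_end_s span in seconds, `t_end_s > t_start_s`.
#' @param rate_hz grid rate in Hz (default 3).
#' @param minute_index optional index carried into error messages.
#' @return List with `grid` (times), `rr`, `ampl`, all of length
#'   `rate_hz * (t_end_s - t_start_s)`.
#' @export
interpolate_uniform <- function(series, t_start_s, t_end_s, rate_hz = 3,
                                minute_index = NA) {
  if (t_end_s <= t_start_s) stop_validation("t_end_s must exceed t_start_s")
  tt <- series$times_s
  in_span <- tt >= t_start_s & tt < t_end_s
  if (sum(in_span) < 4) {
    stop_validation(sprintf(
      "cubic interpolation needs >= 4 support points in span%s (found %d)",
      if (is.na(minute_index)) "" else sprintf(" (minute %s)", minute_index),
      sum(in_span)))
  }
  # Include a little context outside the span so the spline is not forced to
  # a natural boundary exactly at the window edge.
  idx <- range(which(in_span))
  lo <- max(1L, idx[1] - 2L)
  hi <- min(length(tt), idx[2] + 2L)
  sel <- lo:hi
  n_out <- round(rate_hz * (t_end_s - t_start_s))
  grid <- t_start_s + (seq_len(n_out) - 1L) / rate_hz
  g <- pmin(pmax(grid, tt[sel][1]), tt[sel][length(sel)])
  f_rr <- splinefun(tt[sel], series$rr_s[sel], method = "natural")
  f_am <- splinefun(tt[sel], series$ampl[sel], method = "natural")
  list(grid = grid, rr = f_rr(g), ampl = f_am(g))
}

#' Assemble the 900x2 input window for one labeled minute
#'
#' The window for minute `m` spans the labeled minute plus its surrounding
#' two minutes on each side — five 1-minute segments, `[60(m-2), 60(m+3))`
#' seconds — resampled to `300 * rate_hz` uniform points per channel
#' (900 at the default 3 Hz). For the first/last two minutes the nominal
#' grid extends beyond the recording; those grid points are held at the
#' nearest boundary support value so every annotated minute still yields a
#' full-size window (required for per-recording AHI coverage).
#'
#' @param rr a (median-filtered) `rr_series` for the whole recording.
#' @param minute_index 0-based minute index.
#' @param total_minutes number of labeled minutes in the recording.
#' @param labels a [minute_labels] for the recording.
#' @param rate_hz grid rate (default 3).
#' @param context segments of context on each side (default 2).
#' @return An object of class `window_tensor`: list with `record_id`,
#'   `minute_index`, `grid`, `rr`, `ampl`, `label`.
#' @export
assemble_window <- function(rr, minute_index, total_minutes, labels,
                            rate_hz = 3, context = 2) {
  if (total_minutes < 2 * context + 1) {
    stop_validation(sprintf("recording shorter than %d minutes",
                            2 * context + 1))
  }
  if (minute_index < 0 || minute_index >= total_minutes) {
    stop_validation("minute_index out of range")
  }
  t0 <- 60 * (minute_index - context)
  t1 <- 60 * (minute_index + context + 1)
  # Clamp the support span to the recording; the nominal grid keeps its full
  # 5-minute extent and out-of-span points are boundary-padded by the
  # interpolator's nearest-value rule.
  span <- t1 - t0
  tt <- rr$times_s
  sub <- rr[tt >= max(0, t0) & tt < min(60 * total_minutes, t1), ,
            drop = FALSE]
  if (nrow(sub) < 4) {
    stop_validation(sprintf("minute %d: too few beats in window",
                            minute_index))
  }
  n_out <- round(rate_hz * span)
  grid <- t0 + (seq_len(n_out) - 1L) / rate_hz
  g <- pmin(pmax(grid, sub$times_s[1]), sub$times_s[nrow(sub)])
  f_rr <- splinefun(sub$times_s, sub$rr_s, method = "natural")
  f_am <- splinefun(sub$times_s, sub$ampl, method = "natural")
  structure(list(record_id = labels$record_id,
                 minute_index = minute_index,
                 grid = grid,
                 rr = f_rr(g),
                 ampl = f_am(g),
                 label = labels$labels[minute_index + 1L]),
            class = "window_tensor")
}

#' @export
print.window_tensor <- function(x, ...) {
  cat(sprintf("<window_tensor> %s minute %d: %d pts/channel, label %s\n",
              x$record_id, x$minute_index, length(x$rr), x$label))
  invisible(x)
}

#' Run the full preprocessing pipeline on one recording
#'
#' R-peak detection, RR/amplitude extraction, median-filter artifact
#' correction, then one context window per labeled minute.
#'
#' @param rec an [ecg_recording].
#' @param labels a [minute_labels]; its length fixes the number of windows
#'   (the recording is truncated to whole minutes).
#' @param rate_hz interpolation grid rate (default 3).
#' @param context context minutes on each side (default 2).
#' @param median_window,median_tolerance artifact-filter settings.
#' @param detector peak-detection function with the [detect_r_peaks]
#'   contract (pluggable).
#' @param verbose print the number of corrected RR outliers.
#' @return A list of `window_tensor` objects (class `window_set`), one per
#'   labeled minute, in minute order; attributes `record_id`,
#'   `n_corrected`.
#' @export
build_dataset <- function(rec, labels, rate_hz = 3, context = 2,
                          median_window = 5L, median_tolerance = 0.2,
                          detector = detect_r_peaks, verbose = FALSE) {
  total_minutes <- length(labels$labels)
  if (floor(rec$duration_s / 60) < total_minutes) {
    stop_validation("recording shorter than its label sequence")
  }
  peaks <- detector(rec)
  if (length(peaks$peak_times_s) < 2) {
    stop_validation(sprintf("record %s: too few R-peaks detected",
                            rec$record_id))
  }
  rr <- compute_rr_and_amplitude(peaks)
  rr <- median_filter_rr(rr, window = median_window,
                         tolerance = median_tolerance)
  n_corr <- attr(rr, "n_corrected")
  if (isTRUE(verbose)) {
    message(sprintf("record %s: corrected %d RR outliers",
                    rec$record_id, n_corr))
  }
  windows <- lapply(seq_len(total_minutes) - 1L, function(m) {
    assemble_window(rr, m, total_minutes, labels,
                    rate_hz = rate_hz, context = context)
  })
  structure(windows, class = "window_set",
            record_id = rec$record_id, n_corrected = n_corr,
            rr_series = rr)
}

#' Stack a list of windows into a (N, L, 2) array plus labels
#'
#' @param windows list of `window_tensor` objects.
#' @return List with `x` (array `N x L x 2`, channels = RR then amplitude)
#'   and `y` (character labels).
#' @export
windows_to_array <- function(windows) {
  n <- length(windows)
  if (n == 0) stop_validation("no windows supplied")
  l <- length(windows[[1]]$rr)
  x <- array(0, dim = c(n, l, 2))
  y <- character(n)
  for (i in seq_len(n)) {
    x[i, , 1] <- windows[[i]]$rr
    x[i, , 2] <- windows[[i]]$ampl
    y[i] <- windows[[i]]$label
  }
  list(x = x, y = y)
}
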