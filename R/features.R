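#' Time-domain HRV features of an RR-interval sequence
#'
#' The six classic beat-to-beat statistics: RMSSD (root mean square of
#' successive differences), SDNN (here: standard deviation of the successive
#' differences — see `sdnn_convention`), NN50 (successive differences
#' exceeding 50 ms), pNN50 (NN50 over the number of intervals), mean RR and
#' mean heart rate (60 / mean RR).
#'
#' @param rr_s numeric vector of RR intervals in seconds (>= 2 values).
#' @param sdnn_convention `"successive-diff"` (default) computes SDNN as the
#'   standard deviation of adjacent-interval differences; `"classic"`
#'   computes the conventional standard deviation of the intervals
#'   themselves. Both are in use in the apnea-screening literature; the
#'   switch keeps the feature table explicit about which is meant.
#' @return Named numeric vector: `rmssd`, `sdnn` (s), `nn50` (count),
#'   `pnn50` (fraction), `mean_rr` (s), `mean_hr` (bpm).
#' @export
#' @examples
#' time_domain_features(c(0.8, 1.0))
time_domain_features <- function(rr_s,
                                 sdnn_convention = c("successive-diff",
                                                     "classic")) {
  sdnn_convention <- match.arg(sdnn_convention)
  if (length(rr_s) < 2) {
    stop_validation("need at least 2 RR intervals for time-domain features")
  }
  d <- diff(rr_s)
  sdnn <- if (sdnn_convention == "successive-diff") {
    if (length(d) > 1) sd(d) else 0
  } else {
    sd(rr_s)
  }
  c(rmssd = sqrt(mean(d^2)),
    sdnn = sdnn,
    nn50 = sum(abs(d) > 0.050),
    pnn50 = sum(abs(d) > 0.050) / length(rr_s),
    mean_rr = mean(rr_s),
    mean_hr = 60 / mean(rr_s))
}

#' Welch power spectral density of a uniformly sampled series
#'
#' Mean-detrended, Hamming-windowed, 50%-overlapping segments, averaged
#' one-sided periodograms (density scaling, power per Hz).
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param segment segment length (default 256; shortened to `length(x)` for
#'   shorter series).
#' @param overlap fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, segment = 256L, overlap = 0.5) {
  n <- length(x)
  seg <- min(as.integer(segment), n)
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg) - 1L) / (seg - 1L))
  scale <- fs * sum(w^2)
  n_freq <- seg %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    xd <- x[s:(s + seg - 1L)]
    xd <- (xd - mean(xd)) * w
    p <- Mod(fft(xd))^2 / scale
    p <- p[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist when seg is even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (seg %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(n_freq) - 1L) * fs / seg,
       psd = acc / length(starts))
}

#' Frequency-domain HRV features of a uniformly resampled channel
#'
#' Band powers integrated from a Welch PSD over the standard short-term HRV
#' bands — VLF `[0.003, 0.04)`, LF `[0.04, 0.15)`, HF `[0.15, 0.4)` Hz —
#' each normalized by the total (VLF+LF+HF) power, plus the LF/HF ratio and
#' the LF and HF fractions of (LF+HF). A constant (zero-power) input returns
#' all zeros with a warning.
#'
#' @param x uniformly sampled channel (RR or amplitude), length >= 64.
#' @param rate_hz sampling rate of the channel (default 3).
#' @param bands named list of band edges in Hz.
#' @param segment Welch segment length.
#' @return Named numeric vector: `vlf_norm`, `lf_norm`, `hf_norm`,
#'   `lf_hf_ratio`, `lf_frac`, `hf_frac`.
#' @export
spectral_features <- function(x, rate_hz = 3,
                              bands = list(vlf = c(0.003, 0.04),
                                           lf = c(0.04, 0.15),
                                           hf = c(0.15, 0.4)),
                              segment = 256L) {
  if (length(x) < 64) {
    stop_validation("need >= 64 samples for spectral features")
  }
  sp <- welch_psd(x - mean(x), fs = rate_hz, segment = segment)
  band_power <- function(edges) {
    sel <- sp$freq >= edges[1] & sp$freq < edges[2]
    df <- sp$freq[2] - sp$freq[1]
    sum(sp$psd[sel]) * df
  }
  vlf <- band_power(bands$vlf)
  lf <- band_power(bands$lf)
  hf <- band_power(bands$hf)
  total <- vlf + lf + hf
  if (!is.finite(total) || total <= .Machine$double.eps) {
    warning("zero total band power (constant input); returning zeros")
    return(c(vlf_norm = 0, lf_norm = 0, hf_norm = 0,
             lf_hf_ratio = 0, lf_frac = 0, hf_frac = 0))
  }
  c(vlf_norm = vlf / total,
    lf_norm = lf / total,
    hf_norm = hf / total,
    lf_hf_ratio = if (hf > 0) lf / hf else 0,
    lf_frac = if (lf + hf > 0) lf / (lf + hf) else 0,
    hf_frac = if (lf + hf > 0) hf / (lf + hf) else 0)
}

FEATURE_NAMES <- c(
  "rmssd", "sdnn", "nn50", "pnn50", "mean_rr", "mean_hr",
  "rr_vlf_norm", "rr_lf_norm", "rr_hf_norm", "rr_lf_hf_ratio",
  "rr_lf_frac", "rr_hf_frac",
  "ampl_vlf_norm", "ampl_lf_norm", "ampl_hf_norm", "ampl_lf_hf_ratio",
  "ampl_lf_frac", "ampl_hf_frac")

#' Extract the 18-value HRV feature vector for one window
#'
#' Twelve RR-derived features (six time-domain from the beat-to-beat
#' intervals in the window span, six frequency-domain from the interpolated
#' RR channel) plus six amplitude-derived frequency-domain features, in a
#' fixed column order. These hand-crafted features feed the comparison
#' classifiers; the CNN consumes the raw window channels instead.
#'
#' @param window a `window_tensor`.
#' @param rr_raw the (filtered) `rr_series` of the recording; beat-to-beat
#'   intervals falling inside the window span are used for the time-domain
#'   block. If `NULL`, intervals are taken from the interpolated RR channel.
#' @param sdnn_convention see [time_domain_features()].
#' @return Named numeric vector of length 18 (order of `FEATURE_NAMES`).
#' @export
extract_feature_vector <- function(window, rr_raw = NULL,
                                   sdnn_convention = "successive-diff") {
  span <- range(window$grid)
  rr_vals <- if (!is.null(rr_raw)) {
    sel <- rr_raw$times_s >= span[1] & rr_raw$times_s <= span[2] + 1 / 3
    rr_raw$rr_s[sel]
  } else {
    window$rr
  }
  if (length(rr_vals) < 2) rr_vals <- window$rr
  td <- time_domain_features(rr_vals, sdnn_convention = sdnn_convention)
  sp_rr <- suppressWarnings(spectral_features(window$rr))
  sp_am <- suppressWarnings(spectral_features(window$ampl))
  out <- c(td, sp_rr, sp_am)
  names(out) <- FEATURE_NAMES
  out
}

#' Build a labeled feature table for a set of windows
#'
#' @param windows a `window_set` (or list of `window_tensor`s).
#' @param rr_raw optional `rr_series` for the recording (taken from the
#'   `window_set` attribute when present).
#' @param sdnn_convention see [time_domain_features()].
#' @return data.frame with `record_id`, `minute_index`, `label` and the 18
#'   feature columns.
#' @export
extract_feature_matrix <- function(windows, rr_raw = NULL,
                                   sdnn_convention = "successive-diff") {
  if (is.null(rr_raw)) rr_raw <- attr(windows, "rr_series")
  rows <- lapply(windows, function(w) {
    fv <- extract_feature_vector(w, rr_raw, sdnn_convention)
    cbind(data.frame(record_id = w$record_id,
                     minute_index = w$minute_index,
                     label = w$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Min-max feature normalization (fit on train, apply to both)
#'
#' Standard rescaling `x* = (x - x_min) / (x_max - x_min)` with the per-column
#' minimum and maximum taken from the training rows only; training values
#' map into `[0, 1]`, test values outside the training range are allowed to
#' leave it (no clipping). Zero-range columns map to 0.
#'
#' @param train numeric matrix/data.frame of training feature rows.
#' @param test optional matrix/data.frame to transform with the training
#'   scaling.
#' @return List with `train`, `test` (or `NULL`) and the `scaling`
#'   (`min`, `max` per column).
#' @export
#' @examples
#' minmax_fit_transform(matrix(c(1, 2, 3), ncol = 1))$train
minmax_fit_transform <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0) stop_validation("'train' must be non-empty")
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  rng <- maxs - mins
  tf <- function(m) {
    m <- as.matrix(m)
    out <- sweep(m, 2, mins, "-")
    safe <- ifelse(rng > 0, rng, 1)
    out <- sweep(out, 2, safe, "/")
    out[, rng == 0] <- 0
    out
  }
  list(train = tf(train),
       test = if (is.null(test)) NULL else tf(test),
       scaling = list(min = mins, max = maxs))
}
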