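# Shared fixtures and independent oracles, all built in code.

make_peaks <- function(times, amps = rep(1, length(times)),
                       record_id = "fix") {
  structure(list(record_id = record_id,
                 peak_times_s = times,
                 peak_amplitudes = amps),
            class = "r_peaks")
}

make_rr <- function(times, rr, ampl = rep(1, length(rr))) {
  structure(data.frame(times_s = times, rr_s = rr, ampl = ampl),
            class = c("rr_series", "data.frame"), record_id = "fix")
}

# Separable-by-construction window fixture: apnea windows carry a slow
# sinusoid on the RR channel, normal windows are noise only.
separable_windows <- function(n = 200, seed = 99, amp = 0.3) {
  set.seed(seed)
  x <- array(rnorm(n * 900 * 2, 0, 0.1), dim = c(n, 900, 2))
  y <- rep(c("A", "N"), each = n / 2)
  tgrid <- (0:899) / 3
  for (i in seq_len(n / 2)) {
    x[i, , 1] <- x[i, , 1] +
      amp * sin(2 * pi * tgrid / 45 + runif(1, 0, 2 * pi))
  }
  list(x = x, y = y)
}

# Brute-force AUC oracle: fraction of (apnea, normal) pairs where the apnea
# window outscores the normal one, ties counted one half.
pairwise_auc <- function(y, scores) {
  pos <- scores[y == "A"]
  neg <- scores[y == "N"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force valid-placement count for a 1-D kernel.
count_placements <- function(l_in, kernel, stride) {
  sum(sapply(seq(1, l_in, by = stride), function(i) i + kernel - 1 <= l_in))
}

# Direct (single-window) periodogram band power, an independent estimator to
# cross-check Welch band fractions.
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / (n * fs)
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq <= fs / 2
  sel <- freq >= lo & freq < hi & keep
  2 * sum(p[sel]) * fs / n
}

# One small preprocessed recording, cached per test session.
cached_small_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_recording(
        sim_config(duration_min = 10, apnea_minute_fraction = 0.5, seed = 3))
      cache <<- list(sim = sim,
                     windows = build_dataset(sim$recording, sim$labels))
    }
    cache
  }
})
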