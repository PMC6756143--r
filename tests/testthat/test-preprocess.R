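test_that("R-peak detection recovers simulated beats across heart rates", {
  for (hr in c(40, 60, 90, 120)) {
    cfg <- sim_config(duration_min = 5, base_hr = hr, hr_jitter_sd = 0,
                      apnea_minute_fraction = 0, noise_sd = 0, seed = 7)
    sim <- simulate_recording(cfg)
    pk <- detect_r_peaks(sim$recording)
    expect_lte(abs(length(pk$peak_times_s) - length(sim$beat_times_s)), 1)
    expect_true(all(diff(pk$peak_times_s) > 0))
  }
  # 60 bpm for 60 s gives ~60 peaks at ~1 s spacing
  sim60 <- simulate_recording(sim_config(duration_min = 5, base_hr = 60,
                                         hr_jitter_sd = 0, noise_sd = 0,
                                         apnea_minute_fraction = 0, seed = 1))
  pk60 <- detect_r_peaks(sim60$recording)
  expect_equal(length(pk60$peak_times_s), length(sim60$beat_times_s),
               tolerance = 1e-8)
  expect_true(all(abs(diff(pk60$peak_times_s) - 1) < 0.05))
})

test_that("degenerate signals yield an empty peak series or validation error", {
  z <- ecg_recording("z", numeric(6000), 100)
  expect_length(detect_r_peaks(z)$peak_times_s, 0)
  short <- ecg_recording("s", numeric(150), 100)
  expect_error(detect_r_peaks(short), "warm-up")
  lowfs <- ecg_recording("l", numeric(500), 25)
  expect_error(detect_r_peaks(lowfs), "50 Hz")
})

test_that("RR intervals and amplitudes follow the later-peak convention", {
  pk <- make_peaks(c(1.0, 2.0, 3.1), amps = c(0.9, 1.0, 1.1))
  rr <- compute_rr_and_amplitude(pk)
  expect_equal(rr$rr_s, c(1.0, 1.1))
  expect_equal(rr$times_s, c(2.0, 3.1))
  expect_equal(rr$ampl, c(1.0, 1.1))
  # minimal case: two peaks, one interval
  expect_equal(nrow(compute_rr_and_amplitude(make_peaks(c(0, 0.8)))), 1)
  expect_error(compute_rr_and_amplitude(make_peaks(1.0)), "2 peaks")
})

test_that("the median filter replaces only implausible intervals and is idempotent", {
  rr <- make_rr(1:5, c(0.8, 0.8, 3.0, 0.8, 0.8))
  out <- median_filter_rr(rr)
  expect_equal(out$rr_s, rep(0.8, 5))
  expect_equal(attr(out, "n_corrected"), 1L)
  # constant series untouched
  rrc <- make_rr(1:6, rep(0.9, 6))
  expect_equal(median_filter_rr(rrc)$rr_s, rep(0.9, 6))
  # small physiological variation untouched
  rrv <- make_rr(1:5, c(0.8, 0.82, 0.81, 0.79, 0.8))
  expect_equal(median_filter_rr(rrv)$rr_s, c(0.8, 0.82, 0.81, 0.79, 0.8))
  # idempotence on randomized spiky series
  set.seed(5)
  for (i in 1:10) {
    v <- 0.8 + rnorm(40, 0, 0.03)
    v[sample(40, 3)] <- c(2.5, 0.2, 1.9)
    r1 <- median_filter_rr(make_rr(seq_along(v), v))
    r2 <- median_filter_rr(r1)
    expect_equal(r2$rr_s, r1$rr_s)
  }
  # amplitudes never touched; short series returned unchanged
  expect_equal(out$ampl, rr$ampl)
  shrt <- make_rr(1:3, c(0.5, 3, 0.5))
  expect_equal(median_filter_rr(shrt)$rr_s, c(0.5, 3, 0.5))
  expect_error(median_filter_rr(rr, window = 4), "odd")
})

test_that("uniform-grid interpolation has exact length and reproduces low-order signals", {
  tt <- seq(0, 310, by = 0.8)
  # constants are reproduced exactly
  rrc <- make_rr(tt, rep(0.75, length(tt)), rep(1.2, length(tt)))
  g <- interpolate_uniform(rrc, 0, 300, rate_hz = 3)
  expect_length(g$rr, 900)
  expect_length(g$ampl, 900)
  expect_equal(g$rr, rep(0.75, 900))
  expect_equal(g$ampl, rep(1.2, 900))
  # a linear ramp is reproduced to near machine precision inside the support
  rrl <- make_rr(tt, 0.5 + 0.001 * tt)
  gl <- interpolate_uniform(rrl, 0, 300, rate_hz = 3)
  inside <- gl$grid >= min(tt) & gl$grid <= max(tt)
  expect_equal(gl$rr[inside], 0.5 + 0.001 * gl$grid[inside],
               tolerance = 1e-9)
  # output length is rate * span for assorted spans
  for (span in c(30, 60, 150, 300)) {
    gs <- interpolate_uniform(rrc, 10, 10 + span, rate_hz = 3)
    expect_length(gs$rr, 3 * span)
  }
  # too few support points in span is an error carrying the minute index
  sparse <- make_rr(c(1, 2, 3), rep(0.8, 3))
  expect_error(interpolate_uniform(sparse, 0, 60, minute_index = 4),
               "minute 4")
})

test_that("windows span the labeled minute plus context and clamp at the edges", {
  prep <- cached_small_prep()
  ws <- prep$windows
  rr <- attr(ws, "rr_series")
  labels <- prep$sim$labels
  w10 <- ws[[6]]  # interior minute 5: nominal span [180, 480)
  expect_equal(w10$grid[1], 180)
  expect_equal(w10$grid[900] + 1 / 3, 480)
  expect_length(w10$rr, 900)
  # edge minute 0: nominal grid starts at -120 s, values clamped to the
  # first support value
  w0 <- ws[[1]]
  expect_length(w0$rr, 900)
  expect_equal(w0$grid[1], -120)
  first_support <- rr$rr_s[1]
  expect_equal(w0$rr[1], first_support)
  # labels propagate
  for (i in c(1, 4, 9)) {
    expect_identical(ws[[i]]$label, labels$labels[i])
  }
  expect_error(assemble_window(rr, 99, 10, labels), "out of range")
  expect_error(assemble_window(rr, 0, 3, labels), "shorter")
})

test_that("build_dataset yields one 900x2 window per labeled minute, deterministically", {
  prep <- cached_small_prep()
  ws <- prep$windows
  labels <- prep$sim$labels
  expect_length(ws, 10)
  expect_true(all(vapply(ws, function(w) length(w$rr) == 900, logical(1))))
  expect_true(all(vapply(ws, function(w) length(w$ampl) == 900, logical(1))))
  # apnea fraction of windows equals apnea fraction of labels
  expect_equal(mean(vapply(ws, function(w) w$label, character(1)) == "A"),
               mean(labels$labels == "A"))
  # pipeline determinism: identical input gives bit-identical tensors
  ws2 <- build_dataset(prep$sim$recording, labels)
  expect_identical(lapply(ws, function(w) w$rr),
                   lapply(ws2, function(w) w$rr))
  expect_identical(lapply(ws, function(w) w$ampl),
                   lapply(ws2, function(w) w$ampl))
})
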