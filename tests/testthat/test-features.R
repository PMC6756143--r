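test_that("time-domain HRV statistics match hand computation", {
  f <- time_domain_features(c(1.0, 1.0, 1.0))
  expect_equal(unname(f[c("rmssd", "sdnn", "nn50", "pnn50")]),
               c(0, 0, 0, 0))
  expect_equal(unname(f["mean_rr"]), 1.0)
  expect_equal(unname(f["mean_hr"]), 60)

  f2 <- time_domain_features(c(0.8, 1.0))
  expect_equal(unname(f2["rmssd"]), 0.2)
  expect_equal(unname(f2["nn50"]), 1)
  expect_equal(unname(f2["pnn50"]), 0.5)
  expect_equal(unname(f2["mean_rr"]), 0.9)
  expect_equal(unname(f2["mean_hr"]), 60 / 0.9)

  # 40 ms difference does not exceed the 50 ms threshold
  expect_equal(unname(time_domain_features(c(1.0, 1.04))["nn50"]), 0)
  # convention switch: sd of differences (default) vs sd of intervals
  rr <- c(0.8, 0.9, 1.1, 0.7)
  expect_equal(unname(time_domain_features(rr)["sdnn"]), sd(diff(rr)))
  expect_equal(unname(time_domain_features(rr, "classic")["sdnn"]), sd(rr))
  expect_error(time_domain_features(0.8), "2 RR")
})

test_that("time-domain statistics are reversal-invariant", {
  set.seed(11)
  for (i in 1:10) {
    rr <- 0.8 + rnorm(50, 0, 0.05)
    a <- time_domain_features(rr)
    b <- time_domain_features(rev(rr))
    expect_equal(a[c("rmssd", "sdnn", "nn50", "pnn50", "mean_rr", "mean_hr")],
                 b[c("rmssd", "sdnn", "nn50", "pnn50", "mean_rr", "mean_hr")])
  }
})

test_that("spectral features localize pure tones in the right HRV band", {
  tgrid <- (0:899) / 3
  lf_tone <- sin(2 * pi * 0.1 * tgrid)
  sp <- spectral_features(lf_tone)
  expect_gt(sp["lf_frac"], 0.95)
  expect_lt(sp["hf_frac"], 0.05)
  expect_gt(sp["lf_norm"], sp["hf_norm"])

  hf_tone <- sin(2 * pi * 0.25 * tgrid)
  sp2 <- spectral_features(hf_tone)
  expect_gt(sp2["hf_frac"], 0.95)

  vlf_tone <- sin(2 * pi * 0.02 * tgrid)
  sp3 <- spectral_features(vlf_tone)
  expect_gt(sp3["vlf_norm"], 0.8)

  # constant input is degenerate: all zeros with a warning
  expect_warning(sp0 <- spectral_features(rep(1, 900)), "zero total")
  expect_equal(unname(sp0), rep(0, 6))
  expect_error(spectral_features(1:10), "64")
})

test_that("lf and hf fractions sum to one and are amplitude-scale invariant", {
  set.seed(21)
  tgrid <- (0:899) / 3
  for (i in 1:8) {
    x <- sin(2 * pi * runif(1, 0.02, 0.35) * tgrid) + rnorm(900, 0, 0.3)
    sp <- spectral_features(x)
    expect_equal(unname(sp["lf_frac"] + sp["hf_frac"]), 1)
    sp_scaled <- spectral_features(5 * x)
    expect_equal(unname(sp), unname(sp_scaled), tolerance = 1e-10)
  }
})

test_that("Welch band powers agree with direct periodogram integration for tones", {
  tgrid <- (0:899) / 3
  for (f0 in c(0.08, 0.1, 0.2, 0.3)) {
    x <- sin(2 * pi * f0 * tgrid)
    sp <- welch_psd(x, fs = 3, segment = 256)
    df <- sp$freq[2] - sp$freq[1]
    lo <- f0 - 0.02
    hi <- f0 + 0.02
    welch_p <- sum(sp$psd[sp$freq >= lo & sp$freq < hi]) * df
    direct_p <- periodogram_band_power(x, 3, lo, hi)
    expect_equal(welch_p, direct_p, tolerance = 0.2 * direct_p)
    # a unit sinusoid carries power 1/2
    expect_equal(welch_p, 0.5, tolerance = 0.1)
  }
})

test_that("the window feature vector has 18 values in fixed order and discriminates apnea", {
  prep <- cached_small_prep()
  ws <- prep$windows
  rr <- attr(ws, "rr_series")
  fv <- extract_feature_vector(ws[[2]], rr)
  expect_length(fv, 18)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv)[1:6],
                   c("rmssd", "sdnn", "nn50", "pnn50", "mean_rr", "mean_hr"))
  # determinism
  expect_identical(fv, extract_feature_vector(ws[[2]], rr))
  # cyclic heart-rate modulation in apnea minutes raises VLF power of RR
  fm <- extract_feature_matrix(ws)
  expect_equal(nrow(fm), 10)
  vlf_a <- mean(fm$rr_vlf_norm[fm$label == "A"])
  vlf_n <- mean(fm$rr_vlf_norm[fm$label == "N"])
  expect_gt(vlf_a, vlf_n)
})

test_that("min-max normalization maps training columns to [0,1] without clipping tests", {
  out <- minmax_fit_transform(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(out$train), c(0, 0.5, 1))
  # zero-range columns map to 0
  out2 <- minmax_fit_transform(matrix(c(4, 4), ncol = 1))
  expect_equal(as.numeric(out2$train), c(0, 0))
  # scaling is fit on train only; test values may leave [0,1]
  out3 <- minmax_fit_transform(matrix(c(1, 2, 3), ncol = 1),
                               matrix(c(0, 5), ncol = 1))
  expect_equal(as.numeric(out3$test), c(-0.5, 2))
  # every normalized training entry lies in [0,1] for random matrices
  set.seed(31)
  m <- matrix(rnorm(60), 12, 5)
  tr <- minmax_fit_transform(m)$train
  expect_true(all(tr >= 0 & tr <= 1))
  expect_error(minmax_fit_transform(matrix(numeric(0), 0, 3)), "non-empty")
})
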