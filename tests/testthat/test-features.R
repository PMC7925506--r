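make_psd <- function(peak_freq, source) {
  structure(list(freqs = c(0, peak_freq), power_db = c(-100, 0),
                 peak_freq = peak_freq, peak_power_db = 0, source = source),
            class = "psd_estimate")
}

test_that("the expected step window averages the two spectral estimates", {
  expect_equal(expected_step_window(make_psd(2, "accel"), make_psd(1, "gyro")),
               0.5)
  expect_equal(expected_step_window(make_psd(2, "accel"), make_psd(0.8, "gyro")),
               0.5625)
  bad <- make_psd(0, "gyro")
  expect_error(expected_step_window(make_psd(2, "accel"), bad), "peak")
})

test_that("step window on a noise-free trial recovers half the stride period", {
  p <- gait_params("healthy", noise_sigma = 0, stride_jitter_sd = 0,
                   duration = 20, sample_rate = 200)
  tr <- generate_trial(p, seed = 1)
  a <- periodogram_psd(signal_magnitude(tr, "accel"))
  g <- periodogram_psd(signal_magnitude(tr, "gyro"))
  expect_lt(abs(expected_step_window(a, g) - 0.55), 0.02)
})

test_that("valleys of a cosine train land on the analytic minima", {
  fs <- 12.5
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  sig <- processed_signal(-cos(2 * pi * t / 1.2), fs, "filtered", "accel")
  V <- detect_valleys(sig, window = 0.6)
  truth <- seq(0, 10.8, by = 1.2)
  expect_gte(length(V), 8)
  for (v in V) {
    expect_lte(min(abs(v - truth)), 1 / fs + 1e-9)
  }
  expect_true(all(diff(V) > 0))
})

test_that("iterative valley search equals the brute-force interval oracle", {
  set.seed(33)
  fs <- 10
  x <- rnorm(50)
  t <- (0:49) / fs
  sig <- processed_signal(x, fs, "filtered", "accel")
  window <- 0.5
  frac <- 0.3
  V <- detect_valleys(sig, window, search_frac = frac)

  # oracle: replay the stated rule with explicit interval enumeration
  sw <- 2 * window
  span <- t <= 1.5 * window
  v_or <- t[span][which.min(x[span])]
  oracle <- v_or
  repeat {
    lo <- v_or + sw - frac * sw
    hi <- v_or + sw + frac * sw
    if (hi > t[length(t)]) break
    idx <- which(t >= lo & t <= hi)
    v_or <- t[idx][which.min(x[idx])]
    oracle <- c(oracle, v_or)
  }
  expect_equal(V, oracle, tolerance = 1e-12)
})

test_that("detected valleys match generator truth on a jitter-free trial", {
  p <- gait_params("healthy", stride_jitter_sd = 0, duration = 20,
                   sample_rate = 200)
  tr <- generate_trial(p, seed = 5)
  f <- extract_features(tr)
  m <- signal_magnitude(tr, "accel")
  filt <- mallat_lowpass(wavelet_denoise(resample_to_common(m)), 4)
  V <- detect_valleys(filt, 0.55)
  truth <- tr$truth$valley_times
  expect_lte(abs(length(V) - length(truth)), 1)
  sw <- 1.1
  for (v in V) {
    expect_lte(min(abs(v - truth)), sw / 4)
  }
})

test_that("valley detection demands a filtered signal and enough strides", {
  sig <- sine_signal(1, 12.5, 10, stage = "denoised")
  expect_error(detect_valleys(sig, 0.5), "filtered")
  flat <- processed_signal(rep(0, 25), 12.5, "filtered", "accel")
  expect_error(detect_valleys(flat, 2), "insufficient strides")
  expect_error(detect_valleys(flat, 0.1), "window")
})

test_that("cycle durations are the successive valley differences", {
  expect_equal(cycle_durations(c(0.5, 1.6, 2.6)), c(1.1, 1.0))
  expect_equal(cycle_durations(c(0, 1, 2, 3)), c(1, 1, 1))
  set.seed(2)
  V <- cumsum(runif(10, 0.5, 1.5))
  expect_equal(sum(cycle_durations(V)), V[10] - V[1], tolerance = 1e-12)
  expect_error(cycle_durations(1), "2 valleys")
  expect_error(cycle_durations(c(1, 1)), "increasing")
})

test_that("cycle regularity is the sample standard deviation", {
  expect_equal(cycle_regularity(c(1, 1, 1)), 0)
  expect_equal(cycle_regularity(c(1.0, 1.2)), 0.2 / sqrt(2), tolerance = 1e-12)
  set.seed(3)
  cd <- runif(15, 0.8, 1.6)
  # independent two-pass computation
  two_pass <- sqrt(sum((cd - mean(cd))^2) / (length(cd) - 1))
  expect_equal(cycle_regularity(cd), two_pass, tolerance = 1e-12)
  expect_error(cycle_regularity(1), "2 stride")
})

test_that("cadence projects strides per minute", {
  expect_equal(cadence(c(0, 1, 2, 3)), 60)
  expect_equal(cadence(c(2.0, 3.1)), 60 / 1.1, tolerance = 1e-12)
  expect_error(cadence(1), "2 valleys")
})

test_that("cadence equals 60 over the mean stride duration", {
  set.seed(4)
  V <- cumsum(runif(12, 0.6, 1.8))
  expect_equal(cadence(V), 60 / mean(cycle_durations(V)), tolerance = 1e-12)
})

test_that("the feature vector has exactly five features and is deterministic", {
  tr <- generate_trial(gait_params("healthy", duration = 20), seed = 12)
  f1 <- extract_features(tr)
  expect_equal(feature_columns(),
               setdiff(names(f1), "label"))
  expect_length(feature_columns(), 5)
  expect_identical(f1, extract_features(tr))
  expect_gt(f1$mean_cycle_duration_s, 0)
  expect_gte(f1$cycle_regularity_s, 0)
  expect_gt(f1$cadence_cpm, 0)
})

test_that("per-class feature means recover the class stride periods", {
  cohort <- small_cohort(n_h = 6, n_p = 6, seed = 20)
  feats <- cohort_features(cohort)
  truth <- vapply(cohort, function(tr) tr$truth$params$stride_period, 0)
  cls <- vapply(cohort, `[[`, "", "label")
  for (lab in c("healthy", "pathological")) {
    est <- mean(feats$mean_cycle_duration_s[feats$label == lab])
    expect_lt(abs(est - mean(truth[cls == lab])) / mean(truth[cls == lab]),
              0.10)
  }
})

test_that("stage failures are reported with the failing stage named", {
  tr <- generate_trial(gait_params("healthy"), seed = 1)
  tr$accel <- NULL
  expect_error(extract_features(tr), "stage 'magnitude'")
  tr2 <- generate_trial(gait_params("healthy"), seed = 1)
  tr2$accel <- tr2$accel[1:100, ]
  tr2$gyro <- tr2$gyro[1:100, ]
  tr2$time <- tr2$time[1:100]
  expect_error(extract_features(tr2), "stage 'denoise'.*128")
})

test_that("normalized columns attain 0 and 1 and the map inverts exactly", {
  expect_equal(normalize_features(cbind(c(2, 4, 6)))$X[, 1], c(0, 0.5, 1))
  set.seed(7)
  X <- matrix(rnorm(100, 50, 20), 20, 5)
  nf <- normalize_features(X)
  expect_equal(unname(apply(nf$X, 2, min)), rep(0, 5))
  expect_equal(unname(apply(nf$X, 2, max)), rep(1, 5))
  # idempotence
  nf2 <- normalize_features(nf$X)
  expect_equal(nf2$X, nf$X, tolerance = 1e-12)
  # exact inversion
  expect_equal(invert_normalization(nf, nf$X), X, tolerance = 1e-12)
  # unseen data reuse the stored parameters
  Xnew <- matrix(rnorm(25, 50, 20), 5, 5)
  expect_equal(invert_normalization(nf, apply_normalization(nf, Xnew)), Xnew,
               tolerance = 1e-12)
})

test_that("constant feature columns normalize to 0 with a warning", {
  X <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  expect_warning(nf <- normalize_features(X), "constant")
  expect_true(all(nf$X[, "b"] == 0))
  expect_equal(suppressWarnings(invert_normalization(nf, nf$X))[, "b"],
               c(4, 4, 4))
})
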