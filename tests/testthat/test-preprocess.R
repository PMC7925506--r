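test_that("magnitude is the per-sample Euclidean norm", {
  tr <- generate_trial(gait_params("healthy"), seed = 1)
  tr$accel <- matrix(rep(c(3, 4, 0), each = length(tr$time)), ncol = 3,
                     dimnames = list(NULL, c("ax", "ay", "az")))
  m <- signal_magnitude(tr, "accel")
  expect_true(all(abs(m$samples - 5) < 1e-12))
  tr$accel[, 2:3] <- 0
  tr$accel[, 1] <- -2.5
  expect_true(all(abs(signal_magnitude(tr, "accel")$samples - 2.5) < 1e-12))
  tr$accel <- NULL
  expect_error(signal_magnitude(tr, "accel"), "channels")
})

test_that("noise-free magnitude recovers the generator's clean signal", {
  tr <- generate_trial(gait_params("healthy", noise_sigma = 0), seed = 2)
  expect_equal(signal_magnitude(tr, "accel")$samples,
               tr$truth$clean_accel_mag, tolerance = 1e-12)
  expect_equal(signal_magnitude(tr, "gyro")$samples,
               tr$truth$clean_gyro_mag, tolerance = 1e-12)
})

test_that("resampling preserves a band-limited tone at any pool rate", {
  for (fs in c(50, 128, 256, 350)) {
    t_in <- seq(0, 10 - 1 / fs, by = 1 / fs)
    sig <- processed_signal(sin(2 * pi * 2 * t_in), fs, "magnitude", "accel")
    out <- resample_to_common(sig, 200)
    expect_equal(out$sample_rate, 200)
    expect_equal(out$stage, "resampled")
    # duration preserved within one output sample
    expect_lte(abs(length(out$samples) / 200 - 10), 1 / 200 + 1e-9)
    ref <- sin(2 * pi * 2 * (seq_along(out$samples) - 1) / 200)
    rms <- sqrt(mean((out$samples - ref)^2))
    expect_lt(rms, 0.01)
  }
})

test_that("resampling an already-common-rate signal is the identity", {
  sig <- sine_signal(2, 200, 10, stage = "magnitude")
  out <- resample_to_common(sig, 200)
  expect_identical(out$samples, sig$samples)
  expect_equal(out$stage, "resampled")
  expect_error(resample_to_common(out, 200), "magnitude")
})

test_that("very short inputs are rejected before the anti-aliasing filter", {
  sig <- processed_signal(rnorm(16), 50, "magnitude", "accel")
  expect_error(resample_to_common(sig, 200), "32")
})

test_that("denoising is the identity on zero and rejects short inputs", {
  z <- processed_signal(numeric(256), 200, "resampled", "accel")
  expect_true(all(wavelet_denoise(z)$samples == 0))
  short <- processed_signal(rnorm(100), 200, "resampled", "accel")
  expect_error(wavelet_denoise(short), "128")
  expect_error(wavelet_denoise(z, levels = 0), "levels")
})

test_that("universal-threshold shrinkage suppresses white noise", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(4096)
    den <- wavelet_denoise(processed_signal(x, 200, "resampled", "accel"))
    var(den$samples) / var(x)
  }, numeric(1))
  expect_lt(mean(ratios), 0.15)
})

test_that("denoising strictly improves SNR on a noisy gait magnitude", {
  p <- gait_params("healthy", noise_sigma = 0.5, duration = 20,
                   sample_rate = 200)
  tr <- generate_trial(p, seed = 6)
  clean <- tr$truth$clean_accel_mag
  noisy <- signal_magnitude(tr, "accel")$samples
  den <- wavelet_denoise(processed_signal(noisy, 200, "resampled", "accel"))
  rms_in <- sqrt(mean((noisy - clean)^2))
  rms_out <- sqrt(mean((den$samples - clean)^2))
  expect_lt(rms_out, rms_in)
})

test_that("denoising is scale-equivariant on noise-free structure", {
  tr <- generate_trial(gait_params("healthy", noise_sigma = 0), seed = 3)
  x <- tr$truth$clean_accel_mag
  d1 <- wavelet_denoise(processed_signal(x, 200, "resampled", "accel"))$samples
  d5 <- wavelet_denoise(processed_signal(5 * x, 200, "resampled", "accel"))$samples
  expect_equal(d5, 5 * d1, tolerance = 1e-6)
})

test_that("the filter bank halves the rate per level and preserves constants", {
  const <- processed_signal(rep(3.7, 400), 200, "denoised", "accel")
  out <- mallat_lowpass(const, levels = 4)
  expect_equal(out$sample_rate, 12.5)
  expect_equal(out$stage, "filtered")
  expect_true(all(abs(out$samples - 3.7) < 1e-9))
  for (lv in 1:3) {
    expect_equal(mallat_lowpass(const, levels = lv)$sample_rate, 200 / 2^lv)
  }
  expect_error(mallat_lowpass(processed_signal(1:10, 200, "resampled", "accel")),
               "denoised")
})

test_that("the filter bank attenuates a 50 Hz tone by at least 20 dB vs 1 Hz", {
  t <- seq(0, 20 - 1 / 200, by = 1 / 200)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 50 * t)
  out <- mallat_lowpass(processed_signal(x, 200, "denoised", "accel"), 4)
  psd <- periodogram_psd(out)
  p1 <- psd$power_db[which.min(abs(psd$freqs - 1))]
  # 50 Hz aliases nowhere into the 0-6.25 Hz band; compare 1 Hz line to the
  # strongest non-1 Hz residual
  rest <- psd$power_db[abs(psd$freqs - 1) > 0.2 & psd$freqs > 0]
  expect_gt(p1 - max(rest), 20)
})

test_that("the preprocessing chain preserves duration within one output sample", {
  for (fs in c(50, 256)) {
    tr <- generate_trial(gait_params("healthy", sample_rate = fs,
                                     duration = 10), seed = 8)
    m <- signal_magnitude(tr, "accel")
    f <- mallat_lowpass(wavelet_denoise(resample_to_common(m)), 4)
    expect_lte(abs(length(f$samples) / f$sample_rate - 10),
               1 / f$sample_rate + 1e-9)
  }
})

test_that("stride valleys survive denoise + filter on a jitter-free trial", {
  p <- gait_params("healthy", stride_jitter_sd = 0, duration = 20,
                   sample_rate = 200)
  tr <- generate_trial(p, seed = 10)
  m <- signal_magnitude(tr, "accel")
  f <- mallat_lowpass(wavelet_denoise(resample_to_common(m)), 4)
  t_f <- (seq_along(f$samples) - 1) / f$sample_rate
  for (v in tr$truth$valley_times[2:(length(tr$truth$valley_times) - 1)]) {
    win <- which(abs(t_f - v) <= 0.25)
    i_min <- win[which.min(f$samples[win])]
    # the local minimum sits within two output samples of the true valley
    expect_lte(abs(t_f[i_min] - v), 2 / f$sample_rate + 1e-9)
  }
})
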