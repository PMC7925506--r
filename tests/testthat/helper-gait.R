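# shared fixtures, all built in code

# two Gaussian blobs in [0,1]^d, labels "a"/"b"
make_blobs <- function(n_per = 30, d = 2, centers = c(0.2, 0.8), sd = 0.05,
                       seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * d, centers[1], sd), n_per, d),
    matrix(rnorm(n_per * d, centers[2], sd), n_per, d)
  )
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

# a small mixed cohort: cheap enough for unit tests
small_cohort <- function(n_h = 4, n_p = 4, seed = 11, duration = 20) {
  c(
    lapply(seq_len(n_h), function(i) {
      generate_trial(gait_params("healthy", duration = duration),
                     seed = seed + i)
    }),
    lapply(seq_len(n_p), function(i) {
      generate_trial(gait_params("pathological", duration = duration),
                     seed = seed + 100 + i)
    })
  )
}

# sine-based processed signal at a given stage
sine_signal <- function(freq, fs, dur, amp = 1, stage = "denoised",
                        source = "accel", offset = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  processed_signal(offset + amp * sin(2 * pi * freq * t), fs, stage, source)
}
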