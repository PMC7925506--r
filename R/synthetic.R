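#' Gait simulation parameters
#'
#' Bundles the physical parameters of one simulated walking trial recorded by a
#' calf-mounted smartphone IMU. Class defaults encode the two study groups:
#' healthy gait is fast, regular and left/right symmetric; hemiplegic gait is
#' slow, irregular and strongly asymmetric, with weaker angular dynamics.
#'
#' @param label `"healthy"` or `"pathological"`.
#' @param stride_period full gait-cycle duration in seconds (same-foot contact
#'   to same-foot contact). Healthy default 1.1 s, i.e. a step frequency of
#'   about 1.8 Hz; pathological default 1.8 s.
#' @param stride_jitter_sd standard deviation, in seconds, of the i.i.d.
#'   Gaussian perturbation applied to every foot-contact time. Healthy 0.02 s,
#'   pathological 0.15 s.
#' @param step_amplitude peak amplitude, in m/s^2, of the instrumented-leg
#'   foot-contact transient on the acceleration magnitude.
#' @param contralateral_ratio amplitude of the other leg's transient relative
#'   to the instrumented leg, in `[0, 1]`. Near 1 for symmetric gait.
#' @param gyro_amplitude amplitude, in rad/s, of the angular-rate oscillation
#'   at the stride fundamental.
#' @param noise_sigma standard deviation of the additive zero-mean Gaussian
#'   measurement noise applied to each magnitude signal.
#' @param duration trial length in seconds (the study protocol used 10 or 20).
#' @param sample_rate native sensor rate in Hz (device dependent, 50-350).
#'
#' @return object of class `gait_params`.
#' @export
#' @examples
#' gait_params("pathological", duration = 20)
gait_params <- function(label = c("healthy", "pathological"),
                        stride_period = NULL,
                        stride_jitter_sd = NULL,
                        step_amplitude = NULL,
                        contralateral_ratio = NULL,
                        gyro_amplitude = NULL,
                        noise_sigma = 0.25,
                        duration = 10,
                        sample_rate = 200) {
  label <- match.arg(label)
  def <- .class_defaults(label)
  p <- list(
    label = label,
    stride_period = stride_period %||% def$stride_period,
    stride_jitter_sd = stride_jitter_sd %||% def$stride_jitter_sd,
    step_amplitude = step_amplitude %||% def$step_amplitude,
    contralateral_ratio = contralateral_ratio %||% def$contralateral_ratio,
    gyro_amplitude = gyro_amplitude %||% def$gyro_amplitude,
    noise_sigma = noise_sigma,
    duration = duration,
    sample_rate = sample_rate
  )
  .validate_gait_params(p)
  structure(p, class = "gait_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.class_defaults <- function(label) {
  if (label == "healthy") {
    list(stride_period = 1.1, stride_jitter_sd = 0.02, step_amplitude = 4.0,
         contralateral_ratio = 0.9, gyro_amplitude = 1.5)
  } else {
    list(stride_period = 1.8, stride_jitter_sd = 0.15, step_amplitude = 2.5,
         contralateral_ratio = 0.4, gyro_amplitude = 0.9)
  }
}

.validate_gait_params <- function(p) {
  stopifnot(p$stride_period > 0,
            p$stride_jitter_sd >= 0,
            p$step_amplitude > 0,
            p$gyro_amplitude > 0,
            p$noise_sigma >= 0,
            p$duration > 0,
            p$sample_rate > 0)
  if (p$contralateral_ratio < 0 || p$contralateral_ratio > 1) {
    stop("contralateral_ratio must lie in [0, 1]", call. = FALSE)
  }
  if (p$duration * p$sample_rate < 128) {
    stop("duration * sample_rate gives fewer than the 128 samples required ",
         "by the level-4 wavelet denoiser", call. = FALSE)
  }
  invisible(p)
}

# fixed unit direction vectors for the axis split; the Euclidean norm of the
# three channels recovers the (positive) magnitude exactly
.ACCEL_DIR <- c(0.36, 0.48, 0.80)
.GYRO_DIR <- c(0.48, 0.60, 0.64)

# biphasic foot-contact kernel: negative first derivative of a Gaussian,
# scaled so the positive spike (at -width) and the valley (at +width) have
# unit magnitude
.contact_kernel <- function(tau, width) {
  -(tau / width) * exp(0.5 - tau^2 / (2 * width^2))
}

#' Simulate one raw IMU walking trial
#'
#' Builds the clean acceleration magnitude as gravity plus a train of biphasic
#' foot-contact transients (a sharp spike followed by a deceleration valley) at
#' alternating left/right contact times spaced half a stride apart, with the
#' instrumented leg at `step_amplitude` and the contralateral leg attenuated by
#' `contralateral_ratio`. The clean gyroscope magnitude oscillates at the
#' stride fundamental `1/stride_period`, which places the acceleration
#' spectral peak (a per-step event) at the gyroscope's second harmonic.
#' Both magnitudes receive additive zero-mean Gaussian noise of standard
#' deviation `noise_sigma` and are then split over fixed unit direction
#' vectors into three channels.
#'
#' @param params a [gait_params()] object.
#' @param seed integer seed; trials are bit-reproducible given
#'   `(params, seed)`.
#'
#' @return object of class `raw_trial`: list with `time` (seconds), `accel`
#'   and `gyro` (n x 3 matrices, m/s^2 and rad/s), `sample_rate`, `label`, and
#'   `truth` (ground truth: instrumented-leg contact and valley times, the
#'   clean and noisy magnitudes, and the generating parameters).
#' @export
#' @examples
#' tr <- generate_trial(gait_params("healthy", duration = 10), seed = 1)
#' length(tr$truth$valley_times)
generate_trial <- function(params, seed = 1L) {
  stopifnot(inherits(params, "gait_params"))
  .validate_gait_params(params)
  set.seed(as.integer(seed))

  fs <- params$sample_rate
  n <- round(params$duration * fs)
  t <- (seq_len(n) - 1) / fs
  T_s <- params$stride_period
  width <- T_s / 10

  # alternating contacts: instrumented leg at (k + 1/2) * T, other leg a half
  # stride later; keep the full kernel support inside the record
  k_max <- floor((params$duration - 3 * width) / T_s - 0.5)
  k <- 0:max(k_max, 0)
  instr <- (k + 0.5) * T_s
  contra <- instr + T_s / 2
  instr <- instr + stats::rnorm(length(instr), 0, params$stride_jitter_sd)
  contra <- contra + stats::rnorm(length(contra), 0, params$stride_jitter_sd)
  keep_i <- instr > 3 * width & instr < params$duration - 3 * width
  keep_c <- contra > 3 * width & contra < params$duration - 3 * width
  instr <- sort(instr[keep_i])
  contra <- sort(contra[keep_c])

  accel_clean <- rep(9.81, n)
  for (c0 in instr) {
    accel_clean <- accel_clean +
      params$step_amplitude * .contact_kernel(t - c0, width)
  }
  for (c0 in contra) {
    accel_clean <- accel_clean +
      params$contralateral_ratio * params$step_amplitude *
        .contact_kernel(t - c0, width)
  }
  gyro_clean <- params$gyro_amplitude * (2 + sin(2 * pi * t / T_s))

  accel_mag <- accel_clean + stats::rnorm(n, 0, params$noise_sigma)
  gyro_mag <- gyro_clean + stats::rnorm(n, 0, params$noise_sigma)

  trial <- list(
    time = t,
    accel = outer(accel_mag, .ACCEL_DIR),
    gyro = outer(gyro_mag, .GYRO_DIR),
    sample_rate = fs,
    label = params$label,
    truth = list(
      contact_times = instr,
      valley_times = instr + width,   # kernel minimum sits one width after contact
      clean_accel_mag = accel_clean,
      clean_gyro_mag = gyro_clean,
      noisy_accel_mag = accel_mag,
      noisy_gyro_mag = gyro_mag,
      params = params
    )
  )
  colnames(trial$accel) <- c("ax", "ay", "az")
  colnames(trial$gyro) <- c("gx", "gy", "gz")
  structure(trial, class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %s, %.0f Hz, %.1f s (%d samples), %d truth valleys\n",
              x$label, x$sample_rate, length(x$time) / x$sample_rate,
              length(x$time), length(x$truth$valley_times)))
  invisible(x)
}

# move per-class parameter means apart (separation > 1) or together (< 1)
# about their geometric midpoint; used by the widened-separation regime
.widen <- function(healthy, path, separation) {
  mid <- sqrt(healthy * path)
  c(healthy = mid * (healthy / mid)^separation,
    pathological = mid * (path / mid)^separation)
}

#' Simulate a labeled cohort of walking trials
#'
#' Defaults replicate the clinical study shape: 35 healthy plus 25 post-stroke
#' trials, 41 recorded for 10 s and 19 for 20 s with pathological trials
#' over-represented in the 20 s group (12 of 19), captured on heterogeneous
#' devices with native rates drawn from `rate_pool`. Per-trial parameters are
#' drawn around the class defaults (log-normal spread on period and
#' amplitudes) so the two classes overlap rather than separate trivially.
#'
#' @param n_healthy,n_pathological trial counts per class.
#' @param rate_pool candidate native sampling rates in Hz.
#' @param duration_split fraction of trials recorded for 10 s (the remainder
#'   run 20 s).
#' @param seed integer seed for the whole cohort.
#' @param separation class-separation multiplier: 1 keeps the study defaults,
#'   2 doubles the log-scale distance between class parameter means (the
#'   well-separated regime). Parameters are clipped to their validity ranges
#'   (`contralateral_ratio` to `[0, 1]`, contact jitter to at most a sixth of
#'   the stride period).
#' @param long_path_fraction fraction of the 20 s trials assigned to the
#'   pathological class (study value 12/19).
#'
#' @return list of [generate_trial()] objects.
#' @export
#' @examples
#' cohort <- generate_cohort(n_healthy = 3, n_pathological = 2, seed = 1)
#' table(vapply(cohort, `[[`, "", "label"))
generate_cohort <- function(n_healthy = 35, n_pathological = 25,
                            rate_pool = c(50, 100, 128, 200, 256, 350),
                            duration_split = 41 / 60,
                            seed = 1L,
                            separation = 1,
                            long_path_fraction = 12 / 19) {
  stopifnot(n_healthy >= 0, n_pathological >= 0)
  if (length(rate_pool) == 0) stop("rate_pool must not be empty", call. = FALSE)
  set.seed(as.integer(seed))

  total <- n_healthy + n_pathological
  if (total == 0) return(list())
  n20 <- total - round(duration_split * total)
  n20_path <- min(n_pathological, round(n20 * long_path_fraction))
  n20_healthy <- min(n_healthy, n20 - n20_path)

  hd <- .class_defaults("healthy")
  pd <- .class_defaults("pathological")
  sp <- .widen(hd$stride_period, pd$stride_period, separation)
  ga <- .widen(hd$gyro_amplitude, pd$gyro_amplitude, separation)
  sa <- .widen(hd$step_amplitude, pd$step_amplitude, separation)
  jt <- .widen(hd$stride_jitter_sd, pd$stride_jitter_sd, separation)
  cr <- .widen(hd$contralateral_ratio, pd$contralateral_ratio, separation)
  cr <- pmin(pmax(cr, 0), 1)

  labels <- c(rep("healthy", n_healthy), rep("pathological", n_pathological))
  durations <- c(rep(c(20, 10), c(n20_healthy, n_healthy - n20_healthy)),
                 rep(c(20, 10), c(n20_path, n_pathological - n20_path)))
  rates <- sample(rate_pool, total, replace = TRUE)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, total)

  lapply(seq_len(total), function(i) {
    lab <- labels[i]
    period <- sp[[lab]] * stats::rlnorm(1, 0, if (lab == "healthy") 0.12 else 0.15)
    jitter <- min(jt[[lab]] * stats::rlnorm(1, 0, 0.2), period / 6)
    p <- gait_params(
      label = lab,
      stride_period = period,
      stride_jitter_sd = jitter,
      step_amplitude = sa[[lab]] * stats::rlnorm(1, 0, 0.2),
      contralateral_ratio = min(max(cr[[lab]] + stats::rnorm(1, 0, 0.05), 0), 1),
      gyro_amplitude = ga[[lab]] * stats::rlnorm(1, 0, 0.25),
      noise_sigma = 0.25,
      duration = durations[i],
      sample_rate = rates[i]
    )
    generate_trial(p, seed = trial_seeds[i])
  })
}

#' Write / read a trial as CSV plus JSON sidecar
#'
#' The CSV holds columns `t, ax, ay, az, gx, gy, gz`; the sidecar (same path
#' with extension `.json`) records the label, the sample rate and, for
#' synthetic trials, the ground-truth valley times.
#'
#' @param trial a `raw_trial`.
#' @param path CSV file path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   `raw_trial` (with `truth` restored when present in the sidecar).
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "raw_trial"))
  df <- data.frame(t = trial$time, trial$accel, trial$gyro, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(label = trial$label, sample_rate = trial$sample_rate)
  if (!is.null(trial$truth)) {
    side$valley_times <- trial$truth$valley_times
    side$contact_times <- trial$truth$contact_times
  }
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_trial
#' @param path CSV file path written by [write_trial()] (or any file with the
#'   documented column layout).
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("trial file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  t <- df$t
  if (length(t) < 2) stop("trial file has fewer than 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
    stop("timestamps are not uniform within 1%: cannot infer a sampling rate",
         call. = FALSE)
  }
  rate <- 1 / stats::median(dt)

  side_path <- .sidecar_path(path)
  label <- NA_character_
  truth <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    label <- side$label %||% NA_character_
    if (!is.null(side$sample_rate) &&
        abs(side$sample_rate - rate) > 0.01 * side$sample_rate) {
      stop("sampling rate inferred from timestamps (", round(rate, 2),
           " Hz) disagrees with sidecar (", side$sample_rate, " Hz) by more than 1%",
           call. = FALSE)
    }
    rate <- side$sample_rate %||% rate
    if (!is.null(side$valley_times)) {
      truth <- list(valley_times = side$valley_times,
                    contact_times = side$contact_times)
    }
  }
  trial <- list(
    time = t,
    accel = as.matrix(df[, c("ax", "ay", "az")]),
    gyro = as.matrix(df[, c("gx", "gy", "gz")]),
    sample_rate = rate,
    label = label,
    truth = truth
  )
  structure(trial, class = "raw_trial")
}
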