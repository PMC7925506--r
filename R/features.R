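#' Expected per-step interval from the two spectral peaks
#'
#' The acceleration peak is a per-step event (each foot contact excites the
#' magnitude), while the gyroscope fundamental tracks the full stride; under
#' the second-harmonic relation the step interval is `1/peak_freq_accel` from
#' the accelerometer and `1/(2 * peak_freq_gyro)` from the gyroscope. The two
#' estimates are averaged and the result seeds the rolling-window valley
#' search.
#'
#' @param accel_psd,gyro_psd `psd_estimate` objects.
#' @return expected step interval in seconds.
#' @export
#' @examples
#' # accel peak at 2 Hz and gyro peak at 1 Hz both say steps last 0.5 s
expected_step_window <- function(accel_psd, gyro_psd) {
  stopifnot(inherits(accel_psd, "psd_estimate"),
            inherits(gyro_psd, "psd_estimate"))
  fa <- accel_psd$peak_freq
  fg <- gyro_psd$peak_freq
  if (!is.finite(fa) || !is.finite(fg) || fa <= 0 || fg <= 0) {
    stop("undefined spectral peak: cannot estimate a step window", call. = FALSE)
  }
  ((1 / fa) + (1 / (2 * fg))) / 2
}

#' Detect stride valleys by a rolling-window minimum search
#'
#' Strides are delimited by "valleys" of the filtered acceleration magnitude:
#' each foot contact produces a spike followed by a deceleration minimum. The
#' search starts from the global minimum over the first `1.5 * window`
#' seconds; each subsequent guess is the previous valley plus one stride
#' (`stride_factor * window`, two steps per stride), and the accepted valley
#' is the signal minimum within `+/- search_frac` of a stride around that
#' guess. The search stops when the interval would run past the end of the
#' record.
#'
#' @param sig `processed_signal` at stage `"filtered"` (the 12.5 Hz
#'   acceleration magnitude in the default chain).
#' @param window expected per-step interval in seconds, normally from
#'   [expected_step_window()].
#' @param search_frac half-width of the search interval as a fraction of the
#'   stride window.
#' @param stride_factor steps per stride (2: valleys are per-stride events of
#'   the instrumented leg).
#' @return numeric vector of valley times in seconds, strictly increasing,
#'   consecutive valleys at least `(1 - 2 * search_frac)` strides apart.
#' @export
detect_valleys <- function(sig, window, search_frac = 0.3, stride_factor = 2) {
  stopifnot(inherits(sig, "processed_signal"))
  if (sig$stage != "filtered") {
    stop("detect_valleys expects a stage 'filtered' signal, got '",
         sig$stage, "'", call. = FALSE)
  }
  fs <- sig$sample_rate
  if (window <= 2 / fs) {
    stop("window must exceed two sample periods", call. = FALSE)
  }
  x <- sig$samples
  t <- (seq_along(x) - 1) / fs
  t_end <- t[length(t)]
  sw <- stride_factor * window

  first_span <- which(t <= 1.5 * window)
  v <- t[first_span[which.min(x[first_span])]]
  valleys <- v
  repeat {
    guess <- v + sw
    lo <- guess - search_frac * sw
    hi <- guess + search_frac * sw
    if (hi > t_end) break
    idx <- which(t >= lo & t <= hi)
    if (length(idx) == 0) break
    v <- t[idx[which.min(x[idx])]]
    valleys <- c(valleys, v)
  }
  if (length(valleys) < 2) {
    stop("insufficient strides: fewer than 2 valleys detected", call. = FALSE)
  }
  valleys
}

#' Stride (cycle) durations from valley locations
#'
#' Successive differences of the valley times: `C_d[k] = V[k+1] - V[k]`.
#'
#' @param V strictly increasing valley times in seconds.
#' @return vector of stride durations, length `length(V) - 1`.
#' @export
#' @examples
#' cycle_durations(c(0.5, 1.6, 2.6))
cycle_durations <- function(V) {
  if (length(V) < 2) stop("need at least 2 valleys", call. = FALSE)
  if (any(diff(V) <= 0)) stop("valley times must be strictly increasing",
                              call. = FALSE)
  diff(V)
}

#' Cycle regularity: standard deviation of stride durations
#'
#' Sample standard deviation (denominator `n - 1`) of the stride-duration
#' vector; values near zero indicate regular gait.
#'
#' @param C_d stride durations in seconds.
#' @return regularity in seconds.
#' @export
cycle_regularity <- function(C_d) {
  if (length(C_d) < 2) stop("need at least 2 stride durations", call. = FALSE)
  stats::sd(C_d)
}

#' Cadence in cycles per minute
#'
#' Projected strides per minute: `60 * N_c / (V_l - V_f)` with
#' `N_c = length(V) - 1` cycles between the first and last valley.
#'
#' @param V strictly increasing valley times in seconds.
#' @return cadence in cycles/min.
#' @export
#' @examples
#' cadence(c(0, 1, 2, 3))  # 60
cadence <- function(V) {
  if (length(V) < 2) stop("need at least 2 valleys", call. = FALSE)
  span <- V[length(V)] - V[1]
  if (span <= 0) stop("first and last valleys coincide", call. = FALSE)
  60 * (length(V) - 1) / span
}

.STAGE_NAMES <- c("magnitude", "resample", "denoise", "psd", "filter", "valleys")

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Extract the five gait features from one raw trial
#'
#' Runs the full chain: Euclidean magnitudes, resampling to 200 Hz, wavelet
#' denoising, periodogram peaks on the denoised 200 Hz signals, 4-level
#' filter-bank decimation of the acceleration to 12.5 Hz, rolling-window
#' valley detection, and the stride statistics. The five features are the
#' mean stride duration, the stride-duration standard deviation (regularity),
#' the cadence, and the two PSD peak magnitudes.
#'
#' @param trial a `raw_trial`.
#' @param target_rate common analysis rate (Hz).
#' @param levels wavelet decomposition / filter-bank depth.
#' @param search_frac,stride_factor valley-search parameters, see
#'   [detect_valleys()].
#' @param valley_stage `"filtered"` (default; 12.5 Hz analysis signal) or
#'   `"denoised"` to run the valley search at 200 Hz.
#' @return object of class `gait_features`: one-row data frame with columns
#'   `mean_cycle_duration_s`, `cycle_regularity_s`, `cadence_cpm`,
#'   `psd_peak_accel_db`, `psd_peak_gyro_db`, `label`.
#' @export
#' @examples
#' tr <- generate_trial(gait_params("healthy", duration = 10), seed = 3)
#' extract_features(tr)
extract_features <- function(trial, target_rate = 200, levels = 4,
                             search_frac = 0.3, stride_factor = 2,
                             valley_stage = c("filtered", "denoised")) {
  stopifnot(inherits(trial, "raw_trial"))
  valley_stage <- match.arg(valley_stage)

  am <- .with_stage("magnitude", signal_magnitude(trial, "accel"))
  gm <- .with_stage("magnitude", signal_magnitude(trial, "gyro"))
  ar <- .with_stage("resample", resample_to_common(am, target_rate))
  gr <- .with_stage("resample", resample_to_common(gm, target_rate))
  ad <- .with_stage("denoise", wavelet_denoise(ar, levels))
  gd <- .with_stage("denoise", wavelet_denoise(gr, levels))
  apsd <- .with_stage("psd", periodogram_psd(ad))
  gpsd <- .with_stage("psd", periodogram_psd(gd))
  window <- .with_stage("psd", expected_step_window(apsd, gpsd))
  vsig <- if (valley_stage == "filtered") {
    .with_stage("filter", mallat_lowpass(ad, levels))
  } else {
    ad
  }
  if (valley_stage == "denoised") vsig$stage <- "filtered"
  V <- .with_stage("valleys",
                   detect_valleys(vsig, window, search_frac, stride_factor))
  C_d <- cycle_durations(V)
  peaks <- psd_peak_features(apsd, gpsd)

  out <- data.frame(
    mean_cycle_duration_s = mean(C_d),
    cycle_regularity_s = if (length(C_d) >= 2) cycle_regularity(C_d) else 0,
    cadence_cpm = cadence(V),
    psd_peak_accel_db = unname(peaks["psd_peak_accel_db"]),
    psd_peak_gyro_db = unname(peaks["psd_peak_gyro_db"]),
    label = trial$label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gait_features", class(out))
  out
}

#' Feature matrix for a cohort of trials
#'
#' Applies [extract_features()] to every trial; failing trials are
#' quarantined (dropped with a warning naming the failing stage) rather than
#' aborting the cohort.
#'
#' @param trials list of `raw_trial` objects.
#' @param ... passed to [extract_features()].
#' @return data frame with one row per successfully processed trial, a
#'   `trial_id` column, the five feature columns and `label`; quarantined
#'   trial ids are attached as `attr(, "quarantined")`.
#' @export
cohort_features <- function(trials, ...) {
  rows <- vector("list", length(trials))
  failed <- character(0)
  for (i in seq_along(trials)) {
    id <- sprintf("trial_%03d", i)
    res <- tryCatch(extract_features(trials[[i]], ...), error = function(e) e)
    if (inherits(res, "error")) {
      warning("quarantined ", id, ": ", conditionMessage(res), call. = FALSE)
      failed <- c(failed, id)
    } else {
      rows[[i]] <- cbind(trial_id = id, res)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "quarantined") <- failed
  out
}

#' Feature columns used for classification, in canonical order
#' @export
feature_columns <- function() {
  c("mean_cycle_duration_s", "cycle_regularity_s", "cadence_cpm",
    "psd_peak_accel_db", "psd_peak_gyro_db")
}
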