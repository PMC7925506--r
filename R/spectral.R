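#' Periodogram power spectral density with peak extraction
#'
#' Plain (rectangular-window) periodogram of the mean-removed signal on its
#' native rate's one-sided frequency grid, reported in dB
#' (`10 * log10(PSD)`). The one-sided scaling is exact: summing the PSD over
#' the grid times the bin width recovers the signal variance (Parseval). The
#' peak is the maximum over all non-DC bins; the DC bin is excluded because
#' the gravity/mean offset would otherwise dominate.
#'
#' @param sig `processed_signal` (any stage; for the study pipeline the
#'   denoised, unfiltered 200 Hz signal is used).
#' @return object of class `psd_estimate`: list with `freqs` (Hz, from 0 to
#'   the Nyquist frequency), `power_db`, `peak_freq`, `peak_power_db` and
#'   `source`.
#' @export
#' @examples
#' s <- processed_signal(sin(2 * pi * 2 * (0:3999) / 200), 200,
#'                       "denoised", "accel")
#' periodogram_psd(s)$peak_freq
periodogram_psd <- function(sig) {
  stopifnot(inherits(sig, "processed_signal"))
  x <- sig$samples
  n <- length(x)
  if (n < 16) stop("periodogram requires at least 16 samples", call. = FALSE)
  fs <- sig$sample_rate
  x <- x - mean(x)
  if (stats::var(x) < 1e-20) {
    stop("no spectral peak: signal is constant (all non-DC power ~ 0)",
         call. = FALSE)
  }
  X <- stats::fft(x)
  n_half <- n %/% 2
  k <- 0:n_half
  psd <- (abs(X[k + 1])^2) / (fs * n)
  # one-sided: double everything except DC and (for even n) the Nyquist bin
  scale <- rep(2, n_half + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_half + 1] <- 1
  psd <- psd * scale
  freqs <- k * fs / n
  power_db <- 10 * log10(pmax(psd, .Machine$double.xmin))
  peak_idx <- which.max(power_db[-1]) + 1L
  structure(list(freqs = freqs, power_db = power_db,
                 peak_freq = freqs[peak_idx],
                 peak_power_db = power_db[peak_idx],
                 source = sig$source),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %s: peak %.3f Hz at %.2f dB (%d bins, df = %.4f Hz)\n",
              x$source, x$peak_freq, x$peak_power_db, length(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' PSD peak features
#'
#' The two spectral gait features: the maximum PSD magnitude (dB) of the
#' acceleration and of the gyroscope signal.
#'
#' @param accel_psd,gyro_psd `psd_estimate` objects for the respective
#'   sensors.
#' @return named numeric vector `c(psd_peak_accel_db, psd_peak_gyro_db)`.
#' @export
psd_peak_features <- function(accel_psd, gyro_psd) {
  stopifnot(inherits(accel_psd, "psd_estimate"),
            inherits(gyro_psd, "psd_estimate"))
  if (accel_psd$source != "accel" || gyro_psd$source != "gyro") {
    stop("mismatched sources: expected an accel and a gyro psd_estimate, got '",
         accel_psd$source, "' and '", gyro_psd$source, "'", call. = FALSE)
  }
  c(psd_peak_accel_db = accel_psd$peak_power_db,
    psd_peak_gyro_db = gyro_psd$peak_power_db)
}
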