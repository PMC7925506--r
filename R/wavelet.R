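# Decimated discrete wavelet transform with half-point symmetric extension.
# Filters are the order-4 least-asymmetric Daubechies family (symlet, "sym4").
# Coefficient conventions and boundary bookkeeping follow the standard
# pyramid scheme: analysis keeps floor((n + L - 1)/2) coefficients per band,
# synthesis trims L - 2 samples from each side and cuts back to the recorded
# per-level length, which yields perfect reconstruction to machine precision.

.sym4 <- list(
  dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783, 0.03222310060404270),
  dec_hi = c(-0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
             0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333),
  rec_lo = c(0.03222310060404270, -0.01260396726203783, -0.09921954357684722,
             0.29785779560527736, 0.80373875180591614, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333),
  rec_hi = c(-0.07576571478927333, 0.02963552764599851, 0.49761866763201545,
             -0.80373875180591614, 0.29785779560527736, 0.09921954357684722,
             -0.01260396726203783, -0.03222310060404270)
)

.conv_full <- function(x, h) stats::convolve(x, rev(h), type = "open")

# one analysis step: symmetric extension, convolve, keep every second sample
.dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  p <- L - 1L
  stopifnot(n >= p)
  xe <- c(rev(x[seq_len(p)]), x, rev(x[seq.int(n - p + 1L, n)]))
  y <- .conv_full(xe, h)
  nout <- (n + L - 1L) %/% 2L
  y[seq.int(L + 1L, by = 2L, length.out = nout)]
}

# one synthesis step: zero-interleave, convolve with synthesis pair, trim
.idwt_step <- function(cA, cD, n_out, filt = .sym4) {
  stopifnot(length(cA) == length(cD))
  L <- length(filt$rec_lo)
  up <- function(v) {
    u <- numeric(2L * length(v))
    u[seq.int(1L, by = 2L, length.out = length(v))] <- v
    u
  }
  y <- .conv_full(up(cA), filt$rec_lo) + .conv_full(up(cD), filt$rec_hi)
  nfull <- 2L * length(cA) - L + 2L
  y <- y[seq.int(L - 1L, length.out = nfull)]
  y[seq_len(n_out)]
}

#' Multilevel symlet-4 wavelet decomposition
#'
#' Internal engine for [wavelet_denoise()] and [mallat_lowpass()].
#'
#' @param x numeric signal.
#' @param levels number of decomposition levels.
#' @return list with `approx` (level-`levels` approximation), `details`
#'   (list of detail coefficient vectors, level 1 first) and `lengths`
#'   (input length at each level, needed for exact reconstruction).
#' @keywords internal
.dwt_decompose <- function(x, levels) {
  stopifnot(levels >= 1L)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (w in seq_len(levels)) {
    lengths[w] <- length(a)
    details[[w]] <- .dwt_step(a, .sym4$dec_hi)
    a <- .dwt_step(a, .sym4$dec_lo)
  }
  list(approx = a, details = details, lengths = lengths)
}

#' @keywords internal
.dwt_reconstruct <- function(dec) {
  a <- dec$approx
  for (w in rev(seq_along(dec$details))) {
    a <- .idwt_step(a, dec$details[[w]], dec$lengths[w])
  }
  a
}

# soft shrinkage: sign(x) * max(|x| - t, 0)
.soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
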