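#' @importFrom stats fft median quantile rnorm runif rlnorm rpois sd var
#' @importFrom utils head tail
NULL

GRAVITY_MS2 <- 9.80665

#' Zero-phase Butterworth filter
#'
#' Wraps `signal::butter` + `signal::filtfilt` with reflective padding to
#' suppress edge transients on short records.
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate in Hz.
#' @param cutoff_hz scalar (low/high-pass) or length-2 (band-pass) cutoff.
#' @param type "low", "high" or "pass".
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
butter_filtfilt <- function(x, fs_hz, cutoff_hz, type = c("low", "high", "pass"),
                            order = 4L) {
  type <- match.arg(type)
  w <- cutoff_hz / (fs_hz / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("cutoff_hz must lie strictly inside (0, fs_hz/2)")
  }
  bf <- signal::butter(order, w, type = switch(type, low = "low",
                                               high = "high", pass = "pass"))
  npad <- min(length(x) - 1L, max(64L, round(3 * fs_hz)))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1L)]), x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1L)]))
  yp <- signal::filtfilt(bf, xp)
  yp[(npad + 1L):(npad + length(x))]
}

# cumulative trapezoidal integral on a uniform grid
cumtrapz_uniform <- function(x, fs_hz) {
  pracma::cumtrapz(seq_along(x) / fs_hz, x)[, 1]
}

# indices of strict local minima / maxima of a vector
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# dominant frequency of a (detrended) signal within [f_lo, f_hi], by FFT
dominant_frequency <- function(x, fs_hz, f_lo = 0.3, f_hi = 4) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n, 256L)))
  sp <- Mod(fft(c(x * signal::hanning(n), rep(0, nfft - n))))^2
  freqs <- (seq_len(nfft) - 1L) * fs_hz / nfft
  band <- which(freqs >= f_lo & freqs <= f_hi)
  if (!length(band)) stop("frequency band empty at this sampling rate")
  freqs[band[which.max(sp[band])]]
}

# fraction of spectral power of a detrended, Hann-tapered signal in [f_lo, f_hi]
band_power_fraction <- function(x, fs_hz, f_lo, f_hi) {
  x <- x - mean(x)
  if (sum(x^2) == 0) return(0)
  n <- length(x)
  x <- x * signal::hanning(n)
  nfft <- 2^ceiling(log2(max(n, 64L)))
  sp <- Mod(fft(c(x, rep(0, nfft - n))))^2
  half <- seq_len(floor(nfft / 2) + 1L)
  freqs <- (half - 1L) * fs_hz / nfft
  sum(sp[half][freqs >= f_lo & freqs <= f_hi]) / sum(sp[half][freqs > 0])
}
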