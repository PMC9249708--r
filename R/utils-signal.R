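#' Zero-phase Butterworth band-pass filter
#'
#' Filters a numeric vector forward and backward (`signal::filtfilt`) with a
#' Butterworth band-pass, so the output has zero phase distortion and the
#' effective attenuation is twice the single-pass design.
#'
#' @param x numeric vector, the signal in microvolts.
#' @param srate sampling rate in Hz.
#' @param low,high band edges in Hz; `0 < low < high < srate / 2`.
#' @param order Butterworth design order of the single pass (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
zerophase_bandpass <- function(x, srate, low, high, order = 4L) {
  stopifnot(is.numeric(x), srate > 0)
  if (!(low > 0 && low < high)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (high >= srate / 2) {
    stop("upper band edge must be below the Nyquist frequency (",
         srate / 2, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (srate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase Butterworth high-pass filter
#' @inheritParams zerophase_bandpass
#' @param cutoff cutoff frequency in Hz.
#' @return filtered numeric vector.
#' @export
zerophase_highpass <- function(x, srate, cutoff, order = 2L) {
  stopifnot(srate > 0, cutoff > 0, cutoff < srate / 2)
  bf <- signal::butter(order, cutoff / (srate / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# Centered moving average of window length k samples; edges use the
# shrinking window actually available (no NA padding).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 1/f^a amplitude-shaped Gaussian-phase noise, scaled to a target RMS.
# Built in the frequency domain: unit-exponent slope gives the pink
# background typical of resting EEG.
oneoverf_noise <- function(n, srate, exponent = 1, rms = 15) {
  if (n < 4L) return(stats::rnorm(n, sd = rms))
  nf <- n %/% 2L
  f <- (1:nf) * srate / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf) * 2 * pi
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = Mod(spec[nf]), imaginary = 0)
    full[(nf + 2L):n] <- Conj(spec[(nf - 1L):1L])
  } else {
    full[(nf + 2L):n] <- Conj(spec[nf:1L])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * rms / s
}

# Magnitude of the complex Morlet wavelet transform at centre frequency f0,
# computed by FFT convolution.  The wavelet is normalised so that a pure
# sinusoid at f0 with amplitude A produces a magnitude trace of ~A microvolts.
morlet_amplitude <- function(x, srate, f0, sigma_t) {
  n <- length(x)
  len <- 2^ceiling(log2(n + ceiling(8 * sigma_t * srate)))
  tt <- (0:(len - 1L)) / srate
  tt <- ifelse(tt > len / srate / 2, tt - len / srate, tt)
  gauss <- exp(-tt^2 / (2 * sigma_t^2))
  w <- gauss * exp(2i * pi * f0 * tt)
  w <- w * (2 / sum(gauss))
  xp <- c(x, numeric(len - n))
  conv <- stats::fft(stats::fft(xp) * stats::fft(w), inverse = TRUE) / len
  Mod(conv)[seq_len(n)]
}

# Integral of the linearly interpolated function (freqs, vals) over
# [lo, hi].  Exactly additive over adjacent intervals, which is what makes
# relative band powers over a partition sum to the total to machine
# precision.
trapz_band <- function(freqs, vals, lo, hi) {
  lo <- max(lo, freqs[1L])
  hi <- min(hi, freqs[length(freqs)])
  if (hi <= lo) return(0)
  inner <- freqs > lo & freqs < hi
  fx <- c(lo, freqs[inner], hi)
  fy <- c(stats::approx(freqs, vals, xout = lo)$y,
          vals[inner],
          stats::approx(freqs, vals, xout = hi)$y)
  sum(diff(fx) * (fy[-1L] + fy[-length(fy)]) / 2)
}
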