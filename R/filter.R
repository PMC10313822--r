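# Zero-phase low-pass filtering with a 4-pole Bessel magnitude response,
# applied in the frequency domain. Bilayer amplifiers use 4-pole Bessel
# hardware filters; a zero-phase digital realisation keeps event edges
# symmetric, which matters for half-amplitude idealization.

# 4th-order Bessel polynomial B4(s) = s^4 + 10 s^3 + 45 s^2 + 105 s + 105
# (delay-normalised). |B4(i w)|^2 evaluated directly.
.bessel4_mag2 <- function(w) {
  re <- w^4 - 45 * w^2 + 105
  im <- 105 * w - 10 * w^3
  105^2 / (re^2 + im^2)
}

# -3 dB frequency of the delay-normalised prototype (~2.1139), cached.
.bessel4_w3db <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      w <<- stats::uniroot(function(x) .bessel4_mag2(x) - 0.5,
                           c(0.5, 5), tol = 1e-12)$root
    }
    w
  }
})

# Gain of the filter at frequency f (Hz) for cutoff fc (-3 dB point, Hz).
.bessel4_gain <- function(f, fc) {
  sqrt(.bessel4_mag2(f / fc * .bessel4_w3db()))
}

# Core routine on a bare numeric vector. Reflective padding suppresses FFT
# wrap-around at the trace ends; DC gain is exactly 1.
.lowpass_bessel4 <- function(x, sampling_rate, cutoff) {
  n <- length(x)
  if (n < 2L) return(x)
  pad <- min(n - 1L, max(16L, ceiling(10 * sampling_rate / cutoff)))
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  m <- length(xp)
  freqs <- c(0:(m %/% 2), -((m - m %/% 2 - 1L):1L)) * sampling_rate / m
  gain <- .bessel4_gain(abs(freqs), cutoff)
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter a current trace
#'
#' Applies a zero-phase low-pass filter with the magnitude response of a
#' 4-pole Bessel filter (the bilayer-amplifier standard) at the requested
#' cutoff. DC gain is 1 to within 1e-6, so constant traces pass unchanged.
#'
#' @param trace A [trace()] object.
#' @param cutoff -3 dB cutoff frequency in Hz; must be below the Nyquist
#'   frequency. Default 1000 Hz, matching a 1 kHz recording filter.
#' @return A filtered copy of the trace; `metadata$filter_cutoff` is updated.
#' @examples
#' acq <- acquisition_params(duration = 0.05, seed = 1)
#' tr <- simulate_trace(wt_channel_model(), acq, voltage = 0)
#' tr2 <- lowpass_filter(tr, 500)
#' @export
lowpass_filter <- function(trace, cutoff = 1000) {
  stopifnot(inherits(trace, "blm_trace"))
  fs <- trace$metadata$sampling_rate
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie in (0, sampling_rate/2); got ", format(cutoff),
         " Hz at fs = ", format(fs), " Hz", call. = FALSE)
  }
  trace$current <- .lowpass_bessel4(trace$current, fs, cutoff)
  trace$metadata$filter_cutoff <- cutoff
  trace
}
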