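#' Design a Hamming windowed-sinc FIR filter
#'
#' Classic windowed-sinc design: a sinc at the cutoff frequency multiplied
#' by a Hamming window, normalized to unit DC gain (lowpass); the highpass
#' kernel is obtained by spectral inversion. The magnitude response of this
#' design passes through -6 dB (amplitude 0.5) at the cutoff. The study's
#' filters are: 0.1 Hz highpass, order 8250, transition band 0.2 Hz; 40 Hz
#' lowpass, order 166, transition band 10 Hz; 1 Hz highpass (order 8250)
#' for the ICA training copy. All at 500 Hz sampling.
#'
#' @param type `"lowpass"` or `"highpass"`.
#' @param cutoff_hz cutoff frequency (-6 dB point), Hz.
#' @param order filter order (even; kernel length `order + 1`).
#' @param transition_bw_hz nominal transition band width (stored for
#'   reporting; for a Hamming window it is tied to the order,
#'   approximately `3.3 * fs / order`).
#' @param fs sampling rate, Hz.
#' @return A `filter_kernel` list: `coefficients`, `order`, `cutoff_hz`,
#'   `transition_bw_hz`, `type`, `fs`.
#' @export
design_windowed_sinc <- function(type = c("lowpass", "highpass"),
                                 cutoff_hz, order,
                                 transition_bw_hz = 3.3 * fs / order,
                                 fs = 500) {
  type <- match.arg(type)
  if (order %% 2 != 0) stopf("order must be even (linear-phase type I)")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stopf("cutoff must lie strictly inside (0, fs/2)")
  m <- order / 2
  n <- (-m):m
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)    # Hamming window, symmetric
  h <- h * w
  h <- h / sum(h)                        # unit DC gain
  if (type == "highpass") {
    delta <- numeric(order + 1)
    delta[m + 1] <- 1
    h <- delta - h                       # spectral inversion: zero DC gain
  }
  structure(list(coefficients = h, order = order, cutoff_hz = cutoff_hz,
                 transition_bw_hz = transition_bw_hz, type = type, fs = fs),
            class = "filter_kernel")
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Magnitude response of a FIR kernel
#'
#' @param kernel a `filter_kernel`.
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @return Magnitude of the frequency response at `freq_hz`.
#' @export
filter_response <- function(kernel, freq_hz) {
  h <- kernel$coefficients
  k <- seq_along(h) - 1
  vapply(freq_hz, function(f)
    Mod(sum(h * exp(-2i * pi * f * k / kernel$fs))), numeric(1))
}

#' Apply a FIR filter with zero-phase delay compensation
#'
#' FFT convolution with reflection padding at both edges; the linear-phase
#' group delay of `order/2` samples is compensated so the output is aligned
#' with the input and has the same length.
#'
#' @param x numeric vector, or channels x samples matrix (filtered row-wise).
#' @param kernel a `filter_kernel`.
#' @return Filtered signal, same shape as `x`.
#' @export
apply_filter <- function(x, kernel) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, apply_filter, kernel = kernel))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  h <- kernel$coefficients
  m <- kernel$order / 2
  n <- length(x)
  if (n <= length(h)) stopf("signal (%d samples) must be longer than the
 filter kernel (%d taps)", n, length(h))
  pad <- min(kernel$order, n - 1)
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1]),   # reflected edges
          x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  nfft <- stats::nextn(length(xp) + length(h) - 1, 2)
  y <- Re(fft(fft(c(xp, numeric(nfft - length(xp)))) *
              fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  # causal convolution delay m, plus pad offset
  y[(pad + m + 1):(pad + m + n)]
}
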