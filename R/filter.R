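#' Design a zero-phase lowpass FIR for slow hemodynamics
#'
#' Kaiser-windowed sinc lowpass with passband edge 0.04 Hz and stopband
#' edge 0.08 Hz at 1 Hz sampling (the frame rate of the pD series),
#' designed for at least 60 dB stopband attenuation.  The filter is
#' symmetric and applied centered, so the group delay is exactly
#' compensated (zero net delay); DC gain is normalized to 1 so constant
#' signals pass unchanged.
#'
#' @param passband_hz passband edge (default 0.04)
#' @param stopband_hz stopband edge (default `2 * passband_hz`)
#' @param atten_db target stopband attenuation in dB (default 60; the
#'   design adds headroom)
#' @param fs sampling rate in Hz (default 1)
#' @return numeric vector of odd length: the filter taps
#' @export
design_lowpass <- function(passband_hz = 0.04, stopband_hz = 2 * passband_hz,
                           atten_db = 60, fs = 1) {
  stopifnot(stopband_hz > passband_hz, stopband_hz < fs / 2)
  A <- atten_db + 5                      # design headroom
  dw <- 2 * pi * (stopband_hz - passband_hz) / fs
  beta <- if (A > 50) 0.1102 * (A - 8.7) else if (A >= 21)
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21) else 0
  n_taps <- ceiling((A - 8) / (2.285 * dw))
  if (n_taps %% 2 == 1) n_taps <- n_taps + 1   # even order -> odd length
  m <- n_taps / 2
  fc <- (passband_hz + stopband_hz) / 2 / fs   # cutoff, cycles/sample
  k <- seq(-m, m)
  h <- 2 * fc * sinc(2 * fc * k)
  w <- besselI(beta * sqrt(pmax(0, 1 - (k / m)^2)), 0) / besselI(beta, 0)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Lowpass-filter a series or a pD stack
#'
#' Applies the delay-compensated FIR of [design_lowpass()] along time.
#' Edges are padded by replicating the first/last sample so the output
#' has the input's length; a series shorter than the filter errors.
#'
#' @param x numeric vector, or a [pd_stack()] (filtered per pixel)
#' @param passband_hz,stopband_atten_db filter specification (defaults
#'   0.04 Hz and 60 dB)
#' @param fs sampling rate in Hz; taken from the stack when `x` is a
#'   [pd_stack()], default 1 otherwise
#' @return filtered object of the same shape/class
#' @export
lowpass_filter <- function(x, passband_hz = 0.04, stopband_atten_db = 60,
                           fs = NULL) {
  if (inherits(x, "pd_stack")) {
    fs <- if (is.null(fs)) x$frame_rate_hz else fs
    h <- design_lowpass(passband_hz, atten_db = stopband_atten_db, fs = fs)
    d <- dim(x$data)
    flat <- matrix(x$data, nrow = d[1] * d[2])   # pixels x time
    out <- x
    out$data <- array(filter_rows(flat, h), dim = d)
    return(out)
  }
  fs <- if (is.null(fs)) 1 else fs
  h <- design_lowpass(passband_hz, atten_db = stopband_atten_db, fs = fs)
  drop(filter_rows(matrix(x, nrow = 1), h))
}

# centered FIR along rows of a pixels x time matrix, replicate padding;
# the convolution inner loop is compiled (src/fir_filter.cpp)
filter_rows <- function(m, h) {
  L <- length(h)
  n <- ncol(m)
  if (n <= L) stop("series length (", n, ") must exceed the filter length (",
                   L, ")")
  fir_filter_mat(m, h)
}
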