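#' Butterworth band-pass filter as second-order sections
#'
#' Designs a digital Butterworth band-pass filter of the given order and
#' returns it as a cascade of biquad (second-order) sections rather than as
#' one high-order transfer function.  At order 10 a band-pass design expands
#' to a degree-20 polynomial whose coefficients are numerically degenerate in
#' double precision; factoring the design into pole pairs keeps it stable.
#' The analog prototype poles are computed in closed form, transformed to a
#' band pass with [signal::sftrans()] and discretised with
#' [signal::bilinear()].
#'
#' @param order filter order of the low-pass prototype (the band-pass cascade
#'   has `order` biquad sections).
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return a numeric `order` x 6 matrix; each row is one section
#'   `(b0, b1, b2, a0, a1, a2)`.
#' @export
butter_bandpass_sos <- function(order, lo, hi, fs) {
  stopifnot(order >= 1, lo > 0, hi > lo, hi < fs / 2)
  k <- seq_len(order)
  proto <- signal::Zpg(z = complex(0),
                       p = exp(1i * pi * (2 * k + order - 1) / (2 * order)),
                       g = 1)
  TT <- 2
  W <- 2 / TT * tan(pi * c(lo, hi) / fs)   # prewarped band edges
  bp <- signal::sftrans(proto, W = W, stop = FALSE)
  dz <- signal::bilinear(bp, T = TT)
  p <- dz$p
  p <- p[order(Re(p), abs(Im(p)), sign(Im(p)))]   # conjugates adjacent
  z <- dz$z[order(Re(dz$z))]                       # order zeros at +1, order at -1
  gper <- Re(dz$g)^(1 / order)
  sos <- matrix(0, order, 6)
  for (j in seq_len(order)) {
    zj <- z[c(j, 2 * order + 1 - j)]   # pair one low-edge with one high-edge zero
    pj <- p[c(2 * j - 1, 2 * j)]
    sos[j, 1:3] <- gper * Re(signal::poly(zj))
    sos[j, 4:6] <- Re(signal::poly(pj))
  }
  sos
}

#' Zero-phase band-pass filtering of a neurons-by-time matrix
#'
#' Applies a biquad cascade forward and backward (zero phase) along time.
#' The series are zero-padded by `pad_s` seconds on both sides before
#' filtering and the padding is removed afterwards, so filter start-up
#' transients decay inside the padding rather than in the data.
#'
#' @param x numeric matrix, neurons x time (a single time series is also
#'   accepted).
#' @param sos second-order-section matrix from [butter_bandpass_sos()].
#' @param fs sampling rate in Hz.
#' @param pad_s zero-padding duration in seconds on each side.
#' @return filtered matrix with the same shape as `x`.
#' @export
filtfilt_padded <- function(x, sos, fs, pad_s = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  npad <- round(pad_s * fs)
  n <- nrow(x); T <- ncol(x)
  xp <- cbind(matrix(0, n, npad), x, matrix(0, n, npad))
  yp <- sos_filtfilt_cols(sos, t(xp))     # columns are neurons
  y <- t(yp)[, npad + seq_len(T), drop = FALSE]
  if (vec) drop(y) else y
}

#' Analytic-signal envelope via the Hilbert transform
#'
#' Computes the magnitude of the analytic signal of each row (the canonical
#' FFT construction: double positive frequencies, zero negative ones).
#'
#' @param x numeric matrix, neurons x time, or a single time series.
#' @return matrix (or vector) of instantaneous amplitudes, same shape as `x`.
#' @export
hilbert_envelope <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  T <- ncol(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[c(1, T / 2 + 1)] <- 1
    h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T + 1) / 2)] <- 2
  }
  X <- mvfft(t(x))                 # columns are neurons
  env <- Mod(mvfft(X * h, inverse = TRUE)) / T
  env <- t(env)
  if (vec) drop(env) else env
}
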