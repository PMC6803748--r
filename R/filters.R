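# Butterworth IIR band-pass design and second-order-section filtering.
#
# The recording chain this package models band-filters EEG with an 18th-order
# Butterworth IIR filter; no filter-design package is available at run time,
# so the design (analog prototype -> band-pass transform -> bilinear
# transform) is implemented here and realized as cascaded biquads for
# numerical stability.  Per-biquad recursion runs in C via stats::filter.

#' Butterworth band-pass filter specification
#'
#' Designs a digital Butterworth band-pass filter and returns it as cascaded
#' second-order sections (biquads).  `order` is the order of the final
#' band-pass filter (twice the low-pass prototype order), so `order = 18`
#' reproduces an "18th-order Butterworth band-pass" in the usual reporting
#' convention of EEG hardware.
#'
#' @param order Even filter order (>= 2) of the band-pass filter.
#' @param band_lo_hz,band_hi_hz Pass-band edges in Hz, `0 < lo < hi < fs/2`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `filter_spec`: list with `sos` (n x 5 matrix of
#'   `b1, b2, a0=1 implicit, a1, a2` stored as columns `b0 b1 b2 a1 a2`),
#'   per-section gain already folded into the numerators, and the design
#'   parameters.
#' @examples
#' fs <- filter_spec(18, 8, 30, 256)
#' f <- seq(1, 120, by = 1)
#' mag <- filter_gain(fs, f)
#' @export
filter_spec <- function(order, band_lo_hz, band_hi_hz, sample_rate_hz) {
  stopifnot(length(order) == 1L, order >= 2, order %% 2 == 0)
  if (!(band_lo_hz > 0 && band_lo_hz < band_hi_hz &&
        band_hi_hz < sample_rate_hz / 2))
    stop("require 0 < band_lo_hz < band_hi_hz < sample_rate_hz/2")
  n <- order %/% 2L                      # low-pass prototype order
  fs2 <- 2 * sample_rate_hz              # bilinear constant (T = 1/fs)

  # pre-warped analog edge frequencies
  w1 <- fs2 * tan(pi * band_lo_hz / sample_rate_hz)
  w2 <- fs2 * tan(pi * band_hi_hz / sample_rate_hz)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # low-pass -> band-pass: s <- (s^2 + w0^2) / (bw * s); each prototype pole
  # yields two band-pass poles (roots of s^2 - p*bw*s + w0^2)
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2 + 0i)
  p_bp <- c(pb + disc, pb - disc)

  # bilinear transform to the z-plane
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  if (any(Mod(z_p) >= 1 - 1e-10))
    stop("unstable filter design (pole on/outside unit circle); ",
         "reduce order or widen the band")

  # pair each pole with its conjugate into biquad denominators
  cplx <- z_p[Im(z_p) > 1e-9]
  realp <- sort(Re(z_p[abs(Im(z_p)) <= 1e-9]))
  sections <- vector("list", n)
  s <- 1L
  for (p in cplx) {
    sections[[s]] <- c(-2 * Re(p), Mod(p)^2)   # a1, a2
    s <- s + 1L
  }
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[2]; realp <- realp[-(1:2)]
    sections[[s]] <- c(-(p1 + p2), p1 * p2)
    s <- s + 1L
  }
  if (s != n + 1L) stop("internal error: pole pairing failed")

  # numerator: n zeros at z = 1 and n at z = -1 -> (1 - z^-2) per section
  sos <- t(vapply(sections, function(a) c(1, 0, -1, a[1], a[2]),
                  numeric(5)))

  spec <- structure(
    list(sos = sos, order = as.integer(order),
         band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
         sample_rate_hz = sample_rate_hz),
    class = "filter_spec")

  # unity gain at the (digital) geometric center of the pass band
  fc <- sample_rate_hz / pi * atan(w0 / fs2)
  g <- filter_gain(spec, fc)
  gs <- g^(-1 / n)                        # spread gain across sections
  spec$sos[, 1:3] <- spec$sos[, 1:3] * gs
  spec
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth band-pass: order %d, %.3g-%.3g Hz at %g Hz (%d biquads)\n",
              x$order, x$band_lo_hz, x$band_hi_hz, x$sample_rate_hz,
              nrow(x$sos)))
  invisible(x)
}

#' Magnitude response of a designed filter
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Frequencies (Hz) at which to evaluate `|H(f)|`.
#' @return Numeric vector of magnitudes.
#' @export
filter_gain <- function(spec, freq_hz) {
  w <- 2 * pi * freq_hz / spec$sample_rate_hz
  z1 <- exp(-1i * w)
  z2 <- z1 * z1
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(spec$sos))) {
    b <- spec$sos[s, 1:3]; a <- spec$sos[s, 4:5]
    h <- h * (b[1] + b[2] * z1 + b[3] * z2) / (1 + a[1] * z1 + a[2] * z2)
  }
  Mod(h)
}

# one biquad, zero initial state; FIR part vectorized, IIR part in C
.biquad <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  if (n > 1) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
  if (n > 2) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(v, -a, method = "recursive"))
}

#' Apply a filter causally (forward only)
#'
#' Direct cascaded-biquad filtering with zero initial conditions, as a
#' real-time system would run.  Group delay is not compensated.
#'
#' @param x Numeric signal.
#' @param spec A `filter_spec`.
#' @return Filtered signal, same length.
#' @export
sosfilt <- function(x, spec) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("input contains NA")
  y <- x
  for (s in seq_len(nrow(spec$sos)))
    y <- .biquad(y, spec$sos[s, 1:3], spec$sos[s, 4:5])
  if (!all(is.finite(y))) stop("filter produced non-finite output")
  y
}

#' Apply a filter with zero phase (forward-backward)
#'
#' Forward-backward filtering with odd-reflection padding at both ends to
#' suppress edge transients.  The effective magnitude response is |H|^2; the
#' phase is zero, so event latencies are preserved (used for offline ERD/ERS
#' curves).
#'
#' @inheritParams sosfilt
#' @param pad_len Padding length in samples (default `3 * order`, capped at
#'   `length(x) - 1`).
#' @return Filtered signal, same length.
#' @export
filtfilt_sos <- function(x, spec, pad_len = NULL) {
  n <- length(x)
  if (is.null(pad_len)) pad_len <- min(3L * spec$order * 2L, n - 1L)
  pre <- 2 * x[1] - x[seq(pad_len + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad_len)]
  xx <- c(pre, x, post)
  y <- sosfilt(xx, spec)
  y <- rev(sosfilt(rev(y), spec))
  y[seq(pad_len + 1, pad_len + n)]
}

#' Filter a trial array
#'
#' Applies a filter along the sample axis of a `trials x channels x samples`
#' array.
#'
#' @param data 3-d numeric array (trials x channels x samples).
#' @param spec A `filter_spec`.
#' @param mode `"zerophase"` (offline, latency-preserving) or `"causal"`
#'   (online simulation).
#' @return Array of the same shape.
#' @export
filter_array <- function(data, spec, mode = c("zerophase", "causal")) {
  mode <- match.arg(mode)
  f <- if (mode == "causal") sosfilt else filtfilt_sos
  out <- data
  for (tr in seq_len(dim(data)[1]))
    for (ch in seq_len(dim(data)[2]))
      out[tr, ch, ] <- f(data[tr, ch, ], spec)
  out
}
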