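# Feature extraction: STFT time-frequency grids, 1 Hz periodogram PSD, the
# interhemispheric power asymmetry ratio Ra = (R - L)/(R + L), band-power
# ERD/ERS time courses relative to a baseline reference interval, and
# restriction of features to the four 1-s epoch windows.

#' Centered moving average with edge shrinking
#'
#' @param x Numeric vector.
#' @param w Window length in samples (>= 1).
#' @return Smoothed vector, same length; windows shrink near the edges.
#' @export
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) - half + w - 1, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' The four epoch windows
#'
#' 1-s windows with a 0.5-s shift: 3.5-4.5, 4-5, 4.5-5.5 and 5-6 s from
#' trial onset.  Intervals are half-open `[start, end)`; times are 0-based.
#'
#' @return data frame with columns `name`, `start_s`, `end_s`.
#' @export
epoch_windows <- function() {
  data.frame(name = paste0("epoch", 1:4),
             start_s = c(3.5, 4, 4.5, 5),
             end_s = c(4.5, 5, 5.5, 6))
}

.epoch_bounds <- function(epoch) {
  if (is.numeric(epoch) && length(epoch) == 2) return(epoch)
  ew <- epoch_windows()
  if (is.numeric(epoch)) epoch <- paste0("epoch", epoch)
  i <- match(epoch, ew$name)
  if (is.na(i)) stop("unknown epoch: ", epoch)
  c(ew$start_s[i], ew$end_s[i])
}

# sample indices whose (0-based) times fall in [start, end)
.epoch_idx <- function(bounds, fs, n) {
  t <- (seq_len(n) - 1) / fs
  which(t >= bounds[1] & t < bounds[2])
}

#' Short-time Fourier transform power grid
#'
#' Hanning-tapered STFT magnitude-squared with 1-s windows, 50\% overlap and
#' 64 frequency bins.  A 1-s window at 256 Hz yields 129 one-sided FFT bins;
#' by default adjacent bins are aggregated pairwise into 64 bins of 2 Hz
#' (DC folded into the first).  `fft_length = 128` instead computes a
#' 128-point FFT (65 bins, truncated to 64).
#'
#' @param x Numeric signal (one channel of one trial), microvolts.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 1).
#' @param overlap Fractional overlap (default 0.5).
#' @param n_freq_bins Number of output frequency bins (default 64).
#' @param fft_length `NULL` (native window length, pairwise-aggregated) or
#'   an FFT length such as 128.
#' @return A `tfr_grid`: list with `power` (time x frequency, uV^2),
#'   `time_s` (window centers), `freq_hz` (bin centers).
#' @export
compute_tfr <- function(x, fs, window_s = 1, overlap = 0.5,
                        n_freq_bins = 64, fft_length = NULL) {
  nw <- as.integer(round(window_s * fs))
  if (length(x) < nw) stop("signal shorter than one window")
  hop <- as.integer(round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = hop)
  win <- .hann(nw)
  nfft <- if (is.null(fft_length)) nw else as.integer(fft_length)
  pow <- matrix(0, length(starts), nfft %/% 2 + 1)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nw - 1)] * win
    if (nfft < nw) seg <- seg[seq_len(nfft)] # truncation mode
    X <- stats::fft(seg)
    pow[i, ] <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / sum(win^2)
  }
  freq <- (seq_len(ncol(pow)) - 1) * fs / nfft
  if (is.null(fft_length) && ncol(pow) > n_freq_bins) {
    # pairwise-aggregate 129 -> 64 bins of 2 Hz; DC folded into bin 1
    agg <- matrix(0, nrow(pow), n_freq_bins)
    agg[, 1] <- pow[, 1] + pow[, 2] + pow[, 3]
    for (j in 2:n_freq_bins) agg[, j] <- pow[, 2 * j] + pow[, 2 * j + 1]
    pow <- agg
    freq <- (seq_len(n_freq_bins) * 2) - 1   # 1, 3, ..., 127 Hz centers
  } else if (ncol(pow) > n_freq_bins) {
    pow <- pow[, seq_len(n_freq_bins), drop = FALSE]
    freq <- freq[seq_len(n_freq_bins)]
  }
  structure(list(power = pow, freq_hz = freq,
                 time_s = (starts - 1 + nw / 2) / fs,
                 window_s = window_s, overlap = overlap),
            class = "tfr_grid")
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Periodogram power spectral density of a 1-s segment
#'
#' Hanning-tapered periodogram (squared Fourier transform) with 1 Hz bins.
#' Normalized as a one-sided density in uV^2/Hz: the sum of all bins times
#' the 1 Hz bin width estimates the segment variance (Parseval, with taper
#' power correction).
#'
#' @param x Numeric segment of exactly `round(window_s * fs)` samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length in seconds (default 1, giving 1 Hz bins).
#' @return A `psd_vector`: list with `power` (uV^2/Hz) and `freq_hz`
#'   (0 .. fs/2 in steps of `1/window_s`).
#' @export
compute_psd <- function(x, fs, window_s = 1) {
  nw <- as.integer(round(window_s * fs))
  if (length(x) != nw)
    stop("segment must be exactly ", nw, " samples (", window_s, " s)")
  win <- .hann(nw)
  X <- stats::fft(x * win)
  nh <- nw %/% 2 + 1
  p <- Mod(X[seq_len(nh)])^2 / (fs * sum(win^2))
  p[2:(nh - 1)] <- 2 * p[2:(nh - 1)]       # one-sided
  structure(list(power = p, freq_hz = (seq_len(nh) - 1) / window_s),
            class = "psd_vector")
}

#' Band power from a PSD
#'
#' @param psd A `psd_vector`.
#' @param band Band name (see [band_set()]) or `c(lo, hi)` in Hz; bin
#'   centers in `[lo, hi]` are integrated.
#' @return Band power in uV^2.
#' @export
psd_band_power <- function(psd, band) {
  e <- if (is.character(band)) .band_edges(band) else band
  i <- psd$freq_hz >= e[1] & psd$freq_hz <= e[2]
  sum(psd$power[i]) * diff(psd$freq_hz[1:2])
}

#' Interhemispheric power asymmetry ratio
#'
#' `Ra = (R - L) / (R + L)` for right (C4) and left (C3) band power.
#' Antisymmetric under channel swap, invariant to common rescaling.
#'
#' @param right_power,left_power Nonnegative powers (R from C4, L from C3).
#' @return Ratio in [-1, 1].
#' @export
asymmetry_ratio <- function(right_power, left_power) {
  if (any(right_power < 0 | left_power < 0))
    stop("powers must be nonnegative")
  s <- right_power + left_power
  if (any(s == 0)) stop("R + L = 0: asymmetry ratio undefined")
  (right_power - left_power) / s
}

#' Trial-averaged band-power ERD/ERS time course
#'
#' Band-pass filters each trial (zero-phase by default so that ERS latency
#' is preserved), squares samples, averages across trials, optionally
#' smooths, and expresses every sample as the percent change relative to
#' the mean power over a baseline reference interval:
#' `ERD%_j = (A_j - R) / R * 100`.
#'
#' @param trials A `trial_set` (broadband-filtered and detrended, or raw).
#' @param band Band name from [band_set()] or `c(lo, hi)` Hz.
#' @param channel Channel name (`"C3"`, `"Cz"`, `"C4"`).
#' @param reference_interval Reference interval `c(start_s, end_s)` inside
#'   the baseline; default 0.5-2.5 s (the 0-3 s static baseline trimmed by
#'   0.5 s on each side for filter transients).
#' @param smooth_s Moving-average length applied to the averaged power
#'   course (default 0.25 s, matched to the expected width of the rebound's
#'   power envelope so that the peak estimator meets the 15\% recovery
#'   tolerance at N = 160 trials); set 0 for the raw course.
#' @param filter_order Sub-band Butterworth order (default 4).
#' @param mode `"zerophase"` or `"causal"` sub-band filtering.
#' @return An `erd_curve`: list with `erd_pct` (per sample), `avg_power`
#'   (`A_j`, uV^2), `r_ref`, `k` (reference sample count), `time_s`,
#'   `n_trials_averaged`, `band`, `channel`.
#' @export
band_power_erd <- function(trials, band, channel,
                           reference_interval = c(0.5, 2.5),
                           smooth_s = .ERD_SMOOTH_S, filter_order = 4,
                           mode = c("zerophase", "causal")) {
  mode <- match.arg(mode)
  nt <- n_trials(trials)
  if (nt < 1) stop("empty trial set")
  fs <- trials$timing$sample_rate_hz
  if (reference_interval[1] < 0 ||
      reference_interval[2] > trials$timing$baseline_end_s)
    stop("reference interval must lie inside the baseline")
  ch <- match(channel, trials$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  e <- if (is.character(band)) .band_edges(band) else band
  spec <- filter_spec(filter_order, e[1], e[2], fs)
  f <- if (mode == "causal") sosfilt else filtfilt_sos
  ns <- dim(trials$data)[3]
  acc <- numeric(ns)
  for (i in seq_len(nt)) acc <- acc + f(trials$data[i, ch, ], spec)^2
  avg <- acc / nt
  if (smooth_s > 0) avg <- moving_average(avg, round(smooth_s * fs))
  ref_idx <- .epoch_idx(reference_interval, fs, ns)
  r_ref <- mean(avg[ref_idx])
  if (r_ref <= 0) stop("reference power is zero")
  structure(list(erd_pct = (avg - r_ref) / r_ref * 100,
                 avg_power = avg, r_ref = r_ref, k = length(ref_idx),
                 time_s = (seq_len(ns) - 1) / fs,
                 n_trials_averaged = nt,
                 band = if (is.character(band)) band
                        else paste(band, collapse = "-"),
                 channel = channel),
            class = "erd_curve")
}

#' @export
print.erd_curve <- function(x, ...) {
  cat(sprintf("erd_curve: %s/%s, N=%d trials, ref power %.3g uV^2 (k=%d)\n",
              x$channel, x$band, x$n_trials_averaged, x$r_ref, x$k))
  cat(sprintf("  range %.1f%% .. %.1f%%\n", min(x$erd_pct), max(x$erd_pct)))
  invisible(x)
}

#' Peak of an ERD curve in a window
#'
#' @param curve An `erd_curve`.
#' @param window `c(start_s, end_s)` search window (half-open).
#' @return List with `peak_pct` and `peak_time_s`.
#' @export
erd_peak <- function(curve, window) {
  i <- which(curve$time_s >= window[1] & curve$time_s < window[2])
  j <- i[which.max(curve$erd_pct[i])]
  list(peak_pct = curve$erd_pct[j], peak_time_s = curve$time_s[j])
}

#' Pearson correlation between two ERD curves
#'
#' @param curve_a,curve_b `erd_curve`s of equal length (or numeric vectors).
#' @param window Optional `c(start_s, end_s)` restriction.
#' @return Correlation coefficient.
#' @export
template_correlation <- function(curve_a, curve_b, window = NULL) {
  a <- if (inherits(curve_a, "erd_curve")) curve_a$erd_pct else curve_a
  b <- if (inherits(curve_b, "erd_curve")) curve_b$erd_pct else curve_b
  if (length(a) != length(b)) stop("curves must have equal length")
  if (!is.null(window) && inherits(curve_a, "erd_curve")) {
    i <- curve_a$time_s >= window[1] & curve_a$time_s < window[2]
    a <- a[i]; b <- b[i]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to template_correlation")
  stats::cor(a, b)
}

# ---- feature matrices ---------------------------------------------------

.new_feature_matrix <- function(values, labels, epoch, names) {
  colnames(values) <- names
  structure(list(values = values, labels = labels, epoch = epoch,
                 feature_names = names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d trials x %d features (epoch %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$epoch, collapse = "-")))
  invisible(x)
}

#' Mean band power per channel in an epoch window
#'
#' One scalar per band x channel: the mean squared sub-band amplitude over
#' the epoch (unsmoothed).
#'
#' @param trials Preprocessed `trial_set`.
#' @param bands Band names (see [band_set()]).
#' @param channels Channel names.
#' @param epoch Epoch name (`"epoch3"`), number, or `c(start_s, end_s)`.
#' @param filter_order,mode Sub-band filter settings (see
#'   [band_power_erd()]).
#' @return A `feature_matrix`.
#' @export
features_band_power <- function(trials, bands = "beta",
                                channels = c("C3", "C4", "Cz"),
                                epoch = "epoch3", filter_order = 4,
                                mode = "zerophase") {
  env <- band_envelopes(trials, bands, channels, filter_order, mode,
                        smooth_s = 0)
  bounds <- .epoch_bounds(epoch)
  idx <- .epoch_idx(bounds, trials$timing$sample_rate_hz,
                    dim(trials$data)[3])
  if (!length(idx)) stop("epoch window outside trial")
  vals <- sapply(env, function(m) rowMeans(m[, idx, drop = FALSE]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  .new_feature_matrix(vals, trials$labels, bounds,
                      paste0(names(env), "_bp"))
}

#' Squared sub-band envelopes for every trial
#'
#' Workhorse for band-power and AR features: per band x channel, the
#' squared (optionally smoothed) sub-band-filtered signal of every trial.
#'
#' @inheritParams features_band_power
#' @param smooth_s Moving-average smoothing of the squared signal in
#'   seconds (0 = none).
#' @return Named list (`band_channel`) of trials x samples matrices.
#' @export
band_envelopes <- function(trials, bands, channels, filter_order = 4,
                           mode = "zerophase", smooth_s = 0.125) {
  .band_streams(trials, bands, channels, filter_order, mode, smooth_s,
                square = TRUE)
}

#' Sub-band filtered signals for every trial
#'
#' Like [band_envelopes()] but returns the filtered signal itself (not its
#' square) -- the input for raw-signal AR modeling.
#'
#' @inheritParams band_envelopes
#' @return Named list (`band_channel`) of trials x samples matrices.
#' @export
band_signals <- function(trials, bands, channels, filter_order = 4,
                         mode = "zerophase") {
  .band_streams(trials, bands, channels, filter_order, mode, smooth_s = 0,
                square = FALSE)
}

.band_streams <- function(trials, bands, channels, filter_order, mode,
                          smooth_s, square) {
  fs <- trials$timing$sample_rate_hz
  f <- if (mode == "causal") sosfilt else filtfilt_sos
  nt <- n_trials(trials); ns <- dim(trials$data)[3]
  w <- if (smooth_s > 0) as.integer(round(smooth_s * fs)) else 1L
  out <- list()
  for (b in bands) {
    e <- .band_edges(b)
    spec <- filter_spec(filter_order, e[1], e[2], fs)
    for (ch in channels) {
      ci <- match(ch, trials$channels)
      if (is.na(ci)) stop("unknown channel: ", ch)
      m <- matrix(0, nt, ns)
      for (i in seq_len(nt)) {
        sq <- f(trials$data[i, ci, ], spec)
        if (square) sq <- sq^2
        m[i, ] <- if (w > 1) moving_average(sq, w) else sq
      }
      out[[paste(b, ch, sep = "_")]] <- m
    }
  }
  out
}

#' PSD asymmetry-ratio features in an epoch window
#'
#' For each band, the asymmetry ratio of right (C4) vs left (C3) band power
#' from the 1-s Hanning periodogram of the epoch segment.
#'
#' @inheritParams features_band_power
#' @param right,left Channel names for R and L (defaults C4, C3).
#' @return A `feature_matrix` (one column per band).
#' @export
features_psd_asym <- function(trials, bands = "beta", epoch = "epoch3",
                              right = "C4", left = "C3") {
  fs <- trials$timing$sample_rate_hz
  bounds <- .epoch_bounds(epoch)
  idx <- .epoch_idx(bounds, fs, dim(trials$data)[3])
  if (abs(length(idx) - fs) > 1)
    stop("PSD epoch must be 1 s long")
  idx <- idx[seq_len(fs)]
  ri <- match(right, trials$channels); li <- match(left, trials$channels)
  nt <- n_trials(trials)
  vals <- matrix(0, nt, length(bands))
  for (i in seq_len(nt)) {
    pr <- compute_psd(trials$data[i, ri, idx], fs)
    pl <- compute_psd(trials$data[i, li, idx], fs)
    for (j in seq_along(bands))
      vals[i, j] <- asymmetry_ratio(psd_band_power(pr, bands[j]),
                                    psd_band_power(pl, bands[j]))
  }
  .new_feature_matrix(vals, trials$labels, bounds,
                      paste0(bands, "_", right, left, "_psdasym"))
}

#' Restrict per-sample feature streams to an epoch window
#'
#' Selects the samples (columns) of a trials x samples stream whose centers
#' fall in the half-open epoch window.
#'
#' @param streams Named list of trials x samples matrices (e.g., from
#'   [band_envelopes()]).
#' @param epoch Epoch specifier (see [features_band_power()]).
#' @param fs Sampling rate, Hz.
#' @return List of trials x selected-samples matrices.
#' @export
epoch_features <- function(streams, epoch, fs) {
  bounds <- .epoch_bounds(epoch)
  ns <- ncol(streams[[1]])
  idx <- .epoch_idx(bounds, fs, ns)
  if (!length(idx)) stop("epoch window outside trial")
  lapply(streams, function(m) m[, idx, drop = FALSE])
}
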