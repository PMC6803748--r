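# Cleaning and band filtering: 8-30 Hz broadband (18th-order Butterworth),
# 20 uV amplitude-based artifact rejection on the raw signal, linear
# detrending, and decomposition into the four analysis bands.
#
# Fixed pipeline order (logged in the result): broadband filter ->
# artifact rejection (on pre-filter amplitudes) -> detrend -> sub-band
# filter.

#' The four analysis frequency bands
#'
#' alpha 8-12, SMR 12-15, beta 16-24 and high beta 25-30 Hz.  The 15-16 Hz
#' gap between SMR and beta is reproduced as printed in the protocol the
#' package models, not "fixed".
#'
#' @return data frame with columns `band`, `lo_hz`, `hi_hz`.
#' @export
band_set <- function() {
  data.frame(band = c("alpha", "smr", "beta", "high_beta"),
             lo_hz = c(8, 12, 16, 25),
             hi_hz = c(12, 15, 24, 30))
}

.band_edges <- function(band) {
  bs <- band_set()
  i <- match(band, bs$band)
  if (is.na(i)) stop("unknown band: ", band,
                     " (expected one of ", paste(bs$band, collapse = ", "), ")")
  c(bs$lo_hz[i], bs$hi_hz[i])
}

#' Broadband 8-30 Hz filtering of a trial set
#'
#' @param trials A `trial_set`.
#' @param spec Optional [filter_spec()]; default 18th-order Butterworth
#'   8-30 Hz at the set's sampling rate.
#' @param mode `"zerophase"` for offline curves (no group delay),
#'   `"causal"` for the online simulator.
#' @return The trial set with filtered data; `$preproc` log updated.
#' @export
bandpass_filter <- function(trials, spec = NULL,
                            mode = c("zerophase", "causal")) {
  mode <- match.arg(mode)
  fs <- trials$timing$sample_rate_hz
  if (is.null(spec)) spec <- filter_spec(18, 8, 30, fs)
  if (dim(trials$data)[3] < 3 * spec$order)
    stop("trials too short for the filter's transient")
  trials$data <- filter_array(trials$data, spec, mode)
  trials$preproc <- c(trials$preproc,
                      sprintf("broadband %g-%g Hz order %d (%s)",
                              spec$band_lo_hz, spec$band_hi_hz, spec$order,
                              mode))
  trials
}

#' Sub-band decomposition
#'
#' One filtered copy of the data per analysis band (4th-order Butterworth;
#' the protocol specifies the 18th order only for the broadband stage).
#'
#' @param trials A `trial_set` (typically already broadband filtered).
#' @param bands Character vector of [band_set()] names.
#' @param order Butterworth order per band filter.
#' @inheritParams bandpass_filter
#' @return Named list of `trial_set`s, one per band, each tagged with
#'   `$band`.
#' @export
subband_filter <- function(trials, bands = band_set()$band, order = 4,
                           mode = c("zerophase", "causal")) {
  mode <- match.arg(mode)
  fs <- trials$timing$sample_rate_hz
  out <- lapply(bands, function(b) {
    e <- .band_edges(b)
    if (e[2] >= fs / 2) stop("band above Nyquist: ", b)
    ts <- trials
    ts$data <- filter_array(trials$data, filter_spec(order, e[1], e[2], fs),
                            mode)
    ts$band <- b
    ts$preproc <- c(ts$preproc, sprintf("subband %s (%s)", b, mode))
    ts
  })
  names(out) <- bands
  out
}

#' Amplitude-based artifact rejection
#'
#' Splits each trial into fixed segments (default 1 s) and flags segments in
#' which any channel's absolute raw amplitude exceeds the threshold
#' (default 20 uV above the recording's nominal clean range -- the rejection
#' is evaluated on the signal passed in, which should be the raw, pre-filter
#' data).  Trials with a flagged segment overlapping the analysis window
#' are dropped from feature extraction; sample values are never modified.
#'
#' @param trials A `trial_set` (raw amplitudes).
#' @param threshold_uv Rejection threshold in microvolts (> 0), default 20.
#' @param segment_s Segment length in seconds, default 1.
#' @param analysis_window Two-element vector of seconds; a trial is retained
#'   only if no flagged segment intersects it.  Default `c(3, 6)`.
#' @return A `clean_trial_set`: the input plus `mask` (trials x segments
#'   logical, TRUE = flagged), `retained` (trial indices kept) and a
#'   `rejection` summary data frame.
#' @export
reject_artifacts <- function(trials, threshold_uv = 20, segment_s = 1,
                             analysis_window = c(3, 6)) {
  stopifnot(threshold_uv > 0, segment_s > 0)
  fs <- trials$timing$sample_rate_hz
  ns <- dim(trials$data)[3]
  seg_len <- as.integer(round(segment_s * fs))
  n_seg <- ceiling(ns / seg_len)
  nt <- n_trials(trials)
  mask <- matrix(FALSE, nt, n_seg)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_len + 1):min(s * seg_len, ns)
    # max over channels and samples within the segment, per trial
    mx <- apply(abs(trials$data[, , idx, drop = FALSE]), 1, max)
    mask[, s] <- mx > threshold_uv
  }
  seg_start <- (seq_len(n_seg) - 1) * segment_s
  seg_end <- pmin(seg_start + segment_s, ns / fs)
  in_win <- seg_end > analysis_window[1] & seg_start < analysis_window[2]
  bad_trial <- rowSums(mask[, in_win, drop = FALSE]) > 0
  if (all(bad_trial))
    stop("all ", nt, " trials rejected at ", threshold_uv,
         " uV; max amplitudes range ",
         paste(round(range(apply(abs(trials$data), 1, max)), 1),
               collapse = "-"), " uV")
  out <- trials
  out$mask <- mask
  out$retained <- which(!bad_trial)
  out$rejection <- data.frame(threshold_uv = threshold_uv,
                              segment_s = segment_s,
                              n_trials = nt,
                              n_dropped = sum(bad_trial))
  out$preproc <- c(out$preproc,
                   sprintf("rejection >%g uV: dropped %d/%d trials",
                           threshold_uv, sum(bad_trial), nt))
  class(out) <- c("clean_trial_set", class(trials))
  out
}

#' Keep only retained (artifact-free) trials
#'
#' @param trials A `clean_trial_set` from [reject_artifacts()].
#' @return A `trial_set` containing only retained trials.
#' @export
retained_trials <- function(trials) {
  if (is.null(trials$retained)) return(trials)
  subset_trials(trials, trials$retained)
}

#' Remove per-trial, per-channel linear trends
#'
#' Least-squares straight-line fit subtracted from every channel of every
#' trial; output has (numerically) zero mean and zero linear trend.
#' Idempotent.
#'
#' @param trials A `trial_set`, or a numeric vector.
#' @return Same type as the input, detrended.
#' @export
detrend <- function(trials) {
  if (is.numeric(trials)) return(.detrend_vec(trials))
  for (tr in seq_len(dim(trials$data)[1]))
    for (ch in seq_len(dim(trials$data)[2]))
      trials$data[tr, ch, ] <- .detrend_vec(trials$data[tr, ch, ])
  trials$preproc <- c(trials$preproc, "detrend (linear)")
  trials
}

.detrend_vec <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2            # centered regressor
  x - mean(x) - t * sum(t * x) / sum(t * t)
}

#' Standard offline preprocessing chain
#'
#' Broadband filter, artifact rejection on raw amplitudes, retention
#' filtering, detrending -- in the fixed pipeline order.
#'
#' @param trials Raw `trial_set`.
#' @param mode Filtering mode, see [bandpass_filter()].
#' @param threshold_uv Rejection threshold (default 20 uV).
#' @return Preprocessed `trial_set` (retained trials only).
#' @export
preprocess <- function(trials, mode = c("zerophase", "causal"),
                       threshold_uv = 20) {
  mode <- match.arg(mode)
  clean <- reject_artifacts(trials, threshold_uv)
  kept <- retained_trials(clean)
  kept <- bandpass_filter(kept, mode = mode)
  detrend(kept)
}
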