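# Online neurofeedback simulation: class-specific band-power thresholds
# Th = MEAN + coefficient * STDEV derived from session-1 reference-interval
# statistics, a causal 8 Hz control signal (squared band-filtered EEG,
# block-averaged and smoothed with a 3-sample trailing moving average), a
# single decision read at second 5.5, and run-wise success bookkeeping.

#' Threshold from reference statistics
#'
#' `Th = MEAN + coefficient * STDEV`, exact arithmetic.
#'
#' @param mean_power Reference-interval mean power (MEAN).
#' @param stdev_power Reference-interval power standard deviation (>= 0).
#' @param coefficient Positive STDEV coefficient (default 6).
#' @param band,channel,class_direction Optional metadata tags.
#' @return A `threshold_spec` with field `Th`.
#' @export
compute_threshold <- function(mean_power, stdev_power, coefficient = 6,
                              band = NA, channel = NA,
                              class_direction = NA) {
  if (stdev_power < 0) stop("negative STDEV")
  if (coefficient <= 0) stop("coefficient must be > 0")
  structure(list(Th = mean_power + coefficient * stdev_power,
                 MEAN = mean_power, STDEV = stdev_power,
                 coefficient = coefficient, band = band, channel = channel,
                 class_direction = class_direction,
                 provenance = "session1"),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec: Th = %.4g = %.4g + %g x %.4g  [%s/%s -> %s]\n",
              x$Th, x$MEAN, x$coefficient, x$STDEV, x$channel, x$band,
              x$class_direction))
  invisible(x)
}

#' Causal 8 Hz control signal of one trial channel
#'
#' Causally band-filters the raw channel (broadband 8-30 Hz then the target
#' sub-band, both causal -- a real-time system cannot be acausal), squares,
#' block-averages to 8 Hz, and applies a 3-sample trailing moving average.
#' A 9-s trial at 256 Hz yields 72 control-signal samples; sample k covers
#' `[(k-1)/8, k/8)` seconds, so its trailing 3-sample window at k = 44 ends
#' exactly at second 5.5.
#'
#' @param x Raw single-channel signal (microvolts), or a `trial_set` with
#'   `trial` and `channel` given.
#' @param band Band name (see [band_set()]) or `c(lo, hi)` Hz.
#' @param fs Sampling rate, Hz (taken from the trial set if given).
#' @param trial,channel Trial index and channel name when `x` is a
#'   `trial_set`.
#' @param rate_hz Control-signal rate (default 8).
#' @param smooth_n Trailing moving-average length (default 3).
#' @param prefilter Apply the causal 18th-order 8-30 Hz broadband stage
#'   first (default TRUE).
#' @return A `control_signal`: numeric vector with attribute `time_s`
#'   (block end times).
#' @export
make_control_signal <- function(x, band, fs = NULL, trial = NULL,
                                channel = NULL, rate_hz = 8, smooth_n = 3,
                                prefilter = TRUE) {
  if (inherits(x, "trial_set")) {
    fs <- x$timing$sample_rate_hz
    ci <- match(channel, x$channels)
    if (is.na(ci)) stop("unknown channel: ", channel)
    x <- x$data[trial, ci, ]
  }
  if (is.null(fs)) stop("fs required for a bare signal")
  block <- as.integer(round(fs / rate_hz))
  if (length(x) < block) stop("trial shorter than one control-signal block")
  if (prefilter) x <- sosfilt(x, filter_spec(18, 8, 30, fs))
  e <- if (is.character(band)) .band_edges(band) else band
  x <- sosfilt(x, filter_spec(4, e[1], e[2], fs))
  nb <- length(x) %/% block
  p <- colMeans(matrix(x[seq_len(nb * block)]^2, nrow = block))
  cs <- moving_average_trailing(p, smooth_n)
  structure(cs, time_s = seq_len(nb) / rate_hz, class = "control_signal")
}

#' Trailing moving average
#'
#' @param x Numeric vector.
#' @param n Window length; windows shrink at the start.
#' @return Averaged vector of the same length.
#' @export
moving_average_trailing <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_along(x) - n + 1, 1)
  (cs[seq_along(x) + 1] - cs[lo]) / (seq_along(x) - lo + 1)
}

#' Session-1 control-signal reference statistics
#'
#' Pools the single-trial control-signal samples falling in the reference
#' interval across all session-1 trials of a channel and returns their mean
#' and standard deviation -- the MEAN and STDEV entering the threshold
#' equation.  Single-trial (not trial-averaged) statistics are used because
#' the threshold is applied online to single-trial control signals; see the
#' methods vignette.
#'
#' @param trials Session-1 `trial_set` (raw data).
#' @param band Band name or `c(lo, hi)`.
#' @param channel Channel name.
#' @param reference_interval Seconds, default 0.5-2.5.
#' @return List with `MEAN`, `STDEV`, `n`, plus the per-trial control
#'   signals (`cs`, trials x samples) for reuse.
#' @export
reference_cs_stats <- function(trials, band, channel,
                               reference_interval = c(0.5, 2.5)) {
  if (!identical(trials$session_id, "session1"))
    warning("threshold statistics should come from session-1 data")
  nt <- n_trials(trials)
  cs1 <- make_control_signal(trials, band, trial = 1, channel = channel)
  csm <- matrix(0, nt, length(cs1))
  csm[1, ] <- cs1
  if (nt > 1)
    for (i in 2:nt)
      csm[i, ] <- make_control_signal(trials, band, trial = i,
                                      channel = channel)
  tvec <- attr(cs1, "time_s")
  ref <- tvec > reference_interval[1] & tvec <= reference_interval[2]
  pool <- as.vector(csm[, ref])
  list(MEAN = mean(pool), STDEV = stats::sd(pool), n = length(pool),
       cs = csm, time_s = tvec)
}

#' Select the STDEV coefficient from session-1 class curves
#'
#' Generalizes the worked recipe of the study this package models: express
#' each class's peak control-signal excursion (trial-averaged, within one
#' second after imagery offset) in baseline-SD units; the threshold starts
#' one SD above the lower class's excursion and is pushed up to three SD
#' where feasible, but must stay at least three SD below the higher class's
#' peak.  With excursions of 2 and 9 SD this yields the coefficient 6
#' ("2 + 1 safety + 3").  If the two curves are inseparable (within 1 SD),
#' the default 6 is returned with `feasible = FALSE`.
#'
#' @param excursion_hi Peak excursion (in SD units) of the class the
#'   channel should detect.
#' @param excursion_lo Peak excursion of the other class on that channel.
#' @param default Fallback coefficient (default 6).
#' @return List with integer `coefficient` and logical `feasible`.
#' @export
select_stdev_coefficient <- function(excursion_hi, excursion_lo,
                                     default = 6) {
  if (!is.finite(excursion_hi) || !is.finite(excursion_lo) ||
      excursion_hi - excursion_lo <= 1)
    return(list(coefficient = default, feasible = FALSE))
  lo <- max(round(excursion_lo), 0)
  cand <- min(lo + 1 + 3, floor(excursion_hi - 3))
  if (cand < lo + 1)
    return(list(coefficient = default, feasible = FALSE))
  list(coefficient = as.integer(max(cand, lo + 1)), feasible = TRUE)
}

#' Derive the forward/backward threshold pair from session 1
#'
#' Computes reference MEAN/STDEV per control channel (C3 for forward, C4
#' for backward), measures each class's trial-averaged peak excursion after
#' imagery offset, selects the STDEV coefficient (`"auto"` recipe with
#' fallback 6, or a fixed number), and returns both `threshold_spec`s.
#'
#' @param session1 Session-1 `trial_set` (raw).
#' @param band Band name or `c(lo, hi)` Hz (the subject's ERS band).
#' @param coefficient `"auto"` or a positive number.
#' @param reference_interval Seconds, default 0.5-2.5.
#' @param peak_window_s Post-offset search window length (default 1).
#' @return List with elements `forward` and `backward`
#'   (`threshold_spec`s), and the per-channel excursions.
#' @export
derive_thresholds <- function(session1, band, coefficient = "auto",
                              reference_interval = c(0.5, 2.5),
                              peak_window_s = 1) {
  off <- session1$timing$mi_offset_s
  out <- list()
  exc <- list()
  for (dir in c("forward", "backward")) {
    ch <- if (dir == "forward") "C3" else "C4"
    st <- reference_cs_stats(session1, band, ch, reference_interval)
    tsel <- st$time_s > off & st$time_s <= off + peak_window_s
    curve_own <- colMeans(st$cs[session1$labels == dir, , drop = FALSE])
    curve_other <- colMeans(st$cs[session1$labels != dir, , drop = FALSE])
    hi <- (max(curve_own[tsel]) - st$MEAN) / st$STDEV
    lo <- (max(curve_other[tsel]) - st$MEAN) / st$STDEV
    coef <- if (identical(coefficient, "auto"))
      select_stdev_coefficient(hi, lo)$coefficient
    else coefficient
    out[[dir]] <- compute_threshold(st$MEAN, st$STDEV, coef,
                                    band = if (is.character(band)) band
                                           else paste(band, collapse = "-"),
                                    channel = ch, class_direction = dir)
    exc[[dir]] <- c(hi = hi, lo = lo)
  }
  out$excursions <- exc
  out
}

#' Decide one trial from its two control signals
#'
#' Forward if only the C3 signal reaches its threshold at the decision
#' sample, backward if only C4 does, `none` if neither; if both cross, the
#' trial fails (`none`) -- the conservative tie rule for a case the
#' protocol leaves unspecified.
#'
#' @param cs_c3,cs_c4 `control_signal`s of the trial.
#' @param th_forward,th_backward `threshold_spec`s (C3/forward, C4/backward).
#' @param decision_time_s Decision read-out time (default 5.5).
#' @return Character: `"forward"`, `"backward"` or `"none"`.
#' @export
decide_trial <- function(cs_c3, cs_c4, th_forward, th_backward,
                         decision_time_s = 5.5) {
  if (is.null(th_forward$Th) || is.null(th_backward$Th))
    stop("missing threshold")
  tvec <- attr(cs_c3, "time_s")
  k <- which(abs(tvec - decision_time_s) < 1e-9)
  if (!length(k)) stop("decision time does not map to a control sample")
  f <- cs_c3[k] >= th_forward$Th
  b <- cs_c4[k] >= th_backward$Th
  if (f && !b) "forward" else if (b && !f) "backward" else "none"
}

#' Simulate the online loop over one run
#'
#' Builds both causal control signals for every trial, applies the decision
#' rule at second 5.5, and scores per-class success rates with all trials
#' of a class in the denominator (a `none` decision counts as failure).
#'
#' @param run `trial_set` of one session-2 run (raw data).
#' @param thresholds List from [derive_thresholds()] (session-1 only).
#' @param band Band name or edges used for the control signals.
#' @param decision_time_s Decision time (default 5.5).
#' @return A `run_outcome`: data frame `decisions` (trial, label, decision,
#'   correct, cs values), per-class and overall `success_pct`, `run_id`.
#' @export
simulate_run <- function(run, thresholds, band,
                         decision_time_s = 5.5) {
  nt <- n_trials(run)
  if (nt == 0) stop("empty run")
  if (!identical(thresholds$forward$provenance, "session1"))
    stop("thresholds must be derived from session-1 data")
  dec <- character(nt); c3v <- numeric(nt); c4v <- numeric(nt)
  for (i in seq_len(nt)) {
    cs3 <- make_control_signal(run, band, trial = i, channel = "C3")
    cs4 <- make_control_signal(run, band, trial = i, channel = "C4")
    dec[i] <- decide_trial(cs3, cs4, thresholds$forward,
                           thresholds$backward, decision_time_s)
    k <- which(abs(attr(cs3, "time_s") - decision_time_s) < 1e-9)
    c3v[i] <- cs3[k]; c4v[i] <- cs4[k]
  }
  decisions <- data.frame(trial = seq_len(nt),
                          label = as.character(run$labels),
                          decision = dec,
                          correct = dec == as.character(run$labels),
                          cs_c3 = c3v, cs_c4 = c4v)
  succ <- sapply(c("forward", "backward"), function(cl) {
    i <- decisions$label == cl
    if (!any(i)) NA_real_ else 100 * mean(decisions$correct[i])
  })
  structure(list(decisions = decisions, success_pct = succ,
                 overall_pct = 100 * mean(decisions$correct),
                 run_id = unique(run$run_id)),
            class = "run_outcome")
}

#' @export
print.run_outcome <- function(x, ...) {
  cat(sprintf("run_outcome (run %s): overall %.1f%% (forward %.1f%%, backward %.1f%%)\n",
              paste(x$run_id, collapse = ","), x$overall_pct,
              x$success_pct["forward"], x$success_pct["backward"]))
  invisible(x)
}

#' Simulate all runs of a session-2 set
#'
#' @param session2 Session-2 `trial_set` (raw).
#' @inheritParams simulate_run
#' @return List of `run_outcome`s (one per run) plus a `summary` data
#'   frame of success rates by run and class.
#' @export
simulate_session <- function(session2, thresholds, band,
                             decision_time_s = 5.5) {
  runs <- sort(unique(session2$run_id))
  outcomes <- lapply(runs, function(r)
    simulate_run(subset_trials(session2, session2$run_id == r),
                 thresholds, band, decision_time_s))
  names(outcomes) <- paste0("run", runs)
  summary <- do.call(rbind, lapply(outcomes, function(o)
    data.frame(run = o$run_id, forward = o$success_pct["forward"],
               backward = o$success_pct["backward"],
               overall = o$overall_pct, row.names = NULL)))
  list(outcomes = outcomes, summary = summary)
}

#' Learning-curve statistics across subjects
#'
#' Per-run, per-class mean and SD of success rates across subjects, and the
#' paired t statistic between the two classes within each run (direct
#' implementation of the standard paired formula).
#'
#' @param rates Array `subjects x runs x class(forward, backward)` of
#'   success percentages (or a list of per-subject `summary` frames from
#'   [simulate_session()]).
#' @return List with `mean` and `sd` (runs x class) and `paired_t` per run
#'   (NA with a single subject).
#' @export
learning_stats <- function(rates) {
  if (is.list(rates) && !is.array(rates)) {
    rates <- simplify2array(lapply(rates, function(s)
      as.matrix(s[, c("forward", "backward")])))
    rates <- aperm(rates, c(3, 1, 2))
  }
  ns <- dim(rates)[1]; nr <- dim(rates)[2]
  mn <- apply(rates, c(2, 3), mean)
  sdv <- apply(rates, c(2, 3), stats::sd)
  paired_t <- rep(NA_real_, nr)
  if (ns >= 2) {
    for (r in seq_len(nr)) {
      d <- rates[, r, 1] - rates[, r, 2]
      sd_d <- stats::sd(d)
      paired_t[r] <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(ns))
    }
  }
  dimnames(mn) <- dimnames(sdv) <-
    list(paste0("run", seq_len(nr)), c("forward", "backward"))
  list(mean = mn, sd = sdv, paired_t = paired_t, n_subjects = ns)
}
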