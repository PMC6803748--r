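# End-to-end drivers: the per-subject offline BCI simulation (train on
# session 1, test on session 2), the per-subject neurofeedback simulation,
# and the multi-subject pipeline producing the study-style report table
# (per-subject accuracy by method plus AV/STDEV rows).

.band_name <- function(profile) {
  if (profile$ers_band == "high_beta") "high_beta" else "beta"
}

# session-2 seed derived deterministically from the session-1 seed
.session2_seed <- function(seed) as.integer(seed + 5000L)

#' Offline BCI simulation for one virtual subject
#'
#' Generates session 1 and session 2 for the profile, preprocesses both
#' (zero-phase), extracts features in the subject's ERS band, trains the
#' requested classifier on session 1 and scores it on session 2 -- the
#' machine-learning analogue of running the trained model online.
#'
#' Feature sets: `"bp_ar"` (band-power envelope per channel modeled with
#' AR-Burg, AIC order in 2..30 chosen on session 1; the study's
#' classifier 2), `"bp_arx"` (same with ARX and both class templates),
#' `"bp"` (plain epoch band power), `"psd_asym"` (PSD asymmetry ratio
#' C4/C3; the study's classifier 1).
#'
#' @param profile A [subject_profile()].
#' @param seed Session-1 seed (session 2 uses a derived seed).
#' @param feature_set One of `"bp_ar"`, `"bp_arx"`, `"bp"`, `"psd_asym"`.
#' @param classifier `"linear_svm"` or `"diag_lda"`.
#' @param C SVM regularization (default the study optimum 1e-2).
#' @param epoch Epoch window (default `"epoch4"`, the window containing
#'   the post-imagery rebound in both sessions; see the methods vignette).
#' @param channels Channels used for band-power features.
#' @param orders AIC candidate orders.
#' @param n_trials Trials per session (default 320; smaller values scale
#'   the simulation down for quick checks).
#' @param cv Also run 10-fold CV on the session-1 features (default TRUE).
#' @return List with `accuracy_pct`, `cv1` (10-fold CV report on
#'   session 1, or NULL), `model`, `orders_used`, `n_test`.
#' @export
simulate_offline_bci <- function(profile, seed = 101,
                                 feature_set = c("bp_ar", "bp_arx", "bp",
                                                 "psd_asym"),
                                 classifier = c("linear_svm", "diag_lda"),
                                 C = 1e-2, epoch = "epoch4",
                                 channels = c("C3", "C4", "Cz"),
                                 orders = 2:30, n_trials = 320, cv = TRUE) {
  feature_set <- match.arg(feature_set)
  classifier <- match.arg(classifier)
  band <- .band_name(profile)
  s1 <- preprocess(generate_session(profile, n_trials, "session1", seed))
  s2 <- preprocess(generate_session(profile, n_trials, "session2",
                                    .session2_seed(seed)))
  fx <- function(ts, train = NULL)
    switch(feature_set,
           bp_ar = features_ar(ts, band, channels, epoch, "ar",
                               orders = orders, train = train),
           bp_arx = features_ar(ts, band, channels, epoch, "arx",
                                orders = orders, train = train),
           bp = features_band_power(ts, band, channels, epoch),
           psd_asym = features_psd_asym(ts, band, epoch))
  f1 <- fx(s1)
  f2 <- fx(s2, train = f1)
  model <- .train_one(f1, classifier, C)
  pred <- predict(model, f2)
  acc <- 100 * mean(pred == f2$labels)
  cv1 <- if (cv) cross_validate(f1, classifier, C = C, seed = seed)
  list(accuracy_pct = acc, cv1 = cv1, model = model,
       orders_used = f1$orders_used, n_test = length(f2$labels))
}

#' Neurofeedback simulation for one virtual subject
#'
#' Derives the forward/backward thresholds from session 1 (auto STDEV
#' coefficient, fallback 6) and replays session 2 through the online loop.
#'
#' @param profile A [subject_profile()].
#' @param seed Session-1 seed.
#' @param coefficient `"auto"` or a number (see [derive_thresholds()]).
#' @param skill_run If not `NULL` (e.g. 4), session 2 is generated with
#'   that run's skill multiplier applied to all runs -- the "after
#'   training" condition.
#' @param n_trials Trials per session (default 320).
#' @return List with `thresholds`, `session` (per-run outcomes + summary),
#'   `overall_pct`.
#' @export
simulate_neurofeedback <- function(profile, seed = 101,
                                   coefficient = "auto",
                                   skill_run = NULL, n_trials = 320) {
  band <- .band_name(profile)
  s1 <- generate_session(profile, n_trials, "session1", seed)
  p2 <- profile
  if (!is.null(skill_run))
    p2$skill_by_run <- matrix(rep(profile$skill_by_run[skill_run, ],
                                  each = 4), nrow = 4,
                              dimnames = dimnames(profile$skill_by_run))
  s2 <- generate_session(p2, n_trials, "session2", .session2_seed(seed))
  th <- derive_thresholds(s1, band, coefficient)
  sim <- simulate_session(s2, th, band)
  list(thresholds = th, session = sim,
       overall_pct = 100 * mean(unlist(lapply(sim$outcomes, function(o)
         o$decisions$correct))))
}

#' Pipeline configuration
#'
#' @param n_subjects Number of virtual subjects.
#' @param seeds Session-1 seeds, one per subject (default 101, 102, ...).
#' @param profiles List of [subject_profile()]s (default cohort).
#' @param feature_sets Named feature sets to evaluate offline.
#' @param classifiers Matching classifier kinds.
#' @param C SVM regularization.
#' @param epoch Epoch window.
#' @param coefficient Neurofeedback STDEV coefficient mode.
#' @param n_trials Trials per session per subject (default 320).
#' @param out_dir Optional directory for report artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 10, seeds = NULL, profiles = NULL,
                            feature_sets = c(psd_asym_lda = "psd_asym",
                                             bp_ar_svm = "bp_ar"),
                            classifiers = c(psd_asym_lda = "diag_lda",
                                            bp_ar_svm = "linear_svm"),
                            C = 1e-2, epoch = "epoch4",
                            coefficient = "auto", n_trials = 320,
                            out_dir = NULL) {
  if (is.null(seeds)) seeds <- 100L + seq_len(n_subjects)
  if (is.null(profiles)) profiles <- default_subject_profiles(n_subjects)
  stopifnot(length(seeds) == n_subjects, length(profiles) == n_subjects,
            identical(names(feature_sets), names(classifiers)))
  structure(list(n_subjects = n_subjects, seeds = as.integer(seeds),
                 profiles = profiles, feature_sets = feature_sets,
                 classifiers = classifiers, C = C, epoch = epoch,
                 coefficient = coefficient, n_trials = as.integer(n_trials),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the full multi-subject pipeline
#'
#' For every subject: offline BCI simulation per configured method and the
#' neurofeedback simulation; assembles the study-style report table
#' (per-subject rows plus AV and STDEV) and, if `out_dir` is set, writes
#' `report.csv` and `report.json` tagged with the config hash.
#'
#' @param config A [pipeline_config()].
#' @return List with `table` (data frame), `neurofeedback` (per-subject
#'   run summaries), `config_hash`, `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  methods <- names(config$feature_sets)
  rows <- vector("list", config$n_subjects)
  nf_sum <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    prof <- config$profiles[[i]]
    accs <- vapply(methods, function(m)
      simulate_offline_bci(prof, config$seeds[i],
                           feature_set = config$feature_sets[[m]],
                           classifier = config$classifiers[[m]],
                           C = config$C, epoch = config$epoch,
                           n_trials = config$n_trials,
                           cv = FALSE)$accuracy_pct,
      numeric(1))
    nf <- simulate_neurofeedback(prof, config$seeds[i],
                                 coefficient = config$coefficient,
                                 n_trials = config$n_trials)
    nf_sum[[i]] <- nf$session$summary
    rows[[i]] <- c(accs, neurofeedback = nf$overall_pct)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(subject = seq_len(config$n_subjects), tab)
  if (config$n_subjects > 1) {
    av <- c(subject = NA, colMeans(tab[, -1, drop = FALSE]))
    sdv <- c(subject = NA, apply(tab[, -1, drop = FALSE], 2, stats::sd))
    tab <- rbind(tab, AV = av, STDEV = sdv)
    rownames(tab) <- c(seq_len(config$n_subjects), "AV", "STDEV")
  }
  hash <- .config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$out_dir, "report.csv"))
    jsonlite::write_json(list(config_hash = hash, seeds = config$seeds,
                              table = tab),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(table = tab, neurofeedback = nf_sum, config_hash = hash,
       seeds = config$seeds)
}
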