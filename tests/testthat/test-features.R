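test_that("TFR grid: zeros, tone localization, shape", {
  g0 <- compute_tfr(numeric(512), 256)
  expect_true(all(g0$power == 0))
  expect_equal(ncol(g0$power), 64)
  expect_error(compute_tfr(numeric(100), 256), "shorter")
  t <- (0:2303) / 256
  g <- compute_tfr(sin(2 * pi * 10 * t), 256)
  # argmax frequency bin contains 10 Hz in every time window
  hit <- apply(g$power, 1, function(p) g$freq_hz[which.max(p)])
  expect_true(all(abs(hit - 10) <= 1))
  expect_equal(diff(g$time_s[1:2]), 0.5)       # 50% overlap of 1-s windows
})

test_that("periodogram PSD: zeros, Parseval, leakage", {
  expect_true(all(compute_psd(numeric(256), 256)$power == 0))
  expect_error(compute_psd(numeric(200), 256), "256")
  set.seed(2)
  tot <- replicate(500, {
    p <- compute_psd(rnorm(256), 256)
    sum(p$power) * 1                            # 1 Hz bins
  })
  expect_equal(mean(tot), 1, tolerance = 0.05)  # unit-variance white noise
  p26 <- compute_psd(sin(2 * pi * 26 * (0:255) / 256), 256)
  inband <- p26$freq_hz >= 25 & p26$freq_hz <= 27
  expect_gt(sum(p26$power[inband]) / sum(p26$power), 0.95)
})

test_that("asymmetry ratio: arithmetic, antisymmetry, gain invariance", {
  expect_equal(asymmetry_ratio(5, 5), 0)
  expect_equal(asymmetry_ratio(1, 0), 1)
  expect_equal(asymmetry_ratio(3, 1), 0.5)
  expect_error(asymmetry_ratio(0, 0), "undefined")
  expect_error(asymmetry_ratio(-1, 2), "nonnegative")
  set.seed(5)
  for (i in 1:20) {
    r <- runif(1, 0, 10); l <- runif(1, 0, 10); g <- runif(1, 0.1, 50)
    expect_equal(asymmetry_ratio(r, l), -asymmetry_ratio(l, r))
    expect_equal(asymmetry_ratio(g * r, g * l), asymmetry_ratio(r, l))
    expect_lte(abs(asymmetry_ratio(r, l)), 1)
  }
})

test_that("ERD curve satisfies the defining identity and averaging invariance", {
  s <- cached_session1()
  curve <- band_power_erd(s, "high_beta", "C4")
  expect_equal(curve$erd_pct,
               (curve$avg_power - curve$r_ref) / curve$r_ref * 100)
  expect_gte(min(curve$erd_pct), -100)
  expect_equal(curve$k, length(bcinav:::.epoch_idx(c(0.5, 2.5), 256, 2304)))
  i <- curve$time_s >= 0.5 & curve$time_s < 2.5
  expect_lt(abs(mean(curve$erd_pct[i])), 1e-8)  # zero over the reference
  # N identical trials give the single-trial curve
  one <- subset_trials(s, 1)
  rep5 <- one
  rep5$data <- array(rep(one$data, each = 5),
                     c(5, 3, dim(one$data)[3]))[, , , drop = FALSE]
  for (k in 1:5) rep5$data[k, , ] <- one$data[1, , ]
  rep5$labels <- rep(one$labels, 5)
  rep5$run_id <- rep(1L, 5)
  c1 <- band_power_erd(one, "beta", "C3")
  c5 <- band_power_erd(rep5, "beta", "C3")
  expect_equal(c5$erd_pct, c1$erd_pct, tolerance = 1e-10)
  expect_equal(c5$n_trials_averaged, 5)
})

test_that("ERD amplitude steps recover the defining percentages", {
  # carrier with a 3x power step: Eq. fixed points 0 / 200%
  tm <- paradigm_timing()
  n <- tm$n_samples
  set.seed(21)
  step <- ifelse((seq_len(n) - 1) / 256 >= 5, sqrt(3), 1)
  dat <- array(0, c(30, 3, n))
  for (i in 1:30)
    dat[i, , ] <- rep(bcinav:::.band_noise(n, 256, 25, 30) * step, each = 3)
  ts <- make_ts(dat, rep(c("forward", "backward"), 15))
  curve <- band_power_erd(ts, "high_beta", "C3")
  i <- curve$time_s > 5.6 & curve$time_s < 8.5
  expect_equal(mean(curve$erd_pct[i]), 200, tolerance = 0.15 * 200)
})

test_that("template correlation behaves at its fixed points", {
  s <- cached_session1()
  a <- band_power_erd(subset_trials(s, s$labels == "forward"),
                      "high_beta", "C3")
  b <- band_power_erd(subset_trials(s, s$labels == "backward"),
                      "high_beta", "C4")
  expect_equal(template_correlation(a, a), 1)
  neg <- a; neg$erd_pct <- -a$erd_pct
  expect_equal(template_correlation(a, neg), -1)
  flat <- a; flat$erd_pct <- rep(0, length(a$erd_pct))
  expect_error(template_correlation(a, flat), "variance")
  expect_lt(abs(template_correlation(a, b, window = c(0.5, 2.5))), 0.6)
})

test_that("epoch windows and feature epoching follow the printed bounds", {
  ew <- epoch_windows()
  expect_equal(ew$start_s, c(3.5, 4, 4.5, 5))
  expect_equal(ew$end_s, c(4.5, 5, 5.5, 6))
  streams <- list(a = matrix(0, 2, 2304))
  streams$a[, round(5.25 * 256) + 1] <- 1       # impulse at 5.25 s
  expect_equal(ncol(epoch_features(streams, "epoch3", 256)$a), 256)
  expect_equal(sum(epoch_features(streams, "epoch2", 256)$a), 0)
  expect_equal(sum(epoch_features(streams, "epoch3", 256)$a), 2)
  expect_equal(sum(epoch_features(streams, "epoch4", 256)$a), 2)
  expect_error(epoch_features(streams, c(10, 11), 256), "outside")
})

test_that("feature matrices are finite with matching labels", {
  s <- cached_session1()
  fb <- features_band_power(s, c("beta", "high_beta"), c("C3", "C4"),
                            "epoch3")
  expect_equal(dim(fb$values), c(n_trials(s), 4))
  expect_true(all(is.finite(fb$values)))
  fa <- features_psd_asym(s, c("beta", "high_beta"), "epoch3")
  expect_true(all(abs(fa$values) <= 1))
  expect_identical(fa$labels, s$labels)
})
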