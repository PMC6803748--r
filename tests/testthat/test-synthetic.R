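test_that("paradigm timing encodes both session conventions", {
  t1 <- paradigm_timing("session1")
  t2 <- paradigm_timing("session2")
  expect_equal(t1$mi_offset_s, 5.5)
  expect_equal(t2$mi_offset_s, 5.0)
  expect_equal(t1$n_samples, 2304)
  expect_error(paradigm_timing(mi_offset_s = 4.2), "mi_offset")
  expect_error(paradigm_timing(sample_rate_hz = 100.5), "integer")
})

test_that("sessions are balanced, blocked into 4 runs, and deterministic", {
  prof <- subject_profile(artifact_rate = 0)
  s <- generate_session(prof, 8, "session1", seed = 5)
  expect_equal(as.integer(table(s$labels)), c(4L, 4L))
  expect_equal(as.integer(table(s$run_id)), rep(2L, 4))
  s2 <- generate_session(prof, 8, "session1", seed = 5)
  expect_identical(s$data, s2$data)
  expect_identical(s$labels, s2$labels)
  expect_false(identical(
    s$data, generate_session(prof, 8, "session1", seed = 6)$data))
  expect_error(generate_session(prof, 7), "even")
})

test_that("generate_trial validates its label", {
  expect_error(generate_trial(subject_profile(), paradigm_timing(), "up"),
               "unknown label")
})

test_that("a null profile yields a flat ERD time course", {
  prof <- subject_profile(forward_ers_pct = 0, backward_ers_pct = 0,
                          alpha_erd_fraction = 0, artifact_rate = 0)
  s <- generate_session(prof, 40, "session1", seed = 2)
  curve <- band_power_erd(s, "high_beta", "C4")
  # stationary pink noise: ERD% stays near 0 everywhere outside edges
  i <- curve$time_s > 0.5 & curve$time_s < 8.5
  expect_lt(max(abs(curve$erd_pct[i])), 60)
  expect_lt(abs(mean(curve$erd_pct[i])), 10)
})

test_that("without crosstalk the opposite channel carries no burst", {
  prof <- subject_profile(crosstalk = 0, artifact_rate = 0,
                          backward_ers_pct = 600)
  tm <- paradigm_timing("session1")
  set.seed(31)
  n <- 400
  sp <- filter_spec(4, 25, 30, 256)
  win <- bcinav:::.epoch_idx(c(5.6, 6.1), 256, tm$n_samples)
  ref <- bcinav:::.epoch_idx(c(0.5, 2.5), 256, tm$n_samples)
  pw <- replicate(n, {
    x <- generate_trial(prof, tm, "backward")
    f <- filtfilt_sos(x["C3", ], sp)
    c(mean(f[win]^2), mean(f[ref]^2))
  })
  # C3 burst-window band power equals its baseline power on average
  # (ratio of ensemble means -- a mean of per-trial ratios would carry a
  # Jensen inflation of ~2/dof)
  expect_equal(mean(pw[1, ]) / mean(pw[2, ]), 1, tolerance = 0.1)
})

test_that("class exchangeability: swapping class parameters swaps bursts", {
  a <- subject_profile(forward_ers_pct = 600, backward_ers_pct = 200,
                       forward_latency_s = 0.3, backward_latency_s = 0.2,
                       crosstalk = 0, artifact_rate = 0)
  b <- subject_profile(forward_ers_pct = 200, backward_ers_pct = 600,
                       forward_latency_s = 0.2, backward_latency_s = 0.3,
                       crosstalk = 0, artifact_rate = 0)
  tm <- paradigm_timing("session1")
  set.seed(77); xf <- generate_trial(a, tm, "forward")
  set.seed(77); xb <- generate_trial(b, tm, "backward")
  # identical backgrounds, and the identical burst lands on the class's
  # dominant channel (C3 forward / C4 backward)
  expect_equal(xf["Cz", ], xb["Cz", ])
  expect_equal(xf["C3", ] - xb["C3", ], xb["C4", ] - xf["C4", ])
  expect_gt(stats::sd(xf["C3", ] - xb["C3", ]), 0)
})

test_that("artifact injection follows its contract", {
  prof <- subject_profile(artifact_rate = 0)
  s <- cached_session1()
  expect_identical(inject_artifacts(s, 0), s)
  expect_error(inject_artifacts(s, 1, amplitude_uv = 15), "20")
  set.seed(4)
  si <- inject_artifacts(s, 0.5, 50)
  expect_gt(nrow(si$artifacts), 0)
  # every injected spike exceeds the 20 uV criterion at its position
  for (r in seq_len(nrow(si$artifacts))) {
    a <- si$artifacts[r, ]
    ch <- match(a$channel, si$channels)
    seg <- si$data[a$trial, ch, a$sample:(a$sample + 20)]
    expect_gt(max(abs(seg)), 20)
  }
})

test_that("injected artifact counts are Poisson with the requested rate", {
  tm <- paradigm_timing()
  set.seed(9)
  nt <- 1000
  ts <- make_ts(array(0, c(nt, 3, tm$n_samples)),
                rep(c("forward", "backward"), nt / 2))
  ts <- inject_artifacts(ts, 0.5, 50)
  n_inj <- nrow(ts$artifacts)
  expect_lt(abs(n_inj - 500), 3 * sqrt(500))
})

test_that("default cohort is 7 high-beta and 3 central-beta subjects", {
  profs <- default_subject_profiles(10)
  expect_equal(sum(vapply(profs, `[[`, "", "ers_band") == "high_beta"), 7)
  m <- default_skill_by_run()
  # learning-curve emulation: backward multipliers increase run 1 -> 4
  expect_true(all(diff(m[, "backward"]) > 0))
})
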