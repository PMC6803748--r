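test_that("threshold arithmetic is exact", {
  expect_identical(compute_threshold(0, 1, 6)$Th, 6)
  expect_identical(compute_threshold(10, 0, 6)$Th, 10)
  expect_identical(compute_threshold(2, 0.5, 6)$Th, 5)
  expect_error(compute_threshold(0, -1), "negative")
  expect_error(compute_threshold(0, 1, 0), "coefficient")
})

test_that("STDEV coefficient selection reproduces the worked recipe", {
  # excursions 2 and 9 SD -> 2 + 1 safety + 3 = 6
  expect_equal(select_stdev_coefficient(9, 2),
               list(coefficient = 6L, feasible = TRUE))
  # inseparable curves -> infeasible, default 6
  expect_equal(select_stdev_coefficient(3, 3),
               list(coefficient = 6, feasible = FALSE))
  expect_equal(select_stdev_coefficient(NA, 1)$feasible, FALSE)
  # threshold always sits between the two excursions when feasible
  set.seed(1)
  for (i in 1:50) {
    lo <- runif(1, 0, 4); hi <- lo + runif(1, 1.5, 12)
    s <- select_stdev_coefficient(hi, lo)
    if (s$feasible) {
      expect_gte(s$coefficient, lo)
      expect_lte(s$coefficient, hi)
    }
  }
})

test_that("control signal has the documented rate, value and timing", {
  fs <- 256
  t <- (0:(9 * fs - 1)) / fs
  x <- sqrt(2) * sin(2 * pi * 27.4 * t)        # unit power, center of band
  cs <- make_control_signal(x, "high_beta", fs = fs, prefilter = FALSE)
  expect_length(cs, 72)                        # 9 s at 8 Hz
  expect_equal(attr(cs, "time_s")[44], 5.5)    # decision sample
  expect_equal(mean(cs[20:70]), 1, tolerance = 0.05)
  expect_error(make_control_signal(x[1:10], "beta", fs = fs), "shorter")
})

test_that("trailing moving average uses only past samples", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(moving_average_trailing(x, 3), c(1, 1.5, 2, 3, 4))
})

test_that("decision rule covers all four cases at 5.5 s", {
  cs <- function(v) structure(rep(v, 72), time_s = (1:72) / 8,
                              class = "control_signal")
  thf <- compute_threshold(0, 1, 5)            # Th = 5
  thb <- compute_threshold(0, 1, 6)            # Th = 6
  expect_equal(decide_trial(cs(5.5), cs(1), thf, thb), "forward")
  expect_equal(decide_trial(cs(1), cs(7), thf, thb), "backward")
  expect_equal(decide_trial(cs(1), cs(1), thf, thb), "none")
  expect_equal(decide_trial(cs(9), cs(9), thf, thb), "none")  # tie rule
  expect_error(decide_trial(cs(1), cs(1), list(), thb), "threshold")
  expect_error(decide_trial(cs(1), cs(1), thf, thb, decision_time_s = 5.43),
               "decision time")
})

test_that("reference statistics pool single-trial control signals", {
  s <- cached_session1()
  st <- reference_cs_stats(s, "high_beta", "C4")
  expect_equal(nrow(st$cs), n_trials(s))
  expect_gt(st$STDEV, 0.3 * st$MEAN)  # single-trial variability, not N-avg
  expect_lt(st$STDEV, 2 * st$MEAN)
})

test_that("raising the coefficient never raises the false-positive rate", {
  s <- cached_session1()
  st3 <- reference_cs_stats(s, "high_beta", "C3")
  st4 <- reference_cs_stats(s, "high_beta", "C4")
  # baseline-only decision samples: use a pre-cue sample (t = 2.5 s) as a
  # stand-in decision point on null data
  k <- which(st3$time_s == 2.5)
  fp <- vapply(3:9, function(co) {
    th3 <- compute_threshold(st3$MEAN, st3$STDEV, co)
    th4 <- compute_threshold(st4$MEAN, st4$STDEV, co)
    mean(st3$cs[, k] >= th3$Th | st4$cs[, k] >= th4$Th)
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))
  expect_lt(fp[4], 0.05)                       # 6 SD: rare crossings
})

test_that("the simulated loop is driven by injected ERS strength", {
  # very strong, exactly lateralized ERS with a fixed coefficient: every
  # decision correct; no ERS: almost no crossings
  strong <- subject_profile(forward_ers_pct = 8000, backward_ers_pct = 8000,
                            forward_latency_s = 0.3,
                            backward_latency_s = 0.3,
                            crosstalk = 0, artifact_rate = 0,
                            skill_by_run = matrix(1, 4, 2))
  s1 <- generate_session(strong, 24, "session1", 41)
  th <- derive_thresholds(s1, "high_beta", coefficient = 6)
  s2 <- generate_session(strong, 24, "session2", 42)
  out <- simulate_run(s2, th, "high_beta")
  expect_gte(out$overall_pct, 95)
  null <- subject_profile(forward_ers_pct = 0, backward_ers_pct = 0,
                          artifact_rate = 0)
  s2n <- generate_session(null, 24, "session2", 43)
  outn <- simulate_run(s2n, th, "high_beta")
  expect_lte(outn$overall_pct, 10)
  expect_true(all(outn$decisions$decision %in%
                    c("none", "forward", "backward")))
})

test_that("thresholds must come from session 1", {
  s <- cached_session1()
  th <- derive_thresholds(s, "high_beta", 6)
  th$forward$provenance <- "session2"
  expect_error(simulate_run(s, th, "high_beta"), "session-1")
})

test_that("learning statistics: degenerate and hand-computed cases", {
  r <- array(70, c(3, 4, 2))
  ls <- learning_stats(r)
  expect_true(all(ls$sd == 0))
  expect_true(all(ls$paired_t == 0))           # equal class rates -> t = 0
  # hand-computed paired t on two subjects, one run:
  # d = (80-60, 70-66) = (20, 4); mean 12, sd 11.3137; t = 12/(11.3137/sqrt 2)
  r2 <- array(c(80, 70, 60, 66), c(2, 1, 2))
  t_hand <- 12 / (stats::sd(c(20, 4)) / sqrt(2))
  expect_equal(learning_stats(r2)$paired_t, t_hand)
  # single subject: means only
  expect_true(is.na(learning_stats(array(1, c(1, 4, 2)))$paired_t[1]))
})
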