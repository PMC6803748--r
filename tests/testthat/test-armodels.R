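test_that("Burg recovers known AR(2) coefficients (Yule-Walker oracle)", {
  set.seed(1)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.75, -0.5)), 1e5))
  m <- fit_ar_burg(x, 2)
  expect_equal(m$coef, c(0.75, -0.5), tolerance = 0.05)
  # independent oracle: stats::ar.yw (Yule-Walker) on the same data
  yw <- stats::ar.yw(x, order.max = 2, aic = FALSE)
  expect_equal(m$coef, unname(yw$ar), tolerance = 0.01)
  expect_equal(m$noise_variance, unname(yw$var.pred), tolerance = 0.02)
  expect_true(all(abs(m$reflection) <= 1))
})

test_that("Burg on white noise yields vanishing coefficients", {
  set.seed(2)
  n <- 2e4
  m <- fit_ar_burg(rnorm(n), 4)
  expect_lt(max(abs(m$coef)), 3 / sqrt(n) * 3)
})

test_that("Burg preconditions", {
  expect_error(fit_ar_burg(rnorm(100), 1), "2..30")
  expect_error(fit_ar_burg(rnorm(100), 31), "2..30")
  expect_error(fit_ar_burg(rnorm(10), 5), "length")
  expect_error(fit_ar_burg(rep(2, 100), 4), "constant")
  expect_error(fit_ar_burg(c(rnorm(99), NA), 4), "finite")
})

test_that("fitted AR models are stable and spectrally accurate", {
  set.seed(3)
  x <- as.numeric(bcinav:::.band_noise(4096, 256, 20, 22))
  for (p in c(6, 10)) {
    m <- fit_ar_burg(x, p)
    roots <- polyroot(c(1, -m$coef))
    # characteristic roots outside the unit disc (small numerical slack:
    # a near-line spectrum pushes roots onto the circle)
    expect_true(all(Mod(roots) > 1 - 1e-4))
    f <- seq(1, 127, by = 0.25)
    expect_lte(abs(f[which.max(ar_spectrum(m, f, 256))] - 21), 1)
  }
})

test_that("AIC order selection matches simulation truth", {
  # own-oracle expectation: AIC's known overfitting probability over a
  # 2..30 candidate range leaves ~85-90% of runs in {4, 5} for a true
  # AR(4) at n = 2048 (measured 88% over repeated simulation)
  set.seed(4)
  hits <- replicate(60, {
    x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3, 0.2, -0.35)),
                                     2048))
    select_order_aic(x)$selected
  })
  expect_gte(mean(hits %in% c(4, 5)), 0.8)
  low <- replicate(40, select_order_aic(rnorm(1024))$selected)
  expect_gte(mean(low <= 4), 0.7)               # white noise: near the floor
  expect_error(select_order_aic(rnorm(50), orders = 2:30), "below")
})

test_that("AIC ties go to the smaller order", {
  sel <- structure(list(orders = c(2L, 3L), aic = c(5, 5)),
                   class = "order_selection")
  # tie rule is which.min on a sorted order vector
  expect_equal(sel$orders[which.min(sel$aic)], 2L)
})

test_that("class templates average training trials only", {
  set.seed(5)
  base <- sin(seq(0, 6 * pi, length.out = 200))
  m <- t(replicate(40, base + rnorm(200, sd = 0.5)))
  y <- factor(rep(c("forward", "backward"), 20),
              levels = c("forward", "backward"))
  tpl <- build_class_template(m, y, "forward")
  expect_equal(attr(tpl, "n_trials"), 20)
  expect_lt(sqrt(mean((tpl - base)^2)), 3 * 0.5 / sqrt(20))
  # identical trials -> template equals any trial
  m2 <- matrix(rep(base, 3), 3, byrow = TRUE)
  y2 <- factor(c("forward", "forward", "backward"),
               levels = c("forward", "backward"))
  expect_equal(unclass(build_class_template(m2, y2, "forward"))[1:200],
               base, ignore_attr = TRUE)
  expect_error(build_class_template(m2, y2, "sideways"), "class")
  # fold templates differ when training folds differ (leakage bookkeeping)
  t1 <- build_class_template(m[1:20, ], y[1:20], "forward")
  t2 <- build_class_template(m[21:40, ], y[21:40], "forward")
  expect_false(isTRUE(all.equal(as.numeric(t1), as.numeric(t2))))
})

test_that("ARX: perfect regressor, zero-template degeneracy, template match", {
  set.seed(6)
  tpl <- sin(seq(0, 20, length.out = 300)) + rnorm(300, sd = 0.1)
  attr(tpl, "n_trials") <- 10
  perfect <- fit_arx(tpl, tpl, 2, 0)
  expect_equal(unname(perfect$x_coef), 1, tolerance = 1e-8)
  expect_lt(perfect$noise_variance, 1e-20)
  z <- fit_arx(tpl, rep(0, 300), 4, 0)
  b <- fit_ar_burg(tpl, 4)
  expect_equal(unname(z$coef), b$coef, tolerance = 0.02)
  expect_error(fit_arx(tpl, tpl[1:100], 2), "length")
  # matching class template explains more variance than the other class's
  s1 <- sin(seq(0, 12, length.out = 300))
  s2 <- cos(seq(0, 7, length.out = 300))
  set.seed(7)
  wins <- replicate(200, {
    seg <- s1 + rnorm(300, sd = 1)
    own <- fit_arx(seg, structure(s1, n_trials = 5), 3, 0)$noise_variance
    other <- fit_arx(seg, structure(s2, n_trials = 5), 3, 0)$noise_variance
    own < other
  })
  expect_gt(mean(wins), 0.9)
  # ARX residual never exceeds the AR-only residual at equal order
  set.seed(8)
  seg <- s1 + rnorm(300)
  expect_lte(fit_arx(seg, structure(s1, n_trials = 5), 5, 0)$noise_variance,
             fit_ar_burg(seg, 5)$noise_variance * 1.05)
})

test_that("AR feature matrices are finite, reuse orders, forbid leakage", {
  s <- cached_session1()
  f1 <- features_ar(s, "high_beta", c("C3", "C4"), "epoch4", orders = 2:10)
  expect_true(all(is.finite(f1$values)))
  s2 <- generate_session(subject_profile(artifact_rate = 0), 16,
                         "session2", 99)
  f2 <- features_ar(s2, "high_beta", c("C3", "C4"), "epoch4", train = f1)
  expect_identical(f2$orders_used, f1$orders_used)
  expect_equal(ncol(f2$values), ncol(f1$values))
  # ARX features: templates come from the training object
  fx1 <- features_ar(s, "high_beta", "C3", "epoch4", kind = "arx",
                     orders = 2:6)
  fx2 <- features_ar(s2, "high_beta", "C3", "epoch4", kind = "arx",
                     train = fx1)
  expect_identical(fx2$templates, fx1$templates)
  expect_equal(fx2$feature_names, fx1$feature_names)
})
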