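sep_fm <- function(n = 100, gap = 5, d = 2, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d, gap), n), matrix(rnorm(n * d, -gap), n))
  make_fm(x, factor(rep(c("forward", "backward"), each = n),
                    levels = c("forward", "backward")))
}

test_that("diagonal LDA separates well-separated Gaussians", {
  fm <- sep_fm()
  expect_gte(cross_validate(fm, "diag_lda", seed = 1)$mean_accuracy, 0.99)
  # chance level on exchangeable classes
  set.seed(8)
  fm0 <- make_fm(matrix(rnorm(400), 200), fm$labels)
  acc <- cross_validate(fm0, "diag_lda", seed = 1)$mean_accuracy
  expect_lt(abs(acc - 0.5), 2 * sqrt(0.25 / 200) * 2 + 0.05)
  expect_error(train_diag_lda(make_fm(matrix(rnorm(10), 5),
                                      factor(rep("forward", 5),
                                             levels = c("forward",
                                                        "backward")))),
               "two classes")
})

test_that("diagonal LDA equals the closed-form Gaussian discriminant", {
  set.seed(9)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 1.2), n), matrix(rnorm(n * 2, -0.7), n))
  y <- factor(rep(c("forward", "backward"), each = n),
              levels = c("forward", "backward"))
  fm <- make_fm(x, y)
  model <- train_diag_lda(fm, zscore = FALSE)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.25), seq(-3, 3, 0.25)))
  colnames(grid) <- fm$feature_names
  pred <- predict(model, grid)
  # brute-force posterior comparison with the same mu/var/prior estimates
  mu1 <- colMeans(x[y == "forward", ]); mu2 <- colMeans(x[y == "backward", ])
  cen <- x - rbind(matrix(mu1, n, 2, byrow = TRUE),
                   matrix(mu2, n, 2, byrow = TRUE))
  v <- colSums(cen^2) / (2 * n - 2)
  ll1 <- -colSums((t(grid) - mu1)^2 / v) / 2
  ll2 <- -colSums((t(grid) - mu2)^2 / v) / 2
  oracle <- ifelse(ll1 >= ll2, "forward", "backward")
  expect_equal(as.character(pred), oracle)
})

test_that("linear SVM: separation, small-C limit, convergence diagnostics", {
  fm <- sep_fm(gap = 3)
  m <- train_linear_svm(fm, C = 10)
  expect_true(m$converged)
  expect_equal(mean(predict(m, fm) == fm$labels), 1)   # zero training errors
  m0 <- train_linear_svm(fm, C = 1e-9)
  expect_lt(sqrt(sum(m0$w^2)), 1e-5)                   # weights vanish
  expect_error(train_linear_svm(fm, C = -1))
  expect_error(train_linear_svm(sep_fm(n = 40, gap = 0.1), C = 100,
                                max_pass = 2),
               "converge")
})

test_that("linear SVM matches the exact QP on a 6-point set", {
  x <- matrix(c(1, 1,  2, 0.5,  1.6, 2.2,
                -1, -0.8,  -2, 0.2,  -1.2, -2), 6, 2, byrow = TRUE)
  y <- c(1, 1, 1, -1, -1, -1)
  oracle <- qp_svm_oracle(x, y)
  fm <- make_fm(x, factor(ifelse(y == 1, "forward", "backward"),
                          levels = c("forward", "backward")))
  m <- train_linear_svm(fm, C = 1e4, zscore = FALSE, tol = 1e-6,
                        max_pass = 1e5)
  # identical support set; weights agree up to the O(b^2) perturbation of
  # the regularized-bias formulation
  sv <- which(m$alpha > 1e-6 * max(m$alpha))
  expect_setequal(sv, oracle$sv)
  expect_equal(m$w, oracle$w, tolerance = 0.01)
  expect_equal(m$b, oracle$b, tolerance = 0.02)
})

test_that("cross-validation partitions trials exactly once, reproducibly", {
  fm <- sep_fm(n = 160)                       # 320 trials
  cv <- cross_validate(fm, "diag_lda", seed = 4)
  expect_equal(cv$n_folds, 10)
  expect_equal(as.integer(table(cv$folds)), rep(32L, 10))
  expect_equal(sort(unlist(lapply(1:10, function(f) which(cv$folds == f)))),
               1:320)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  expect_equal(sum(cv$confusion), 320)
  cv2 <- cross_validate(fm, "diag_lda", seed = 4)
  expect_identical(cv, cv2)                   # same data + seed -> identical
  expect_error(cross_validate(fm, "diag_lda", n_folds = 400), "at least")
})

test_that("label permutation drives accuracy to chance", {
  fm <- sep_fm(n = 60, gap = 2, seed = 12)
  set.seed(13)
  accs <- replicate(20, {
    p <- fm
    p$labels <- sample(fm$labels)
    cross_validate(p, "diag_lda", seed = 5)$mean_accuracy
  })
  # binomial 95% interval around 0.5 for the mean of 20 x 120 decisions
  expect_lt(abs(mean(accs) - 0.5), 1.96 * sqrt(0.25 / (20 * 120)) + 0.03)
})

test_that("C grid search enumerates decades and breaks ties downward", {
  fm <- sep_fm(n = 30, gap = 3, seed = 14)
  g <- grid_search_c(fm, seed = 2, n_folds = 5)
  expect_equal(nrow(g$table), 10)
  expect_equal(g$table$C, 10^seq(-7, 2))
  # constant features: every C predicts identically -> tie -> smallest C
  fm0 <- make_fm(matrix(1, 60, 2), fm$labels)
  g0 <- grid_search_c(fm0, seed = 2, n_folds = 5)
  expect_equal(g0$best_c, 1e-7)
  expect_true(all(g0$table$accuracy == g0$table$accuracy[1]))
  # dense grid uses factor-e spacing
  gd_grid <- exp(seq(log(1e-7), log(1e2), by = 1))
  expect_equal(length(gd_grid), 21)
})

test_that("prediction refuses mismatched feature layouts", {
  fm <- sep_fm(n = 20)
  m <- train_diag_lda(fm)
  expect_error(predict(m, matrix(0, 3, 5)), "mismatch")
})
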