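# Classifiers and validation: diagonal LDA (Gaussian discriminant with a
# shared diagonal covariance), linear SVM (L1-loss, dual coordinate
# descent), stratified 10-fold cross-validation, and the exhaustive C grid
# search.  Features are z-scored with training statistics only; exact
# decision ties go to class "forward" (documented constant).

.as_xy <- function(features) {
  if (inherits(features, "feature_matrix"))
    list(x = features$values, y = features$labels)
  else stop("expected a feature_matrix")
}

.zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
.zscore_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, "/")

#' Train a diagonal LDA classifier
#'
#' Two-class Gaussian discriminant with per-class means and a shared
#' diagonal covariance (pooled per-feature variance, floored at 1e-12 times
#' the mean variance).  The decision rule is linear in the features.
#'
#' @param features A `feature_matrix` (two classes, >= 2 trials per class).
#' @param zscore Standardize features with training statistics (default
#'   TRUE).
#' @return A `bci_classifier` of kind `"diag_lda"`.
#' @export
train_diag_lda <- function(features, zscore = TRUE) {
  d <- .as_xy(features)
  classes <- levels(d$y)
  if (length(classes) != 2 || any(table(d$y) < 2))
    stop("need two classes with >= 2 trials each")
  z <- if (zscore) .zscore_fit(d$x)
  x <- if (zscore) .zscore_apply(d$x, z) else d$x
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[d$y == cl, , drop = FALSE])))
  centered <- x - mu[as.integer(d$y), , drop = FALSE]
  v <- colSums(centered^2) / (nrow(x) - 2)
  v <- pmax(v, 1e-12 * mean(v))
  prior <- as.numeric(table(d$y)) / length(d$y)
  structure(list(kind = "diag_lda", classes = classes, mu = mu,
                 var = v, prior = prior, zscore = z,
                 feature_names = features$feature_names,
                 epoch = features$epoch),
            class = "bci_classifier")
}

#' Train a linear SVM
#'
#' L1-loss (hinge) linear support-vector machine solved in the dual by
#' coordinate descent, with the bias handled as an augmented constant
#' feature.  Errors out if the solver has not converged (projected-gradient
#' tolerance 1e-4) within `max_pass` sweeps.
#'
#' @param features A `feature_matrix`.
#' @param C Regularization parameter (> 0); the study's optimum is 1e-2.
#' @param zscore Standardize with training statistics (default TRUE).
#' @param max_pass Maximum coordinate-descent sweeps.
#' @param tol Projected-gradient stopping tolerance (default
#'   `1e-3 * max(1, C)`).
#' @return A `bci_classifier` of kind `"linear_svm"` with weight vector
#'   `w`, bias `b`, dual variables `alpha` and `converged = TRUE`.
#' @export
train_linear_svm <- function(features, C = 1e-2, zscore = TRUE,
                             max_pass = 10000, tol = NULL) {
  stopifnot(C > 0)
  # projected-gradient tolerance; gradients scale with the box size for
  # large C, so the criterion is scaled accordingly
  if (is.null(tol)) tol <- 1e-3 * max(1, C)
  d <- .as_xy(features)
  classes <- levels(d$y)
  if (length(classes) != 2) stop("need exactly two classes")
  z <- if (zscore) .zscore_fit(d$x)
  x <- if (zscore) .zscore_apply(d$x, z) else d$x
  yy <- ifelse(d$y == classes[1], 1, -1)
  X <- cbind(x, 1)                       # augmented bias
  n <- nrow(X)
  qii <- rowSums(X^2)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  converged <- FALSE
  .with_seed(1735L, for (pass in seq_len(max_pass)) {
    pg_max <- 0
    # random coordinate order (fresh each pass, private deterministic
    # stream): cyclic order can stall at large C
    for (i in sample.int(n)) {
      g <- yy[i] * sum(w * X[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(g, 0)
            else if (alpha[i] >= C) max(g, 0) else g
      if (abs(pg) > pg_max) pg_max <- abs(pg)
      if (abs(pg) > 1e-14) {
        anew <- min(max(alpha[i] - g / qii[i], 0), C)
        if (anew != alpha[i]) {
          w <- w + (anew - alpha[i]) * yy[i] * X[i, ]
          alpha[i] <- anew
        }
      }
    }
    if (pg_max < tol) { converged <- TRUE; break }
  })
  if (!converged)
    stop(sprintf(
      "SVM did not converge in %d sweeps (C=%g, n=%d, d=%d, max |PG|=%.3g)",
      max_pass, C, n, ncol(X) - 1, pg_max))
  structure(list(kind = "linear_svm", classes = classes,
                 w = w[-length(w)], b = w[length(w)], C = C,
                 alpha = alpha, converged = converged, zscore = z,
                 feature_names = features$feature_names,
                 epoch = features$epoch),
            class = "bci_classifier")
}

#' @export
print.bci_classifier <- function(x, ...) {
  cat(sprintf("bci_classifier: %s (%d features; classes %s)\n", x$kind,
              length(x$feature_names), paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict class labels
#'
#' @param object A `bci_classifier`.
#' @param features A `feature_matrix` (or numeric matrix) with the same
#'   feature layout as the training set.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.bci_classifier <- function(object, features, ...) {
  x <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (ncol(x) != length(object$feature_names))
    stop("feature dimension mismatch")
  if (!is.null(object$zscore)) x <- .zscore_apply(x, object$zscore)
  score <- if (object$kind == "diag_lda") {
    d1 <- colSums((t(x) - object$mu[1, ])^2 / object$var)
    d2 <- colSums((t(x) - object$mu[2, ])^2 / object$var)
    (d2 - d1) / 2 + log(object$prior[1] / object$prior[2])
  } else {
    as.vector(x %*% object$w + object$b)
  }
  # score >= 0 -> first class; ties go to "forward" (class level 1)
  factor(object$classes[ifelse(score >= 0, 1L, 2L)],
         levels = object$classes)
}

.train_one <- function(features, kind, C = 1e-2, zscore = TRUE) {
  switch(kind,
         diag_lda = train_diag_lda(features, zscore = zscore),
         linear_svm = train_linear_svm(features, C = C, zscore = zscore),
         stop("unknown classifier kind: ", kind))
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds (each fold mirrors the class balance), one model per
#' fold trained on the remaining folds, each trial tested exactly once.
#' Deterministic for a fixed seed.
#'
#' @param features A `feature_matrix`.
#' @param classifier_kind `"diag_lda"` or `"linear_svm"`.
#' @param C SVM regularization (ignored for LDA).
#' @param seed Integer seed controlling the fold assignment.
#' @param n_folds Number of folds (default 10).
#' @return A `cv_report`: per-fold accuracy, mean accuracy, per-class
#'   accuracy, confusion counts, and the fold assignment.
#' @export
cross_validate <- function(features, classifier_kind = "diag_lda",
                           C = 1e-2, seed = 1, n_folds = 10) {
  d <- .as_xy(features)
  n <- length(d$y)
  if (n < n_folds) stop("need at least n_folds trials")
  folds <- integer(n)
  .with_seed(seed, {
    for (cl in levels(d$y)) {
      i <- sample(which(d$y == cl))
      folds[i] <- rep_len(seq_len(n_folds), length(i))
    }
  })
  if (any(tapply(d$y, folds, function(v) length(unique(v))) < 2) ||
      min(table(folds)) < 1)
    stop("a fold lost a class after stratification")
  pred <- factor(rep(NA, n), levels = levels(d$y))
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- features
    tr$values <- features$values[folds != f, , drop = FALSE]
    tr$labels <- d$y[folds != f]
    model <- .train_one(tr, classifier_kind, C)
    te <- features$values[folds == f, , drop = FALSE]
    p <- predict(model, structure(list(values = te,
                                       feature_names = features$feature_names),
                                  class = "feature_matrix"))
    pred[folds == f] <- p
    fold_acc[f] <- mean(p == d$y[folds == f])
  }
  conf <- table(truth = d$y, predicted = pred)
  per_class <- diag(conf) / rowSums(conf)
  structure(list(n_folds = n_folds, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 per_class_accuracy = per_class, confusion = conf,
                 folds = folds, classifier_kind = classifier_kind,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): mean accuracy %.1f%% (folds %.1f-%.1f%%)\n",
              x$n_folds, x$classifier_kind, 100 * x$mean_accuracy,
              100 * min(x$fold_accuracy), 100 * max(x$fold_accuracy)))
  print(round(100 * x$per_class_accuracy, 1))
  invisible(x)
}

#' Exhaustive grid search for the SVM C parameter
#'
#' Cross-validated accuracy over an exponential C grid (default decade
#' steps 1e-7..1e2; `dense = TRUE` uses factor-e steps, the alternative
#' reading of an "exponential search with step e^-1").  Ties return the
#' smaller C.
#'
#' @param features A `feature_matrix`.
#' @param grid Candidate C values.
#' @param dense Use factor-e spacing instead of decades.
#' @param seed Fold seed passed to [cross_validate()].
#' @param n_folds Folds per candidate.
#' @return List with `best_c`, `best_accuracy` and the accuracy `table`.
#' @export
grid_search_c <- function(features, grid = NULL, dense = FALSE, seed = 1,
                          n_folds = 10) {
  if (is.null(grid))
    grid <- if (dense) exp(seq(log(1e-7), log(1e2), by = 1))
            else 10^seq(-7, 2)
  if (!length(grid)) stop("empty grid")
  grid <- sort(grid)
  acc <- vapply(grid, function(C)
    cross_validate(features, "linear_svm", C = C, seed = seed,
                   n_folds = n_folds)$mean_accuracy, numeric(1))
  best <- which.max(acc)                 # ties -> smallest C (grid sorted)
  list(best_c = grid[best], best_accuracy = acc[best],
       table = data.frame(C = grid, accuracy = acc))
}
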