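# Autoregressive feature models: Burg-method AR estimation, ARX with a
# class-template exogenous input (ordinary least squares), and AIC model
# order selection over orders 2..30.
#
# Model convention: x[t] = sum_i a_i x[t-i] (+ sum_j b_j u[t-j]) + e[t];
# coefficients are returned in the predictive sign convention.

#' Fit an autoregressive model by the Burg method
#'
#' Burg's lattice recursion minimizes the sum of forward and backward
#' prediction-error power; reflection coefficients are bounded by 1 in
#' magnitude, so the fitted model is stable for any input.  The segment
#' mean is removed before fitting.
#'
#' @param segment Numeric vector, length > 2 * order.
#' @param order Model order p, between 2 and 30.
#' @param all_orders If TRUE, also return coefficients and residual
#'   variances for every order 1..p (one recursion pass).
#' @return An `ar_model`: list with `order`, `coef` (a_1..a_p),
#'   `noise_variance`, `reflection` (k_1..k_p), `n`, `fit_method`; with
#'   `all_orders`, additionally `coef_by_order` (list) and `var_by_order`.
#' @export
fit_ar_burg <- function(segment, order, all_orders = FALSE) {
  order <- as.integer(order)
  if (order < 2 || order > 30)
    stop("order must be in 2..30 (got ", order, ")")
  n <- length(segment)
  if (n <= 2 * order) stop("segment length must exceed 2 * order")
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  x <- segment - mean(segment)
  v0 <- sum(x^2) / n
  if (v0 == 0) stop("constant segment: zero variance")
  f <- x; b <- x                       # forward / backward errors
  a <- numeric(0)
  kvec <- numeric(order)
  v <- v0
  coef_by_order <- if (all_orders) vector("list", order)
  var_by_order <- numeric(order)
  for (m in seq_len(order)) {
    ff <- f[(m + 1):n]
    bb <- b[m:(n - 1)]
    den <- sum(ff^2) + sum(bb^2)
    k <- if (den > 0) -2 * sum(ff * bb) / den else 0
    kvec[m] <- k
    # order update (Levinson): note predictive sign convention a_i = -phi_i
    a_new <- c(a, 0) + k * c(rev(a), 1)
    a <- a_new
    f_new <- ff + k * bb
    b_new <- bb + k * ff
    f <- c(rep(0, m), f_new)           # keep indexing aligned
    b <- c(rep(0, m), b_new)
    v <- v * (1 - k^2)
    var_by_order[m] <- v
    if (all_orders) coef_by_order[[m]] <- -a
  }
  out <- list(order = order, coef = -a, noise_variance = v,
              reflection = kvec, n = n, fit_method = "burg")
  if (all_orders) {
    out$coef_by_order <- coef_by_order
    out$var_by_order <- var_by_order
  }
  structure(out, class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("%s model: order %d, noise variance %.4g (n=%d)\n",
              toupper(x$fit_method), x$order, x$noise_variance, x$n))
  invisible(x)
}

#' Power spectral density implied by an AR model
#'
#' @param model An `ar_model`.
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate, Hz.
#' @return PSD values `noise_variance / (fs |1 - sum a_i z^-i|^2)`.
#' @export
ar_spectrum <- function(model, freq_hz, fs) {
  z <- exp(-1i * outer(2 * pi * freq_hz / fs, seq_len(model$order)))
  den <- Mod(1 - as.vector(z %*% model$coef))^2
  model$noise_variance / (fs * den)
}

#' Class-template signal from training trials
#'
#' Sample-wise mean across the training trials of one class; used as the
#' exogenous input of ARX models.  Averaging suppresses the zero-mean noise
#' and leaves the class's event-related component.  Templates must be built
#' from training data only; the returned object records its provenance.
#'
#' @param streams Trials x samples matrix (epoch-restricted band signal or
#'   envelope of the training trials).
#' @param labels Factor of class labels, length `nrow(streams)`.
#' @param class `"forward"` or `"backward"`.
#' @return Numeric template with attributes `class` and `n_trials`.
#' @export
build_class_template <- function(streams, labels, class) {
  i <- which(labels == class)
  if (length(i) < 2)
    stop("need >= 2 training trials of class ", class)
  tpl <- colMeans(streams[i, , drop = FALSE])
  attr(tpl, "class_label") <- class
  attr(tpl, "n_trials") <- length(i)
  tpl
}

#' Fit an ARX model by least squares
#'
#' `x[t] = sum_{i=1..p} a_i x[t-i] + sum_{j=0..q} b_j u[t-j] + e[t]` with
#' exogenous input `u` (a class template aligned to the segment).  In-sample
#' residual variance can never exceed that of the AR-only fit of the same
#' order on the same segment.
#'
#' @param segment Numeric vector.
#' @param template Exogenous input, same length as `segment`.
#' @param ar_order AR order p (2..30).
#' @param x_order Exogenous order q (lags 0..q; default 0).
#' @return An `arx_model`: `ar_model` fields plus `x_coef` (b_0..b_q) and
#'   `template_n` (provenance).
#' @export
fit_arx <- function(segment, template, ar_order, x_order = 0) {
  ar_order <- as.integer(ar_order); x_order <- as.integer(x_order)
  if (ar_order < 2 || ar_order > 30) stop("ar_order must be in 2..30")
  if (length(template) != length(segment))
    stop("template length must match the modeled segment")
  n <- length(segment)
  p0 <- max(ar_order, x_order)
  if (n - p0 <= ar_order + x_order + 1)
    stop("segment too short for the requested orders")
  y <- segment - mean(segment)
  u <- template - mean(template)
  t_idx <- (p0 + 1):n
  X <- matrix(0, length(t_idx), ar_order + x_order + 1)
  for (i in seq_len(ar_order)) X[, i] <- y[t_idx - i]
  for (j in 0:x_order) X[, ar_order + 1 + j] <- u[t_idx - j]
  qrX <- qr(X)
  zero_tpl <- all(u == 0)
  if (qrX$rank < ncol(X) && !zero_tpl)
    stop("rank-deficient ARX regression (collinear template?)")
  beta <- qr.coef(qrX, y[t_idx])
  beta[is.na(beta)] <- 0               # zero template -> pure AR
  res <- y[t_idx] - X %*% beta
  structure(list(order = ar_order, coef = beta[seq_len(ar_order)],
                 x_coef = beta[(ar_order + 1):(ar_order + 1 + x_order)],
                 noise_variance = sum(res^2) / length(res),
                 n = n, fit_method = "arx",
                 template_n = attr(template, "n_trials")),
            class = c("arx_model", "ar_model"))
}

#' AIC model-order selection
#'
#' Fits candidate orders and selects the AIC minimizer,
#' `AIC = n log(sigma_hat^2) + 2 k` with `k = p` for AR and
#' `k = p + q + 1` for ARX (Gaussian likelihood form); ties go to the
#' smaller order.  For AR the full candidate range is obtained from a
#' single Burg recursion.
#'
#' @param segment Numeric vector.
#' @param orders Candidate orders (default 2:30).
#' @param model_kind `"ar"` or `"arx"`.
#' @param template Exogenous input (required for `"arx"`).
#' @param x_order Exogenous order for `"arx"`.
#' @return An `order_selection`: list with `orders`, `aic`, `selected`.
#' @export
select_order_aic <- function(segment, orders = 2:30,
                             model_kind = c("ar", "arx"),
                             template = NULL, x_order = 0) {
  model_kind <- match.arg(model_kind)
  orders <- sort(unique(as.integer(orders)))
  n <- length(segment)
  if (max(orders) >= n / 2)
    stop("max candidate order must be below segment length / 2")
  if (model_kind == "ar") {
    fit <- fit_ar_burg(segment, max(orders), all_orders = TRUE)
    sig2 <- fit$var_by_order[orders]
    aic <- n * log(sig2) + 2 * orders
  } else {
    if (is.null(template)) stop("ARX selection needs a template")
    aic <- vapply(orders, function(p) {
      m <- fit_arx(segment, template, p, x_order)
      n * log(m$noise_variance) + 2 * (p + x_order + 1)
    }, numeric(1))
  }
  if (!all(is.finite(aic))) stop("non-finite AIC among candidates")
  structure(list(orders = orders, aic = aic,
                 selected = orders[which.min(aic)]),
            class = "order_selection")
}

#' AR/ARX coefficient features for classification
#'
#' Models the epoch-restricted sub-band signal (default) or its band-power
#' envelope for each trial and channel and emits the coefficient vectors
#' (optionally with the residual variance appended) as a feature matrix.
#' In signal mode the residual variance is the AR-whitened epoch band
#' power -- "AR-modeled band power" -- which carries the class's ERS
#' energy, while the coefficients encode the in-band spectral shape.  The model order is selected
#' once per channel by AIC on the training trials (median of per-trial AIC
#' minimizers) and reused for all trials, so feature dimensions match
#' across training and test sets.  For ARX, templates are built from the
#' supplied training labels only, and both class templates are applied to
#' every trial with the two coefficient sets concatenated -- at prediction
#' time the true class is unknown, so using the matched template alone
#' would leak labels.
#'
#' @param trials Preprocessed `trial_set`.
#' @param band Band name (see [band_set()]).
#' @param channels Channel names (default C3, C4, Cz).
#' @param epoch Epoch specifier (default `"epoch4"`, the post-imagery
#'   rebound window; see the methods vignette).
#' @param kind `"ar"` (Burg) or `"arx"` (least squares with templates).
#' @param orders AIC candidate orders (default 2:30).
#' @param fixed_order Optional integer or per-channel named vector: skip
#'   AIC and use this order (e.g., to encode a test set with the orders
#'   chosen on training data).
#' @param train Optional list from a previous call (fields `orders_used`,
#'   `templates`); reuses its orders and templates (no leakage).
#' @param source `"signal"` (sub-band signal; default) or `"envelope"`
#'   (squared, smoothed sub-band signal).
#' @param include_noise_var Append the residual variance (default TRUE).
#' @param smooth_s Envelope smoothing in envelope mode (default 0.125 s).
#' @return A `feature_matrix` with attributes `orders_used` and
#'   `templates` for reuse on a test set.
#' @export
features_ar <- function(trials, band = "beta",
                        channels = c("C3", "C4", "Cz"),
                        epoch = "epoch4", kind = c("ar", "arx"),
                        orders = 2:30, fixed_order = NULL, train = NULL,
                        source = c("signal", "envelope"),
                        include_noise_var = TRUE, smooth_s = 0.125) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  fs <- trials$timing$sample_rate_hz
  env <- if (source == "signal")
    band_signals(trials, band, channels)
  else band_envelopes(trials, band, channels, smooth_s = smooth_s)
  seg <- epoch_features(env, epoch, fs)
  nt <- n_trials(trials)
  orders_used <- if (!is.null(train)) train$orders_used else NULL
  templates <- if (!is.null(train)) train$templates else NULL
  feats <- list(); fnames <- character(0)
  for (nm in names(seg)) {
    m <- seg[[nm]]
    if (is.null(orders_used[[nm]])) {
      p <- if (!is.null(fixed_order)) {
        if (length(fixed_order) > 1) fixed_order[[nm]] else fixed_order
      } else {
        sel <- apply(m, 1, function(x)
          select_order_aic(x, orders, "ar")$selected)
        as.integer(round(stats::median(sel)))
      }
      orders_used[[nm]] <- as.integer(p)
    }
    p <- orders_used[[nm]]
    if (kind == "ar") {
      f <- t(apply(m, 1, function(x) {
        fit <- fit_ar_burg(x, p)
        c(fit$coef, if (include_noise_var) fit$noise_variance)
      }))
      feats[[nm]] <- f
      fnames <- c(fnames,
                  paste0(nm, "_ar", seq_len(p)),
                  if (include_noise_var) paste0(nm, "_nvar"))
    } else {
      if (is.null(templates[[nm]]))
        templates[[nm]] <- lapply(
          stats::setNames(levels(trials$labels), levels(trials$labels)),
          function(cl) build_class_template(m, trials$labels, cl))
      f <- t(apply(m, 1, function(x) {
        unlist(lapply(templates[[nm]], function(tpl) {
          fit <- fit_arx(x, tpl, p)
          c(fit$coef, fit$x_coef,
            if (include_noise_var) fit$noise_variance)
        }))
      }))
      feats[[nm]] <- f
      for (cl in names(templates[[nm]]))
        fnames <- c(fnames, paste0(nm, "_", cl, "_arx", seq_len(p)),
                    paste0(nm, "_", cl, "_x0"),
                    if (include_noise_var) paste0(nm, "_", cl, "_nvar"))
    }
  }
  vals <- do.call(cbind, feats)
  if (!all(is.finite(vals))) stop("non-finite AR features")
  fm <- .new_feature_matrix(vals, trials$labels, .epoch_bounds(epoch),
                            fnames)
  fm$orders_used <- orders_used
  fm$templates <- templates
  fm
}
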