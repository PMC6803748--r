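# Shared fixtures: bare feature matrices, miniature trial sets, an exact
# hard-margin SVM oracle (support-set enumeration), and a minimal EDF
# writer used to exercise the reader against an independently constructed
# file.

make_fm <- function(x, y) {
  structure(list(values = x, labels = y,
                 feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                 epoch = c(0, 1)),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trial_set wrapper around a trials x channels x samples array
make_ts <- function(data, labels, timing = paradigm_timing(),
                    session = "session1") {
  structure(list(data = data,
                 labels = factor(labels, levels = c("forward", "backward")),
                 channels = c("C3", "Cz", "C4"),
                 timing = timing,
                 run_id = rep(1:4, each = ceiling(dim(data)[1] / 4))[
                   seq_len(dim(data)[1])],
                 subject_id = "fix", session_id = session, seed = 0L,
                 artifacts = data.frame(trial = integer(),
                                        channel = character(),
                                        sample = integer())),
            class = "trial_set")
}

# exact hard-margin linear SVM in 2-d by active-set enumeration: in 2-d
# the optimum's active constraints are 2 points (one per class) or 3
# points, each satisfied with equality y_i (w.x_i + b) = 1.  Solve every
# candidate exactly, keep those feasible for all points, take min ||w||^2.
qp_svm_oracle <- function(x, y) {
  n <- nrow(x)
  best <- NULL
  consider <- function(S) {
    A <- cbind(x[S, , drop = FALSE] * y[S], y[S])
    sol <- tryCatch(qr.solve(A, rep(1, length(S))), error = function(e) NULL)
    if (length(S) == 2) {
      # underdetermined: minimum-norm w with the two equality constraints
      i <- S[1]; j <- S[2]
      d <- x[i, ] - x[j, ]
      if (y[i] == y[j]) return(invisible(NULL))
      w <- 2 * y[i] * d / sum(d^2)
      b <- y[i] - sum(w * x[i, ])
      sol <- c(w, b)
    }
    if (is.null(sol)) return(invisible(NULL))
    w <- sol[1:2]; b <- sol[3]
    marg <- y * (as.vector(x %*% w) + b)
    if (min(marg) >= 1 - 1e-9) {
      nrm <- sum(w^2)
      if (is.null(best) || nrm < best$nrm - 1e-12)
        best <<- list(w = w, b = b, nrm = nrm)
    }
    invisible(NULL)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (y[i] != y[j]) consider(c(i, j))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (length(unique(y[c(i, j, k)])) == 2) consider(c(i, j, k))
  best$sv <- which(abs(y * (as.vector(x %*% best$w) + best$b) - 1) < 1e-6)
  best
}

# minimal EDF writer (one data record per second, 16-bit little endian)
write_edf_fixture <- function(path, signals, fs, record_s = 1,
                              phys_range = c(-200, 200)) {
  ns <- length(signals)
  n_rec <- length(signals[[1]]) / (fs * record_s)
  stopifnot(n_rec == round(n_rec))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    writeChar(formatC(s, width = -w), con, eos = NULL)
  }
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + ns * 256), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad(as.character(record_s), 8)
  pad(as.character(ns), 4)
  for (nm in names(signals)) pad(nm, 16)
  for (i in 1:ns) pad("AgAgCl", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad(as.character(phys_range[1]), 8)
  for (i in 1:ns) pad(as.character(phys_range[2]), 8)
  for (i in 1:ns) pad("-32768", 8)
  for (i in 1:ns) pad("32767", 8)
  for (i in 1:ns) pad("none", 80)
  for (i in 1:ns) pad(as.character(fs * record_s), 8)
  for (i in 1:ns) pad("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  spr <- fs * record_s
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- signals[[s]][((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - phys_range[1]) / gain + (-32768)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# small cached default session-1 set shared by several test files
cached_session1 <- local({
  cache <- NULL
  function(n = 64, seed = 11) {
    if (is.null(cache))
      cache <<- generate_session(subject_profile(artifact_rate = 0), n,
                                 "session1", seed)
    cache
  }
})
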