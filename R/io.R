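# On-disk dataset layout (versioned): one little-endian float64 array per
# session (trials x channels x samples, microvolts) + a JSON header with
# shape, timing, identifiers and an MD5 checksum + a CSV trial table (and
# artifact ground truth, if any).  A minimal EDF (European Data Format)
# reader supports importing real recordings.

.DATASET_VERSION <- 1L

#' Write a trial set to a directory
#'
#' Layout: `data.bin` (float64, little endian, sample-fastest),
#' `header.json` (shape, channels, timing, ids, seed, checksum),
#' `trials.csv` (trial_id, label, run_id, subject_id, session_id, seed) and
#' `artifacts.csv` (injected ground truth, if any).
#'
#' @param trials A `trial_set`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  bin <- file.path(path, "data.bin")
  con <- file(bin, "wb")
  writeBin(as.vector(trials$data), con, size = 8, endian = "little")
  close(con)
  tm <- trials$timing
  header <- list(version = .DATASET_VERSION,
                 dims = dim(trials$data),
                 channels = trials$channels,
                 timing = tm[c("trial_duration_s", "baseline_end_s",
                               "command_end_s", "static_gap_end_s",
                               "mi_offset_s", "sample_rate_hz",
                               "session_mode")],
                 subject_id = trials$subject_id,
                 session_id = trials$session_id,
                 seed = trials$seed,
                 md5 = unname(tools::md5sum(bin)))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(trial_id = seq_along(trials$labels),
               label = as.character(trials$labels),
               run_id = trials$run_id,
               subject_id = trials$subject_id,
               session_id = trials$session_id,
               seed = trials$seed),
    file.path(path, "trials.csv"), row.names = FALSE)
  if (nrow(trials$artifacts))
    utils::write.csv(trials$artifacts, file.path(path, "artifacts.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial set written by [write_dataset()]
#'
#' Verifies the layout version, the MD5 checksum and the array shape;
#' truncated or corrupted files raise explicit errors rather than silent
#' NaNs.
#'
#' @param path Dataset directory.
#' @return A `trial_set`.
#' @export
read_dataset <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("no header.json in ", path)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  if (header$version > .DATASET_VERSION)
    stop("unsupported dataset layout version ", header$version)
  bin <- file.path(path, "data.bin")
  md5 <- unname(tools::md5sum(bin))
  if (!identical(md5, header$md5))
    stop("checksum mismatch for ", bin)
  n_expect <- prod(header$dims)
  if (file.info(bin)$size != 8 * n_expect)
    stop("shape mismatch: expected ", n_expect, " float64 values, file has ",
         file.info(bin)$size / 8)
  con <- file(bin, "rb")
  vals <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
  close(con)
  tab <- utils::read.csv(file.path(path, "trials.csv"),
                         stringsAsFactors = FALSE)
  tm <- header$timing
  timing <- paradigm_timing(tm$session_mode,
                            trial_duration_s = tm$trial_duration_s,
                            baseline_end_s = tm$baseline_end_s,
                            command_end_s = tm$command_end_s,
                            static_gap_end_s = tm$static_gap_end_s,
                            sample_rate_hz = tm$sample_rate_hz,
                            mi_offset_s = tm$mi_offset_s)
  art_f <- file.path(path, "artifacts.csv")
  artifacts <- if (file.exists(art_f))
    utils::read.csv(art_f, stringsAsFactors = FALSE)
  else data.frame(trial = integer(), channel = character(),
                  sample = integer())
  structure(list(data = array(vals, dim = header$dims,
                              dimnames = list(NULL, header$channels, NULL)),
                 labels = factor(tab$label,
                                 levels = c("forward", "backward")),
                 channels = header$channels,
                 timing = timing, run_id = tab$run_id,
                 subject_id = header$subject_id,
                 session_id = header$session_id,
                 seed = header$seed, artifacts = artifacts),
            class = "trial_set")
}

#' Read an EDF (European Data Format) file
#'
#' Minimal reader for uncompressed EDF: parses the ASCII header and the
#' 16-bit little-endian data records and applies the per-signal
#' digital-to-physical scaling.  Annotation signals are not interpreted.
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors, physical
#'   units), `sample_rate_hz` (named vector), `labels`, `n_records`,
#'   `record_duration_s`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- rawToChar(readBin(con, "raw", n))
    trimws(s)
  }
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  rd(8); rd(8)                            # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)                                  # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                         # transducer, dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                                 # prefiltering
  spr <- as.integer(fld(8))               # samples per record
  fld(32)                                 # reserved
  seek(con, header_bytes)
  raw16 <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_records * sum(spr))
    stop("truncated EDF: expected ", n_records * sum(spr),
         " samples, got ", length(raw16))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- phys_min - gain * dig_min
  signals <- vector("list", ns)
  idx <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  for (s in seq_len(ns)) {
    pos <- as.vector(outer((idx[s] + 1):idx[s + 1],
                           (seq_len(n_records) - 1) * per_rec, "+"))
    signals[[s]] <- raw16[pos] * gain[s] + offs[s]
  }
  names(signals) <- labels
  list(signals = signals,
       sample_rate_hz = stats::setNames(spr / record_dur, labels),
       labels = labels, n_records = n_records,
       record_duration_s = record_dur)
}

#' Build a trial set from an EDF recording
#'
#' Maps EDF signal labels to the C3/Cz/C4 montage (matching is
#' case-insensitive on the trailing electrode name, so "EEG C3-A1A2"
#' matches C3) and cuts consecutive fixed-length trials.
#'
#' @param edf Result of [read_edf()].
#' @param labels Per-trial class labels (`forward`/`backward`).
#' @param timing A [paradigm_timing()]; its sampling rate must match the
#'   EDF.
#' @param onsets_s Optional trial-onset times (seconds); default
#'   consecutive trials from 0.
#' @param subject_id,session_id,run_id Metadata.
#' @return A `trial_set`.
#' @export
edf_to_trialset <- function(edf, labels, timing = paradigm_timing(),
                            onsets_s = NULL, subject_id = "edf",
                            session_id = "session1", run_id = NULL) {
  want <- c("C3", "Cz", "C4")
  pick <- vapply(want, function(w) {
    hit <- grep(paste0(w, "$"), edf$labels, ignore.case = TRUE)
    if (!length(hit))
      hit <- grep(w, edf$labels, ignore.case = TRUE)
    if (!length(hit)) stop("EDF has no signal matching channel ", w)
    hit[1]
  }, integer(1))
  fs <- unique(edf$sample_rate_hz[pick])
  if (length(fs) != 1 || abs(fs - timing$sample_rate_hz) > 1e-9)
    stop("EDF sampling rate does not match the paradigm timing")
  nt <- length(labels)
  if (is.null(onsets_s)) onsets_s <- (seq_len(nt) - 1) * timing$trial_duration_s
  ns <- timing$n_samples
  data <- array(0, c(nt, 3, ns), dimnames = list(NULL, want, NULL))
  for (i in seq_len(nt)) {
    a <- round(onsets_s[i] * fs) + 1
    if (a + ns - 1 > length(edf$signals[[pick[1]]]))
      stop("trial ", i, " extends beyond the recording")
    for (ch in 1:3) data[i, ch, ] <- edf$signals[[pick[ch]]][a:(a + ns - 1)]
  }
  structure(list(data = data,
                 labels = factor(labels, levels = c("forward", "backward")),
                 channels = want, timing = timing,
                 run_id = if (is.null(run_id))
                   rep(1:4, each = ceiling(nt / 4))[seq_len(nt)] else run_id,
                 subject_id = subject_id, session_id = session_id,
                 seed = NA_integer_,
                 artifacts = data.frame(trial = integer(),
                                        channel = character(),
                                        sample = integer())),
            class = "trial_set")
}
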