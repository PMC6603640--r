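#' A multi-channel recording
#'
#' Container for a continuous C x T recording with per-interval annotations.
#'
#' @param data C x T numeric matrix.
#' @param sample_rate Sampling rate in Hz (uniform across channels).
#' @param channel_names Character vector of length C.
#' @param annotations Data frame with columns `start_s`, `end_s`, `label`
#'   (integer class >= 2; unannotated time is class 1). May be empty.
#' @param subject_id Identifier.
#' @return A `recording`.
#' @export
recording <- function(data, sample_rate, channel_names = NULL,
                      annotations = NULL, subject_id = "s1") {
  stopifnot(is.matrix(data), sample_rate > 0)
  C <- nrow(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  stopifnot(length(channel_names) == C)
  if (is.null(annotations))
    annotations <- data.frame(start_s = numeric(0), end_s = numeric(0),
                              label = integer(0))
  dur <- ncol(data) / sample_rate
  if (nrow(annotations) > 0 &&
      (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9)))
    stop("annotation interval outside [0, ", dur, "] s")
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names, annotations = annotations,
                 subject_id = subject_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording '%s': %d channels x %d samples @ %g Hz, %d annotations\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$annotations)))
  invisible(x)
}

## ---- EDF ----------------------------------------------------------------
## Plain 16-bit EDF: 256-byte fixed header, 256 bytes per signal of signal
## headers, then data records of little-endian int16 samples. Hand-written
## because the format is simple and fully specified.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) stop("truncated EDF header")
  trimws(raw)
}

#' Read a multi-channel recording
#'
#' `dialect = "edf"` reads a plain 16-bit EDF file (uniform sampling rate
#' required; mixed per-channel rates are rejected). If a sidecar file
#' `<path>.annotations.csv` with columns `start_s,end_s,label` exists, it is
#' loaded as the annotation track. `dialect = "fixture"` reads the package's
#' fixture directory format written by [write_recording_fixture()]:
#' `signals.csv.gz` (one row per channel) plus `meta.json` and optional
#' `annotations.csv`.
#'
#' @param path File (EDF) or directory (fixture) path.
#' @param dialect `"edf"` or `"fixture"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, dialect = c("edf", "fixture")) {
  dialect <- match.arg(dialect)
  if (dialect == "fixture") return(read_recording_fixture(path))
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                                  # version
  edf_field(con, 80); edf_field(con, 80)             # patient, recording ids
  edf_field(con, 8); edf_field(con, 8)               # start date, time
  header_bytes <- suppressWarnings(as.integer(edf_field(con, 8)))
  if (is.na(header_bytes)) stop("EDF parse error: header-bytes field not numeric")
  edf_field(con, 44)                                 # reserved
  n_records <- suppressWarnings(as.integer(edf_field(con, 8)))
  record_dur <- suppressWarnings(as.numeric(edf_field(con, 8)))
  ns <- suppressWarnings(as.integer(edf_field(con, 4)))
  if (is.na(n_records) || is.na(record_dur) || is.na(ns) || ns < 1)
    stop("EDF parse error: record-count/duration/signal-count fields")
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)          # transducer
  for (i in seq_len(ns)) edf_field(con, 8)           # physical dim
  phys_min <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(edf_field(con, 8))), 1)
  phys_max <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(edf_field(con, 8))), 1)
  dig_min <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(edf_field(con, 8))), 1)
  dig_max <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(edf_field(con, 8))), 1)
  if (any(!is.finite(c(phys_min, phys_max, dig_min, dig_max))))
    stop("EDF parse error: physical/digital min/max fields")
  for (i in seq_len(ns)) edf_field(con, 80)          # prefiltering
  nr <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.integer(edf_field(con, 8))), 1L)
  if (any(is.na(nr) | nr < 1)) stop("EDF parse error: samples-per-record field")
  for (i in seq_len(ns)) edf_field(con, 32)          # reserved
  if (length(unique(nr)) != 1L)
    stop("unsupported input: mixed per-channel sampling rates (samples per record: ",
         paste(unique(nr), collapse = ", "), ")")
  expected <- header_bytes + n_records * sum(nr) * 2
  if (file.info(path)$size < expected)
    stop("truncated EDF file: expected ", expected, " bytes, found ",
         file.info(path)$size)
  rate <- nr[1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, ns, n_records * nr[1])
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < nr[i]) stop("truncated EDF data record ", rec)
      data[i, ((rec - 1) * nr[i] + 1):(rec * nr[i])] <- dig * gain[i] + offset[i]
    }
  }
  ann <- NULL
  side <- paste0(path, ".annotations.csv")
  if (file.exists(side)) ann <- utils::read.csv(side)
  recording(data, rate, channel_names = labels, annotations = ann,
            subject_id = sub("\\.edf$", "", basename(path)))
}

#' Write a recording as a plain 16-bit EDF file
#'
#' Internal-quality writer used to build synthetic EDF fixtures in code;
#' signals are scaled to the int16 range per channel. Annotations, if any,
#' are written to the `<path>.annotations.csv` sidecar.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param record_dur Data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_dur = 1) {
  C <- nrow(rec$data); Tn <- ncol(rec$data)
  nr <- as.integer(round(rec$sample_rate * record_dur))
  n_records <- Tn %/% nr
  stopifnot(n_records >= 1)
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- formatC(as.character(x), width = -n)
    writeChar(substr(s, 1, n), con, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 * (1 + C), 8); pad("", 44)
  pad(n_records, 8); pad(format(record_dur), 8); pad(C, 4)
  for (i in seq_len(C)) pad(rec$channel_names[i], 16)
  for (i in seq_len(C)) pad("", 80)
  for (i in seq_len(C)) pad("uV", 8)
  for (i in seq_len(C)) pad(formatC(pmin_[i], digits = 4, format = "g"), 8)
  for (i in seq_len(C)) pad(formatC(pmax_[i], digits = 4, format = "g"), 8)
  for (i in seq_len(C)) pad(-32768, 8)
  for (i in seq_len(C)) pad(32767, 8)
  for (i in seq_len(C)) pad("", 80)
  for (i in seq_len(C)) pad(nr, 8)
  for (i in seq_len(C)) pad("", 32)
  pmin_r <- as.numeric(formatC(pmin_, digits = 4, format = "g"))
  pmax_r <- as.numeric(formatC(pmax_, digits = 4, format = "g"))
  gain <- (pmax_r - pmin_r) / 65535
  for (recd in seq_len(n_records)) {
    for (i in seq_len(C)) {
      x <- rec$data[i, ((recd - 1) * nr + 1):(recd * nr)]
      dig <- as.integer(round((x - pmin_r[i]) / gain[i]) - 32768)
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  if (nrow(rec$annotations) > 0)
    utils::write.csv(rec$annotations, paste0(path, ".annotations.csv"),
                     row.names = FALSE)
  invisible(path)
}

## ---- fixture format -----------------------------------------------------

#' Write a recording to the fixture directory format
#'
#' `signals.csv.gz` holds one row per channel; `meta.json` the rate, channel
#' names and subject id; `annotations.csv` the annotation track (if any).
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_fixture <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- gzfile(file.path(dir, "signals.csv.gz"), "w")
  utils::write.table(rec$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  jsonlite::write_json(list(kind = "recording", sample_rate = rec$sample_rate,
                            channel_names = rec$channel_names,
                            subject_id = rec$subject_id),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (nrow(rec$annotations) > 0)
    utils::write.csv(rec$annotations, file.path(dir, "annotations.csv"),
                     row.names = FALSE)
  invisible(dir)
}

read_recording_fixture <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a fixture directory (no meta.json): ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (identical(meta$kind, "fragments"))
    stop("fixture at ", dir, " holds fragments; use read_fragments()")
  data <- as.matrix(utils::read.table(
    gzfile(file.path(dir, "signals.csv.gz")), sep = ","))
  dimnames(data) <- NULL
  ann_path <- file.path(dir, "annotations.csv")
  ann <- if (file.exists(ann_path)) utils::read.csv(ann_path) else NULL
  recording(data, meta$sample_rate, channel_names = meta$channel_names,
            annotations = ann, subject_id = meta$subject_id)
}

#' Write a fragment dataset to the fixture directory format
#'
#' `signals.csv.gz` holds one row per (fragment, channel); `index.csv` the
#' tabular index (fragment_id, subject_id, label, fragment_index);
#' `meta.json` the dimensions.
#'
#' @param fs A `fragment_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fragments <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- length(fs$fragments)
  d <- dim(fs$fragments[[1]])
  mat <- do.call(rbind, fs$fragments)           # (N*C) x n, fragment-major
  con <- gzfile(file.path(dir, "signals.csv.gz"), "w")
  utils::write.table(mat, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.csv(data.frame(fragment_id = seq_len(N),
                              subject_id = fs$subject, label = fs$label,
                              fragment_index = fs$fragment_index),
                   file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(list(kind = "fragments", n_channels = d[1],
                            fragment_len = d[2], n_fragments = N),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fragment dataset from a fixture directory
#'
#' @param dir Directory written by [write_fragments()].
#' @return A `fragment_set`.
#' @export
read_fragments <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$kind, "fragments"))
    stop("fixture at ", dir, " is not a fragment archive")
  mat <- as.matrix(utils::read.table(
    gzfile(file.path(dir, "signals.csv.gz")), sep = ","))
  dimnames(mat) <- NULL
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  C <- meta$n_channels
  frags <- lapply(seq_len(meta$n_fragments), function(i)
    mat[((i - 1) * C + 1):(i * C), , drop = FALSE])
  structure(list(fragments = frags, label = idx$label,
                 subject = idx$subject_id, fragment_index = idx$fragment_index,
                 cfg = NULL),
            class = "fragment_set")
}

## ---- segmentation -------------------------------------------------------

#' Segment a recording into labeled fragments
#'
#' Cuts half-open windows `[t, t + window_s)` starting at 0, `step_s` apart;
#' a trailing partial window is dropped. A fragment is labeled with an
#' annotation's class when at least `overlap` of the window lies inside that
#' annotated interval (ties between annotations: the earliest wins);
#' otherwise it gets the background class 1.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds; `window_s * sample_rate` must be
#'   a whole number of samples >= 1.
#' @param step_s Step between window starts in seconds.
#' @param overlap Minimal overlap fraction for a positive label (default 0.5).
#' @return A `fragment_set` (possibly empty if the recording is shorter than
#'   one window).
#' @export
segment <- function(rec, window_s, step_s = window_s, overlap = 0.5) {
  win <- window_s * rec$sample_rate
  if (abs(win - round(win)) > 1e-9 || round(win) < 1)
    stop("window_s * sample_rate must be an integer >= 1")
  win <- as.integer(round(win))
  step <- as.integer(round(step_s * rec$sample_rate))
  stopifnot(step >= 1)
  Tn <- ncol(rec$data)
  starts <- seq(1L, by = step, length.out = max(0L, (Tn - win) %/% step + 1L))
  if (Tn < win) starts <- integer(0)
  frags <- vector("list", length(starts))
  labels <- integer(length(starts))
  for (j in seq_along(starts)) {
    s0 <- starts[j]
    frags[[j]] <- rec$data[, s0:(s0 + win - 1L), drop = FALSE]
    t0 <- (s0 - 1L) / rec$sample_rate
    t1 <- t0 + window_s
    lab <- 1L
    if (nrow(rec$annotations) > 0) {
      ov <- pmin(t1, rec$annotations$end_s) - pmax(t0, rec$annotations$start_s)
      hit <- which(ov / window_s >= overlap - 1e-12)
      if (length(hit) > 0) lab <- as.integer(rec$annotations$label[hit[1]])
    }
    labels[j] <- lab
  }
  structure(list(fragments = frags, label = labels,
                 subject = rep(rec$subject_id, length(starts)),
                 fragment_index = seq_along(starts), cfg = NULL),
            class = "fragment_set")
}

## ---- STFT features ------------------------------------------------------

#' Short-time Fourier transform features of one fragment
#'
#' Per channel: Hann-tapered frames of `window` samples every `hop` samples
#' (frames lying fully inside the fragment), one-sided magnitude spectrum per
#' frame with the orthonormal scaling `|fft(x * w)| / sqrt(window)`,
#' optionally `log(1 + .)`, flattened time-major (frame 1's bins, then frame
#' 2's, ...) into one fixed-length vector per channel. Deterministic and
#' shape-stable: fragments of equal length give equal-shape outputs.
#'
#' @param x C x n matrix (one fragment), or a numeric vector (one channel).
#' @param window Frame length in samples (<= n).
#' @param hop Hop between frame starts (>= 1).
#' @param log_scale Apply `log1p` to the magnitudes (default TRUE).
#' @return A `feature_tensor`: list with `values` (C x m matrix), `layout =
#'   "stft_flat"` and `meta` (window, hop, n_bins, n_frames, log_scale).
#' @export
stft_features <- function(x, window = NULL, hop = NULL, log_scale = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  n <- ncol(x)
  if (is.null(window)) window <- max(4L, n %/% 4L)
  if (is.null(hop)) hop <- max(1L, window %/% 2L)
  stopifnot(window <= n, hop >= 1)
  taper <- as.numeric(signal::hanning(window))
  starts <- seq(1L, n - window + 1L, by = hop)
  n_bins <- window %/% 2L + 1L
  vals <- t(apply(x, 1, function(ch) {
    feats <- vapply(starts, function(s0) {
      fr <- ch[s0:(s0 + window - 1L)] * taper
      Mod(stats::fft(fr))[1:n_bins] / sqrt(window)
    }, numeric(n_bins))
    as.numeric(feats)                       # column-major: bins within frame,
  }))                                       # frames consecutive (time-major)
  if (log_scale) vals <- log1p(vals)
  if (!all(is.finite(vals))) stop("non-finite STFT feature")
  structure(list(values = vals, layout = "stft_flat",
                 meta = list(window = window, hop = hop, n_bins = n_bins,
                             n_frames = length(starts), log_scale = log_scale)),
            class = "feature_tensor")
}

#' Apply STFT preprocessing to every fragment of a dataset
#'
#' @param fs A `fragment_set`.
#' @inheritParams stft_features
#' @return A `fragment_set` whose fragments are the C x m STFT feature
#'   matrices.
#' @export
stft_dataset <- function(fs, window = NULL, hop = NULL, log_scale = TRUE) {
  frags <- lapply(fs$fragments, function(f)
    stft_features(f, window, hop, log_scale)$values)
  out <- fs
  out$fragments <- frags
  out
}
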