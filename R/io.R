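# Shared data model and standard-format I/O.
#
# Conventions used throughout the package:
#   * time is continuous seconds; sample indices are 0-based, so a sample
#     index k corresponds to time k / sfreq
#   * signal amplitudes are microvolts
#   * epochs keep window endpoints inclusive: a window [t0, t1] at sampling
#     rate fs has round((t1 - t0) * fs) + 1 samples, symmetric around the
#     lock sample

#' Continuous multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sfreq sampling frequency in Hz.
#' @param ch_names character vector of unique channel names, one per row.
#' @param positions optional data.frame of 3-D channel coordinates with
#'   columns `name`, `x`, `y`, `z`.
#' @param reference reference scheme label (e.g. the recording reference
#'   electrode, `"linked-mastoids"` or `"common-average"`).
#' @return object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, sfreq, ch_names,
                           positions = NULL, reference = "recording") {
  data <- as.matrix(data)
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("sfreq must be a single positive number")
  if (length(ch_names) != nrow(data))
    stop("ch_names must have one entry per data row")
  if (anyDuplicated(ch_names)) stop("channel names must be unique")
  if (!all(is.finite(data))) stop("data must be finite")
  rownames(data) <- ch_names
  structure(list(data = data, sfreq = sfreq, ch_names = as.character(ch_names),
                 positions = positions, reference = reference),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq, x$reference))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param eeg a `continuous_eeg`.
#' @return integer sample count.
#' @export
n_samples <- function(eeg) ncol(eeg$data)

#' Per-sample hypnogram and artifact mask
#'
#' @param stage character or factor vector of sleep stages, one per sample,
#'   with levels among `W`, `N1`, `N2`, `N3`, `REM`.
#' @param movement logical vector flagging movement/artifact samples.
#' @return object of class `hypnogram_mask`.
#' @export
hypnogram_mask <- function(stage, movement = rep(FALSE, length(stage))) {
  stage <- factor(as.character(stage), levels = c("W", "N1", "N2", "N3", "REM"))
  if (anyNA(stage)) stop("unknown sleep stage label")
  if (length(movement) != length(stage))
    stop("movement flag must match stage length")
  structure(list(stage = stage, movement = as.logical(movement)),
            class = "hypnogram_mask")
}

# logical vector: movement-free N2/N3 samples
nrem_clean <- function(mask) {
  mask$stage %in% c("N2", "N3") & !mask$movement
}

#' Expand a 30-s epoch hypnogram to a per-sample mask
#'
#' Standard sleep scoring assigns one stage per 30-s epoch; this expands such
#' a scoring to the per-sample mask the detectors consume.
#'
#' @param stages character vector, one stage per scoring epoch.
#' @param sfreq sampling rate of the recording in Hz.
#' @param n_samples total sample count to produce (the last epoch is
#'   truncated or the final stage extended as needed).
#' @param epoch_s scoring epoch length in seconds (default 30).
#' @param movement optional logical per scoring epoch.
#' @return a [hypnogram_mask()].
#' @export
expand_hypnogram <- function(stages, sfreq, n_samples, epoch_s = 30,
                             movement = NULL) {
  per <- round(epoch_s * sfreq)
  stage <- rep(stages, each = per)[seq_len(n_samples)]
  if (length(stage) < n_samples)
    stage <- c(stage, rep(stages[length(stages)], n_samples - length(stage)))
  mv <- if (is.null(movement)) rep(FALSE, n_samples)
        else rep(movement, each = per)[seq_len(n_samples)]
  mv[is.na(mv)] <- FALSE
  hypnogram_mask(stage, mv)
}

#' Set of fixed-length epochs cut from a recording
#'
#' @param data numeric array, events x channels x time, microvolts (or
#'   component units after PCA).
#' @param times numeric vector of times in seconds relative to the lock
#'   point, strictly increasing with uniform step.
#' @param sfreq sampling frequency in Hz.
#' @param ch_names character vector of channel (or component) names.
#' @param lock lock-point label, e.g. `"stimulus-onset"`, `"SO-downstate"`.
#' @param labels optional per-event category labels.
#' @param participant,session optional identifiers carried along.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, ch_names,
                      lock = "stimulus-onset", labels = NULL,
                      participant = NA, session = NA) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be events x channels x time")
  if (length(times) != dim(data)[3]) stop("times must match the time axis")
  if (length(ch_names) != dim(data)[2]) stop("ch_names must match channels")
  if (!is.null(labels) && length(labels) != dim(data)[1])
    stop("labels must have one entry per event")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    stop("times must be strictly increasing with uniform step")
  structure(list(data = data, times = as.numeric(times), sfreq = sfreq,
                 ch_names = as.character(ch_names), lock = lock,
                 labels = labels, participant = participant, session = session),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d events x %d channels x %d samples @ %g Hz, locked to %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq, x$lock))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in an epoch set
#' @param epochs an `epoch_set`.
#' @return integer event count.
#' @export
n_events <- function(epochs) dim(epochs$data)[1]

#' Select channels from a recording
#' @param eeg a `continuous_eeg`.
#' @param channels channel names to keep, in the requested order.
#' @return a `continuous_eeg` restricted to `channels`.
#' @export
pick_channels <- function(eeg, channels) {
  miss <- setdiff(channels, eeg$ch_names)
  if (length(miss))
    stop("channel(s) not found: ", paste(miss, collapse = ", "),
         "; available: ", paste(eeg$ch_names, collapse = ", "))
  idx <- match(channels, eeg$ch_names)
  out <- continuous_eeg(eeg$data[idx, , drop = FALSE], eeg$sfreq,
                        eeg$ch_names[idx],
                        positions = eeg$positions, reference = eeg$reference)
  attr(out, "history") <- attr(eeg, "history")
  add_history(out, paste0("pick_channels(", paste(channels, collapse = ","), ")"))
}

# ---------------------------------------------------------------------------
# EDF (European Data Format) reader/writer
#
# Minimal EDF support: one continuous recording, identical sampling rate for
# all signals, 16-bit integer samples with per-signal physical scaling.
# Record duration is 1 s, which requires an integer sampling rate.

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to an EDF file
#'
#' @param eeg a [continuous_eeg()].
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly. The quantization step per channel (physical
#'   range / 65535) is attached as attribute `"quantization"`.
#' @export
write_edf <- function(eeg, path) {
  fs <- eeg$sfreq
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf() requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nc <- nrow(eeg$data)
  ns <- ncol(eeg$data)
  n_rec <- as.integer(ceiling(ns / fs))
  pad <- n_rec * fs - ns
  x <- eeg$data
  if (pad > 0) x <- cbind(x, matrix(0, nc, pad))
  # physical scaling per channel
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256L * (nc + 1L)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(nc), 4)
  for (i in seq_len(nc)) wr(eeg$ch_names[i], 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(sprintf("%.8g", pmin_[i]), 8)
  for (i in seq_len(nc)) wr(sprintf("%.8g", pmax_[i]), 8)
  for (i in seq_len(nc)) wr(as.character(dmin), 8)
  for (i in seq_len(nc)) wr(as.character(dmax), 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(as.character(fs), 8)
  for (i in seq_len(nc)) wr("", 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nc)) {
      dig <- round((x[i, cols] - pmin_[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(structure(path, quantization = gain))
}

#' Read an EDF file
#'
#' @param path path to an EDF file.
#' @return a [continuous_eeg()]; all signals must share one sampling rate.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("not an EDF file (unknown version field)")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)           # transducer
  units <- vapply(seq_len(nc), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)           # prefilter
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf() supports a single common sampling rate only")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     signed = TRUE, endian = "little")
      out[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dmin[i]) * gain[i] + pmin_[i]
    }
  }
  eeg <- continuous_eeg(out, fs, labels)
  add_history(eeg, sprintf("read_edf(%s)", basename(path)))
}

# ---------------------------------------------------------------------------
# BrainVision (.vhdr/.vmrk/.eeg) reader/writer: multiplexed IEEE float32.

#' Write a recording as a BrainVision triplet
#'
#' @param eeg a [continuous_eeg()].
#' @param path path of the header file (`.vhdr`); the `.eeg` and `.vmrk`
#'   members are written next to it.
#' @return the header path, invisibly.
#' @export
write_brainvision <- function(eeg, path) {
  stem <- sub("\\.vhdr$", "", path)
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(eeg$data)),
    sprintf("SamplingInterval=%.6f", 1e6 / eeg$sfreq),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(eeg$data)), eeg$ch_names))
  writeLines(hdr, paste0(stem, ".vhdr"), useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", paste0("DataFile=", base, ".eeg"),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,00000000000000000000"),
             paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(eeg$data), con, size = 4L, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

#' Read a BrainVision recording
#'
#' @param path path to the `.vhdr` header; the binary `.eeg` member named in
#'   the header must be present next to it.
#' @return a [continuous_eeg()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  getval <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) stop("header field missing: ", key)
    sub(paste0("^", key, "="), "", ln[1])
  }
  datafile <- file.path(dirname(path), getval("DataFile"))
  if (!file.exists(datafile))
    stop("missing BrainVision member: ", basename(datafile),
         " (named by DataFile in ", basename(path), ")")
  if (toupper(getval("DataFormat")) != "BINARY" ||
      toupper(getval("DataOrientation")) != "MULTIPLEXED")
    stop("only BINARY / MULTIPLEXED BrainVision data are supported")
  fmt <- toupper(getval("BinaryFormat"))
  if (fmt != "IEEE_FLOAT_32")
    stop("unsupported BinaryFormat: ", fmt)
  nc <- as.integer(getval("NumberOfChannels"))
  si <- as.numeric(getval("SamplingInterval"))
  fs <- 1e6 / si
  ch <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch), ","),
                     `[`, "", 1L)[seq_len(nc)]
  sz <- file.info(datafile)$size
  n <- as.integer(sz / 4L / nc)
  con <- file(datafile, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n * nc, size = 4L, endian = "little")
  eeg <- continuous_eeg(matrix(x, nrow = nc), fs, ch_names)
  add_history(eeg, sprintf("read_brainvision(%s)", basename(path)))
}

#' Read an EEG recording, dispatching on format
#'
#' @param path path to an `.edf` or `.vhdr` file.
#' @param format `"EDF"`, `"BrainVision"`, or `"auto"` (by extension).
#' @return a [continuous_eeg()].
#' @export
read_eeg <- function(path, format = c("auto", "EDF", "BrainVision")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "EDF", vhdr = "BrainVision",
                     stop("unknown EEG format for extension '.", ext,
                          "'; expected .edf or .vhdr"))
  }
  switch(format, EDF = read_edf(path), BrainVision = read_brainvision(path))
}

# ---------------------------------------------------------------------------
# resampling / re-referencing / epoching

#' Downsample a recording with anti-alias filtering
#'
#' A zero-phase FIR low-pass (cut-off at 80% of the new Nyquist frequency) is
#' applied, then the signal is linearly interpolated onto the new time grid.
#' The output has `floor((n - 1) * target / sfreq) + 1` samples, i.e. the
#' grid spans the same time range.
#'
#' @param eeg a [continuous_eeg()].
#' @param target_sfreq new sampling rate; must not exceed the current rate.
#' @return a resampled `continuous_eeg`.
#' @export
resample_eeg <- function(eeg, target_sfreq) {
  if (target_sfreq > eeg$sfreq)
    stop("upsampling requested (", target_sfreq, " > ", eeg$sfreq,
         " Hz); resample_eeg() only downsamples")
  if (abs(target_sfreq - eeg$sfreq) < 1e-9) return(eeg)
  n <- ncol(eeg$data)
  t_old <- (seq_len(n) - 1L) / eeg$sfreq
  n_new <- floor((n - 1L) * target_sfreq / eeg$sfreq) + 1L
  t_new <- (seq_len(n_new) - 1L) / target_sfreq
  out <- matrix(0, nrow(eeg$data), n_new)
  for (i in seq_len(nrow(eeg$data))) {
    filt <- fft_lowpass(eeg$data[i, ], eeg$sfreq,
                        pass = 0.8 * target_sfreq / 2,
                        stop = target_sfreq / 2)
    out[i, ] <- stats::approx(t_old, filt, xout = t_new)$y
  }
  res <- continuous_eeg(out, target_sfreq, eeg$ch_names,
                        positions = eeg$positions, reference = eeg$reference)
  attr(res, "history") <- attr(eeg, "history")
  add_history(res, sprintf("resample(%g->%g Hz)", eeg$sfreq, target_sfreq))
}

#' Resample a hypnogram mask by nearest stage label
#'
#' @param mask a [hypnogram_mask()] sampled at `sfreq`.
#' @param sfreq original sampling rate.
#' @param target_sfreq new sampling rate.
#' @param n_new number of samples of the resampled recording.
#' @return a `hypnogram_mask` of length `n_new`.
#' @export
resample_mask <- function(mask, sfreq, target_sfreq, n_new) {
  idx <- pmin(round((seq_len(n_new) - 1L) / target_sfreq * sfreq) + 1L,
              length(mask$stage))
  hypnogram_mask(mask$stage[idx], mask$movement[idx])
}

#' Re-reference a recording
#'
#' `linked-mastoids` subtracts the mean of the two mastoid channels from
#' every channel; `common-average` subtracts the per-sample mean over all
#' scalp channels (mastoids, if present, are excluded from the average but
#' kept in the output).
#'
#' @param eeg a [continuous_eeg()].
#' @param scheme `"linked-mastoids"` or `"common-average"`.
#' @param mastoids names of the two mastoid channels.
#' @return a re-referenced `continuous_eeg`.
#' @export
rereference <- function(eeg, scheme = c("linked-mastoids", "common-average"),
                        mastoids = c("M1", "M2")) {
  scheme <- match.arg(scheme)
  x <- eeg$data
  if (scheme == "linked-mastoids") {
    miss <- setdiff(mastoids, eeg$ch_names)
    if (length(miss))
      stop("mastoid channel(s) missing: ", paste(miss, collapse = ", "),
           "; available channels: ", paste(eeg$ch_names, collapse = ", "))
    ref <- colMeans(x[mastoids, , drop = FALSE])
    x <- sweep(x, 2L, ref, "-")
  } else {
    scalp <- setdiff(eeg$ch_names, mastoids)
    ref <- colMeans(x[scalp, , drop = FALSE])
    x <- sweep(x, 2L, ref, "-")
  }
  out <- continuous_eeg(x, eeg$sfreq, eeg$ch_names,
                        positions = eeg$positions, reference = scheme)
  attr(out, "history") <- attr(eeg, "history")
  add_history(out, paste0("rereference(", scheme, ")"))
}

#' Cut fixed-length epochs around lock times
#'
#' Each epoch spans `window[1]` to `window[2]` seconds around its lock time
#' with both endpoints included, i.e. `round(diff(window) * sfreq) + 1`
#' samples. Events whose window would exceed the recording are dropped with a
#' message; their indices are attached as attribute `"dropped"`.
#'
#' @param eeg a [continuous_eeg()].
#' @param lock_times numeric vector of lock times in seconds.
#' @param window length-2 numeric, window start/end relative to lock (s).
#' @param lock label describing the lock point.
#' @param labels optional per-event labels (subset along with kept events).
#' @return an [epoch_set()] (possibly with zero events).
#' @export
extract_epochs <- function(eeg, lock_times, window, lock = "event",
                           labels = NULL) {
  fs <- eeg$sfreq
  n_t <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  rel <- seq_len(n_t) - 1L + as.integer(round(window[1] * fs))
  times <- rel / fs
  n <- ncol(eeg$data)
  lock_idx <- as.integer(round(lock_times * fs))        # 0-based
  first <- lock_idx + rel[1L]
  last <- lock_idx + rel[n_t]
  keep <- which(first >= 0L & last <= n - 1L)
  if (length(keep) < length(lock_times))
    message(length(lock_times) - length(keep),
            " event(s) dropped: window exceeds recording bounds")
  dat <- array(0, dim = c(length(keep), nrow(eeg$data), n_t))
  for (j in seq_along(keep)) {
    cols <- (lock_idx[keep[j]] + rel) + 1L
    dat[j, , ] <- eeg$data[, cols, drop = FALSE]
  }
  out <- epoch_set(dat, times, fs, eeg$ch_names, lock = lock,
                   labels = if (is.null(labels)) NULL else labels[keep])
  attr(out, "dropped") <- setdiff(seq_along(lock_times), keep)
  attr(out, "history") <- c(attr(eeg, "history"),
                            sprintf("extract_epochs([%g,%g] s, n=%d)",
                                    window[1], window[2], length(keep)))
  out
}

# ---------------------------------------------------------------------------
# tabular I/O

#' Write / read an event or behavior table as TSV
#'
#' Plain tab-separated files with a header row; the standard on-disk form
#' for event tables and behavior count tables.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write an epoch set as a flat TSV plus JSON sidecar
#'
#' The array is flattened to one row per (event, channel) with one column per
#' time sample; axes, labels, lock point and sampling rate go to a `.json`
#' sidecar next to the data file.
#'
#' @param epochs an [epoch_set()].
#' @param stem output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), ncol = d[3],
                 byrow = TRUE)
  df <- data.frame(event = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(epochs$ch_names, d[1]))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- sprintf("t%d", seq_len(d[3]))
  write_tsv(df, paste0(stem, ".tsv"))
  meta <- list(times = epochs$times, sfreq = epochs$sfreq,
               ch_names = epochs$ch_names, lock = epochs$lock,
               labels = epochs$labels, participant = epochs$participant,
               session = epochs$session)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read an epoch set written by [write_epochs()]
#' @param stem path stem used when writing.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- read_tsv(paste0(stem, ".tsv"))
  n_ev <- max(df$event)
  n_ch <- length(meta$ch_names)
  n_t <- length(meta$times)
  arr <- array(0, dim = c(n_ev, n_ch, n_t))
  vals <- as.matrix(df[, -(1:2)])
  for (e in seq_len(n_ev))
    arr[e, , ] <- vals[df$event == e, , drop = FALSE]
  epoch_set(arr, meta$times, meta$sfreq, meta$ch_names, lock = meta$lock,
            labels = meta$labels,
            participant = meta$participant %||% NA,
            session = meta$session %||% NA)
}
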