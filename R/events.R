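# Detection of slow oscillations (SOs), sleep spindles and SO-spindle
# complexes on the NREM-masked signal, plus a Hanning-taper time-frequency
# map of event-locked epochs.
#
# Filter convention: the two-pass ("zero-phase") FIR band-pass uses a tap
# count equal to three cycles of the low cut-off frequency, applied forward
# and backward, matching the convention common in EEG toolboxes.

# Zero-phase FIR filtering: forward-backward application of FIR coefficients
# b via overlap-free FFT convolution, with edge padding by reflection.
fir_filtfilt <- function(x, b) {
  nb <- length(b)
  n <- length(x)
  pad <- min(nb, n - 1L)
  xx <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  one_pass <- function(v) {
    y <- signal::fftfilt(b, c(v, numeric(nb)))
    # compensate the filter's group delay of (nb - 1) / 2 samples
    y[((nb - 1L) %/% 2L + 1L):((nb - 1L) %/% 2L + length(v))]
  }
  y <- one_pass(xx)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

# FIR band-pass with tap count = three cycles of the low cut-off.
fir_bandpass <- function(x, sfreq, band) {
  ntaps <- as.integer(round(3 / band[1] * sfreq))
  if (ntaps %% 2L == 1L) ntaps <- ntaps + 1L    # even order -> odd tap count
  b <- signal::fir1(ntaps, band / (sfreq / 2), type = "pass")
  fir_filtfilt(x, b)
}

# Zero-phase Butterworth band-pass (two-pass; default order 2 per pass).
butter_bandpass <- function(x, sfreq, band, order = 2L) {
  bf <- signal::butter(order, band / (sfreq / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# contiguous runs of movement-free N2/N3 samples, as 1-based index ranges
nrem_segments <- function(mask) true_runs(nrem_clean(mask))

#' Detect slow oscillations
#'
#' The target channel is band-pass filtered between `band[1]` and `band[2]`
#' Hz (two-pass FIR, tap count three cycles of the low cut-off). Within each
#' contiguous run of movement-free N2/N3 samples, candidate events are the
#' spans between successive positive-to-negative zero crossings of the
#' filtered trace that contain a trough followed by a peak. Candidates are
#' kept when their duration lies within `duration_range`. An amplitude
#' criterion then rejects low-amplitude candidates: the default
#' (`"absolute"`) requires a trough-to-peak amplitude of at least
#' `amplitude_threshold` microvolts (75 uV, a canonical minimum for SO
#' detectors); `"mean1.25"` instead keeps events reaching
#' `amplitude_factor` times the mean trough-to-peak amplitude of all
#' duration-valid candidates, `"percentile"` applies a percentile cut, and
#' `"none"` disables the amplitude criterion entirely (pure duration-based
#' detection, useful when validating the zero-crossing logic itself).
#'
#' @param eeg a [continuous_eeg()] (linked-mastoid referenced, typically).
#' @param mask a [hypnogram_mask()] aligned to `eeg`.
#' @param channel channel to detect on (default `"Cz"`).
#' @param band SO filter band in Hz.
#' @param duration_range admissible event duration in seconds.
#' @param amplitude_criterion `"absolute"`, `"mean1.25"`, `"percentile"` or
#'   `"none"`.
#' @param amplitude_threshold trough-to-peak threshold in microvolts for
#'   the `"absolute"` criterion.
#' @param amplitude_factor multiplier for the `"mean1.25"` criterion.
#' @param amplitude_percentile percentile for the `"percentile"` criterion.
#' @return data.frame with one row per SO: `start`, `downstate`, `upstate`,
#'   `end` (seconds), `duration`, `trough_amplitude` and `p2p_amplitude`
#'   (microvolts, from the filtered trace). The filtered trace is attached as
#'   attribute `"filtered"`.
#' @export
detect_slow_oscillations <- function(eeg, mask, channel = "Cz",
                                     band = c(0.3, 1.25),
                                     duration_range = c(0.8, 2),
                                     amplitude_criterion = c("absolute",
                                                             "mean1.25",
                                                             "percentile",
                                                             "none"),
                                     amplitude_threshold = 75,
                                     amplitude_factor = 1.25,
                                     amplitude_percentile = 0.75) {
  amplitude_criterion <- match.arg(amplitude_criterion)
  if (!channel %in% eeg$ch_names) stop("channel not found: ", channel)
  if (length(mask$stage) != ncol(eeg$data))
    stop("mask length does not match recording")
  fs <- eeg$sfreq
  x <- fir_bandpass(eeg$data[channel, ], fs, band)
  segs <- nrem_segments(mask)
  empty <- data.frame(start = numeric(0), downstate = numeric(0),
                      upstate = numeric(0), end = numeric(0),
                      duration = numeric(0), trough_amplitude = numeric(0),
                      p2p_amplitude = numeric(0))
  if (!nrow(segs)) {
    warning("no movement-free N2/N3 samples; returning 0 events")
    return(structure(empty, filtered = x))
  }
  rows <- list()
  for (s in seq_len(nrow(segs))) {
    seg <- x[segs$start[s]:segs$end[s]]
    if (length(seg) < fs) next
    pos2neg <- which(seg[-length(seg)] > 0 & seg[-1L] <= 0)
    if (length(pos2neg) < 2L) next
    for (k in seq_len(length(pos2neg) - 1L)) {
      i0 <- pos2neg[k]
      i1 <- pos2neg[k + 1L]
      dur <- (i1 - i0) / fs
      if (dur < duration_range[1] || dur > duration_range[2]) next
      span <- seg[i0:i1]
      i_min <- which.min(span)
      i_max <- which.max(span)
      if (!(i_min < i_max)) next                    # trough must precede peak
      off <- segs$start[s] + i0 - 2L                # 0-based sample of i0
      rows[[length(rows) + 1L]] <- data.frame(
        start = off / fs,
        downstate = (off + i_min - 1L) / fs,
        upstate = (off + i_max - 1L) / fs,
        end = (off + i1 - i0) / fs,
        duration = dur,
        trough_amplitude = span[i_min],
        p2p_amplitude = span[i_max] - span[i_min])
    }
  }
  if (!length(rows)) return(structure(empty, filtered = x))
  ev <- do.call(rbind, rows)
  if (amplitude_criterion == "absolute") {
    ev <- ev[ev$p2p_amplitude >= amplitude_threshold, , drop = FALSE]
  } else if (amplitude_criterion == "mean1.25") {
    thr <- amplitude_factor * mean(ev$p2p_amplitude)
    ev <- ev[ev$p2p_amplitude >= thr, , drop = FALSE]
  } else if (amplitude_criterion == "percentile") {
    thr <- stats::quantile(ev$p2p_amplitude, amplitude_percentile, names = FALSE)
    ev <- ev[ev$p2p_amplitude >= thr, , drop = FALSE]
  }
  rownames(ev) <- NULL
  structure(ev, filtered = x)
}

#' Detect sleep spindles
#'
#' The target channel is band-pass filtered in the spindle band (two-pass
#' FIR, tap count three cycles of the low cut-off). A root-mean-square (RMS)
#' envelope is computed in centered 200-ms windows stepped sample-by-sample
#' over each contiguous run of movement-free N2/N3 data; the amplitude
#' criterion is the 75th percentile (linear interpolation between order
#' statistics) of all pooled N2/N3 RMS values. Spindles are supra-threshold
#' runs lasting more than `duration_range[1]` and less than
#' `duration_range[2]` seconds. A dual-threshold rule additionally requires
#' the RMS peak of each event to exceed `peak_factor` times the detection
#' threshold, which discriminates genuine spindle bursts from slow
#' background-envelope excursions (set `peak_factor = 0` to disable).
#'
#' @param eeg a [continuous_eeg()].
#' @param mask a [hypnogram_mask()] aligned to `eeg`.
#' @param channel channel to detect on (default `"Cz"`).
#' @param band spindle band in Hz.
#' @param duration_range open interval of admissible durations (s).
#' @param rms_window RMS moving-average window in seconds.
#' @param threshold_percentile percentile of the pooled RMS distribution.
#' @param peak_factor multiple of the detection threshold the event's RMS
#'   peak must reach (0 disables the secondary criterion).
#' @return data.frame with one row per spindle: `onset`, `offset`,
#'   `duration`, `trough` (time of the filtered-signal minimum within the
#'   event), `peak_rms` and `amplitude_peak_time` (time of the RMS-envelope
#'   maximum). The RMS threshold is attached as attribute `"threshold"`, the
#'   pooled RMS values as `"rms_values"`.
#' @export
detect_spindles <- function(eeg, mask, channel = "Cz", band = c(12, 18),
                            duration_range = c(0.5, 3), rms_window = 0.2,
                            threshold_percentile = 0.75, peak_factor = 2) {
  if (!channel %in% eeg$ch_names) stop("channel not found: ", channel)
  if (length(mask$stage) != ncol(eeg$data))
    stop("mask length does not match recording")
  fs <- eeg$sfreq
  win <- as.integer(round(rms_window * fs))
  x <- fir_bandpass(eeg$data[channel, ], fs, band)
  segs <- nrem_segments(mask)
  segs <- segs[segs$end - segs$start + 1L >= win, , drop = FALSE]
  if (!nrow(segs))
    stop("N2/N3 data shorter than one RMS window (", rms_window, " s)")
  half <- (win - 1L) %/% 2L
  seg_rms <- vector("list", nrow(segs))
  seg_off <- integer(nrow(segs))            # 0-based offset of rms[1]
  for (s in seq_len(nrow(segs))) {
    r <- sqrt(moving_average(x[segs$start[s]:segs$end[s]]^2, win))
    # keep only centers whose full window lies inside the segment
    keep <- (half + 1L):(length(r) - half)
    seg_rms[[s]] <- r[keep]
    seg_off[s] <- segs$start[s] - 1L + half
  }
  seg_rms <- seg_rms[lengths(seg_rms) > 0L]
  seg_off <- seg_off[seq_along(seg_rms)]
  if (!length(seg_rms))
    stop("N2/N3 data shorter than one RMS window (", rms_window, " s)")
  thr <- stats::quantile(unlist(seg_rms), threshold_percentile,
                         names = FALSE, type = 7)
  rows <- list()
  for (s in seq_along(seg_rms)) {
    rms <- seg_rms[[s]]
    runs <- true_runs(rms > thr)
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      dur <- (runs$end[k] - runs$start[k] + 1L) / fs
      if (dur <= duration_range[1] || dur >= duration_range[2]) next
      idx <- runs$start[k]:runs$end[k]
      if (peak_factor > 0 && max(rms[idx]) < peak_factor * thr) next
      abs0 <- seg_off[s]                    # 0-based sample of rms index 1
      i_tr <- idx[which.min(x[abs0 + idx])]
      i_pk <- idx[which.max(rms[idx])]
      rows[[length(rows) + 1L]] <- data.frame(
        onset = (abs0 + idx[1L] - 1L) / fs,
        offset = (abs0 + idx[length(idx)] - 1L) / fs,
        duration = dur,
        trough = (abs0 + i_tr - 1L) / fs,
        peak_rms = max(rms[idx]),
        amplitude_peak_time = (abs0 + i_pk - 1L) / fs)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0),
               trough = numeric(0), peak_rms = numeric(0),
               amplitude_peak_time = numeric(0))
  rownames(out) <- NULL
  structure(out, threshold = thr, rms_values = unlist(seg_rms), filtered = x)
}

#' Pair slow oscillations with following spindles
#'
#' For every SO, checks whether a spindle anchor falls in the interval
#' `(downstate, downstate + window]`; if several do, the earliest is paired.
#' The anchor defaults to the spindle onset; the spindle trough or the
#' envelope-peak time can be used instead.
#'
#' @param sos SO table from [detect_slow_oscillations()].
#' @param spindles spindle table from [detect_spindles()].
#' @param window pairing window after the SO downstate, in seconds.
#' @param anchor spindle time used for pairing.
#' @return list with elements `complexes` (data.frame of paired events with
#'   columns from both tables, prefixed `so_`/`sp_`, plus `lag` in seconds),
#'   `solitary_sos` and `solitary_spindles` (the unpaired remainders).
#' @export
pair_so_spindle <- function(sos, spindles, window = 1.5,
                            anchor = c("onset", "trough",
                                       "amplitude_peak_time")) {
  anchor <- match.arg(anchor)
  n_so <- nrow(sos)
  n_sp <- nrow(spindles)
  paired_so <- logical(n_so)
  paired_sp <- logical(n_sp)
  rows <- list()
  if (n_so && n_sp) {
    a <- spindles[[anchor]]
    for (i in seq_len(n_so)) {
      lag <- a - sos$downstate[i]
      hit <- which(lag > 0 & lag <= window)
      if (!length(hit)) next
      j <- hit[which.min(lag[hit])]
      paired_so[i] <- TRUE
      paired_sp[j] <- TRUE
      so_row <- sos[i, , drop = FALSE]
      sp_row <- spindles[j, , drop = FALSE]
      names(so_row) <- paste0("so_", names(so_row))
      names(sp_row) <- paste0("sp_", names(sp_row))
      rows[[length(rows) + 1L]] <- cbind(so_row, sp_row, lag = lag[j])
    }
  }
  complexes <- if (length(rows)) do.call(rbind, rows) else {
    so_cols <- paste0("so_", names(sos))
    sp_cols <- paste0("sp_", names(spindles))
    out <- as.data.frame(matrix(numeric(0), 0,
                                length(so_cols) + length(sp_cols) + 1L))
    names(out) <- c(so_cols, sp_cols, "lag")
    out
  }
  rownames(complexes) <- NULL
  list(complexes = complexes,
       solitary_sos = sos[!paired_so, , drop = FALSE],
       solitary_spindles = spindles[!paired_sp, , drop = FALSE])
}

#' Hanning-taper time-frequency map of event-locked epochs
#'
#' Sliding-window Fourier power with a window of `n_cycles` cycles per
#' frequency, multiplied with a Hanning taper, stepped on a regular grid
#' (default 50 ms). Power is averaged over events and then z-scored across
#' time separately per frequency.
#'
#' @param epochs an [epoch_set()]; the first (or named) channel is used.
#' @param freqs frequencies in Hz (default 1-30 Hz in 1-Hz steps).
#' @param step time-grid step in seconds.
#' @param n_cycles taper length in cycles of each frequency.
#' @param channel channel name or index.
#' @param zscore z-score power across time per frequency (default TRUE).
#' @return list of class `tfr_map` with `power` (frequencies x times),
#'   `freqs` and `times`.
#' @export
tfr_hanning <- function(epochs, freqs = 1:30, step = 0.05, n_cycles = 5,
                        channel = 1L, zscore = TRUE) {
  if (is.character(channel)) channel <- match(channel, epochs$ch_names)
  fs <- epochs$sfreq
  t <- epochs$times
  half_max <- n_cycles / min(freqs) / 2
  t0 <- t[1] + half_max
  t1 <- t[length(t)] - half_max
  if (t0 > t1)
    stop("epoch too short for ", n_cycles, " cycles at ", min(freqs),
         " Hz; need at least ", n_cycles / min(freqs), " s")
  grid <- seq(ceiling(t0 / step) * step, floor(t1 / step) * step, by = step)
  n_ev <- dim(epochs$data)[1]
  pow <- matrix(0, length(freqs), length(grid))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    nwin <- as.integer(round(n_cycles / f * fs))
    taper <- signal::hanning(nwin)
    carrier <- exp(-2i * pi * f * (seq_len(nwin) - 1L) / fs)
    kern <- taper * carrier
    half <- (nwin - 1L) %/% 2L
    centers <- vapply(grid, function(g) which.min(abs(t - g)), 0L)
    for (e in seq_len(n_ev)) {
      x <- epochs$data[e, channel, ]
      for (gi in seq_along(centers)) {
        i0 <- centers[gi] - half
        idx <- i0:(i0 + nwin - 1L)
        pow[fi, gi] <- pow[fi, gi] + abs(sum(x[idx] * kern))^2
      }
    }
  }
  pow <- pow / n_ev
  if (zscore) pow <- t(scale(t(pow)))
  structure(list(power = pow, freqs = freqs, times = grid),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %d frequencies (%g-%g Hz) x %d times (%.2f to %.2f s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
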