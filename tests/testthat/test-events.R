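# SO and spindle detectors, complex pairing, time-frequency map.

test_that("SO detection matches an independent zero-crossing oracle on a sine", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  eeg <- signal_eeg(40 * sin(2 * pi * 0.75 * t), fs)
  mask <- n2_mask(eeg)
  sos <- detect_slow_oscillations(eeg, mask, amplitude_criterion = "none")
  # oracle: count positive-to-negative crossing pairs with in-range spacing
  # on the very trace the detector filtered
  x <- attr(sos, "filtered")
  p2n <- which(x[-length(x)] > 0 & x[-1] <= 0)
  gaps <- diff(p2n) / fs
  expect_identical(nrow(sos), sum(gaps >= 0.8 & gaps <= 2))
  expect_gt(nrow(sos), 30)
  expect_true(all(sos$start < sos$downstate & sos$downstate < sos$upstate &
                  sos$upstate < sos$end))
  expect_true(all(sos$duration >= 0.8 & sos$duration <= 2))
})

test_that("SO duration criteria exclude slow sinusoids and empty signals", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  slow <- signal_eeg(50 * sin(2 * pi * 0.3 * t), fs)  # period 3.3 s > 2 s
  expect_identical(nrow(detect_slow_oscillations(slow, n2_mask(slow),
                                                 amplitude_criterion = "none")),
                   0L)
  flat <- signal_eeg(numeric(2000), fs)
  expect_identical(nrow(detect_slow_oscillations(flat, n2_mask(flat))), 0L)
  # no N2/N3 at all -> empty result with a warning
  wake <- hypnogram_mask(rep("W", 2000))
  expect_warning(out <- detect_slow_oscillations(flat, wake), "N2/N3")
  expect_identical(nrow(out), 0L)
})

test_that("spindle detector finds a planted burst and rejects short runs", {
  fs <- 200
  set.seed(7)
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  burst <- function(center, dur, amp = 25) {
    env <- exp(-(t - center)^2 / (2 * (dur / 6)^2))
    env[abs(t - center) > dur / 2] <- 0           # hard support limit
    amp * env * sin(2 * pi * 14 * t)
  }
  # a single high-amplitude burst over NREM-like background: detected as
  # exactly one event (not split), with the trough at the burst center
  x <- 5 * sleepreplay:::oneoverf_noise(length(t), fs) + burst(30, 1.0)
  eeg <- signal_eeg(x, fs)
  sp <- detect_spindles(eeg, n2_mask(eeg))
  at_burst <- which(abs(sp$trough - 30) < 1)
  expect_length(at_burst, 1L)
  sp <- sp[at_burst, ]
  expect_lt(abs(sp$trough - 30), 0.05 + 1 / 14)   # trough near burst center
  expect_lt(abs(sp$amplitude_peak_time - 30), 0.06)
  expect_true(sp$onset < sp$trough & sp$trough < sp$offset)
  expect_true(sp$duration > 0.5 && sp$duration < 3)
  # a short burst whose supra-threshold run lasts ~0.4 s (0.2 s support
  # plus the RMS window) fails the duration rule
  y <- rnorm(length(t)) * 2 + burst(60, 0.2)
  eeg2 <- signal_eeg(y, fs)
  sp2 <- detect_spindles(eeg2, n2_mask(eeg2))
  expect_false(any(abs(sp2$trough - 60) < 1))
})

test_that("spindle threshold is the 75th percentile and noise yields ~no events", {
  fs <- 200
  set.seed(8)
  eeg <- signal_eeg(rnorm(120 * fs), fs)
  sp <- detect_spindles(eeg, n2_mask(eeg))
  rms <- attr(sp, "rms_values")
  expect_equal(attr(sp, "threshold"),
               stats::quantile(rms, 0.75, names = FALSE, type = 7))
  expect_equal(mean(rms > attr(sp, "threshold")), 0.25, tolerance = 0.001)
  expect_lte(nrow(sp), 2)
  # literal single-threshold rule still yields few events on white noise
  sp0 <- detect_spindles(eeg, n2_mask(eeg), peak_factor = 0)
  expect_lte(nrow(sp0), 8)
  short <- signal_eeg(rnorm(10), fs)
  expect_error(detect_spindles(short, n2_mask(short)), "RMS window")
})

test_that("SO-spindle pairing uses the (0, 1.5] s window and earliest anchor", {
  so <- data.frame(start = 9.5, downstate = 10.0, upstate = 10.6, end = 11,
                   duration = 1.5, trough_amplitude = -70,
                   p2p_amplitude = 110)
  sp <- function(onset) data.frame(onset = onset, offset = onset + 1,
                                   duration = 1, trough = onset + 0.5,
                                   peak_rms = 10,
                                   amplitude_peak_time = onset + 0.5)
  hit <- pair_so_spindle(so, sp(11.2))
  expect_identical(nrow(hit$complexes), 1L)
  expect_equal(hit$complexes$lag, 1.2)
  # beyond the window
  miss <- pair_so_spindle(so, sp(11.8))
  expect_identical(nrow(miss$complexes), 0L)
  expect_identical(nrow(miss$solitary_sos), 1L)
  # multiple candidates -> earliest wins
  two <- pair_so_spindle(so, rbind(sp(10.9), sp(10.3)))
  expect_equal(two$complexes$lag, 0.3)
  expect_identical(nrow(two$solitary_spindles), 1L)
  # empty spindle list
  none <- pair_so_spindle(so, sp(11)[0, ])
  expect_identical(nrow(none$complexes), 0L)
  expect_identical(nrow(none$solitary_sos), 1L)
})

test_that("detected events never overlap movement or non-NREM samples", {
  cfg <- test_cfg(nap_duration = 600)
  sim <- simulate_sleep_recording(cfg, 2)
  eeg <- rereference(sim$eeg, "linked-mastoids")
  ok <- sim$mask$stage %in% c("N2", "N3") & !sim$mask$movement
  sos <- detect_slow_oscillations(eeg, sim$mask)
  for (i in seq_len(nrow(sos))) {
    span <- round(sos$start[i] * cfg$sfreq):round(sos$end[i] * cfg$sfreq) + 1
    expect_true(all(ok[span]))
  }
  sp <- detect_spindles(eeg, sim$mask)
  for (i in seq_len(nrow(sp))) {
    span <- round(sp$onset[i] * cfg$sfreq):round(sp$offset[i] * cfg$sfreq) + 1
    expect_true(all(ok[span]))
  }
  cx <- pair_so_spindle(sos, sp)
  expect_lte(nrow(cx$complexes), min(nrow(sos), nrow(sp)))
  expect_true(all(cx$complexes$lag > 0 & cx$complexes$lag <= 1.5))
})

test_that("Hanning time-frequency map localizes a tone and z-scores rows", {
  fs <- 200
  n_t <- round(9 * fs) + 1
  times <- seq(-4.5, by = 1 / fs, length.out = n_t)
  dat <- array(0, dim = c(3, 1, n_t))
  set.seed(9)
  for (e in 1:3) dat[e, 1, ] <- sin(2 * pi * 14 * times + runif(1, 0, 2 * pi))
  ep <- epoch_set(dat, times, fs, "Cz")
  tfr <- tfr_hanning(ep)
  expect_identical(nrow(tfr$power), 30L)
  expect_identical(tfr$freqs, 1:30)
  # z-scored across time: per-frequency mean 0, SD 1
  expect_equal(rowMeans(tfr$power), rep(0, 30), tolerance = 1e-10)
  expect_equal(apply(tfr$power, 1, sd), rep(1, 30), tolerance = 1e-10)
  # the tone dominates every interior time bin
  raw <- tfr_hanning(ep, zscore = FALSE)
  interior <- raw$times > -2 & raw$times < 2
  expect_true(all(raw$freqs[apply(raw$power[, interior], 2, which.max)] == 14))
  # epoch too short for 5 cycles at 1 Hz
  short <- epoch_set(dat[, , 1:401, drop = FALSE], times[1:401], fs, "Cz")
  expect_error(tfr_hanning(short), "1 Hz")
})
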