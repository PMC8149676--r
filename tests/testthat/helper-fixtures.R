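# Shared in-code fixtures for the test suite.

# small config used throughout unit tests (cheap but realistic)
test_cfg <- function(...) {
  args <- utils::modifyList(list(n_participants = 4L, n_channels = 16L,
                                 sfreq = 200, nap_duration = 300,
                                 seed = 42L),
                            list(...))
  do.call(sim_config, args)
}

# single-channel recording from a plain signal vector
signal_eeg <- function(x, sfreq = 200, name = "Cz") {
  continuous_eeg(matrix(x, nrow = 1), sfreq, name)
}

# all-N2, movement-free mask for a recording
n2_mask <- function(eeg) {
  hypnogram_mask(rep("N2", ncol(eeg$data)))
}

# epochs of a continuous periodic SO-band sine with a spindle burst whose
# envelope peak sits at time `peak_t` (seconds, same clock as `times`)
periodic_so_epoch <- function(peak_t, f_so = 0.75, sfreq = 200,
                              window = c(-2.5, 2.5), spindle_amp = 20,
                              so_amp = 75) {
  n_t <- round(diff(window) * sfreq) + 1
  times <- seq(window[1], by = 1 / sfreq, length.out = n_t)
  x <- so_amp * cos(2 * pi * f_so * times)   # maximum (upstate) at t = 0
  env <- exp(-(times - peak_t)^2 / (2 * 0.15^2))
  x <- x + spindle_amp * env * sin(2 * pi * 14 * times)
  epoch_set(array(x, dim = c(1, 1, n_t)), times, sfreq, "Cz",
            lock = "SO-downstate")
}

expect_angle_equal <- function(a, b, tol) {
  expect_lt(abs(wrap_angle(a - b)), tol)
}
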