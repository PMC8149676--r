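# Synthetic sleep EEG, localizer epochs and behavior with known ground
# truth. The generator emulates the statistical structure the analysis
# pipeline assumes: a 1/f NREM background, biphasic slow oscillations,
# spindle bursts whose envelope peaks are von Mises-coupled to the SO phase,
# category-specific spatial patterns injected after a fraction of SO-spindle
# complexes, and binomial recognition/recall behavior whose consolidation
# covaries with coupling precision.
#
# SO phase bookkeeping: the planted SO waveform is -sin(2*pi*f*tau) with a
# deeper trough than peak; its downstate sits at tau = T/4. Spindle peaks
# are planted by inverting the Hilbert-phase timeline of the band-filtered
# SO template (see so_phase_map), so "phase theta" in the ground truth means
# exactly what the coupling estimator measures.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validation.
#' Defaults describe a plausible 30-min nap: 5 SOs/min at 0.75 Hz with a
#' 75 uV trough, 14-Hz spindle bursts of 20 uV coupled to SO phase
#' `coupling_mu` with von Mises concentration `coupling_kappa`, and a 1/f
#' background of 15 uV total SD per channel.
#'
#' @param n_participants number of participants in cohort-level simulations.
#' @param n_channels number of channels (<= 64; always includes Cz and the
#'   mastoids M1/M2).
#' @param sfreq sampling rate in Hz.
#' @param nap_duration recording length in seconds.
#' @param so_rate slow-oscillation rate during NREM, events/min.
#' @param so_freq SO frequency in Hz (0.5-1.25).
#' @param spindle_freq spindle carrier frequency in Hz (12-18).
#' @param coupling_mu planted preferred SO phase of the spindle envelope
#'   peak, radians (0 = upstate, +/- pi = downstate).
#' @param coupling_kappa event-level von Mises concentration of spindle
#'   phases around `coupling_mu`.
#' @param phase_dispersion_kappa between-participant concentration of the
#'   per-participant preferred phase around `coupling_mu`.
#' @param reactivation_snr ratio of the injected category-pattern peak
#'   amplitude to the background noise SD.
#' @param reactivation_window start/end of the reactivation pattern relative
#'   to the SO downstate, seconds (within [-1.5, 1.5]).
#' @param reactivation_fraction fraction of SO-spindle complexes carrying a
#'   reactivation pattern.
#' @param so_spindle_fraction fraction of planted SOs carrying a coupled
#'   spindle burst.
#' @param solitary_spindle_rate rate of solitary (uncoupled) spindles,
#'   events/min of NREM.
#' @param behavior_link_strength unitless slope tying expected memory
#'   retention to coupling precision (0 = no link).
#' @param noise_sd background noise SD per channel, microvolts.
#' @param so_trough_amp,so_peak_amp SO trough/peak amplitudes, microvolts.
#' @param spindle_amp spindle burst peak amplitude at Cz, microvolts.
#' @param seed master seed; per-participant streams are derived from it
#'   deterministically.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20L, n_channels = 64L, sfreq = 200,
                       nap_duration = 1800, so_rate = 5, so_freq = 0.75,
                       spindle_freq = 14, coupling_mu = -0.64,
                       coupling_kappa = 5, phase_dispersion_kappa = 6,
                       reactivation_snr = 2.5,
                       reactivation_window = c(0.2, 0.9),
                       reactivation_fraction = 0.5,
                       so_spindle_fraction = 0.7,
                       solitary_spindle_rate = 2,
                       behavior_link_strength = 1,
                       noise_sd = 15, so_trough_amp = 75, so_peak_amp = 40,
                       spindle_amp = 20, seed = 1L) {
  stopifnot(n_participants >= 1, n_channels >= 4, n_channels <= 64,
            sfreq > 0, nap_duration > 0, so_rate >= 0,
            coupling_kappa >= 0, phase_dispersion_kappa >= 0,
            reactivation_snr >= 0,
            reactivation_fraction >= 0, reactivation_fraction <= 1,
            so_spindle_fraction >= 0, so_spindle_fraction <= 1,
            solitary_spindle_rate >= 0, noise_sd > 0,
            so_trough_amp > 0, so_peak_amp > 0, spindle_amp >= 0)
  if (so_freq < 0.5 || so_freq > 1.25)
    stop("so_freq must lie within [0.5, 1.25] Hz")
  if (spindle_freq < 12 || spindle_freq > 18)
    stop("spindle_freq must lie within [12, 18] Hz")
  if (reactivation_window[1] < -1.5 || reactivation_window[2] > 1.5 ||
      reactivation_window[1] >= reactivation_window[2])
    stop("reactivation_window must be an increasing interval within [-1.5, 1.5] s")
  structure(list(n_participants = as.integer(n_participants),
                 n_channels = as.integer(n_channels), sfreq = sfreq,
                 nap_duration = nap_duration, so_rate = so_rate,
                 so_freq = so_freq, spindle_freq = spindle_freq,
                 coupling_mu = coupling_mu, coupling_kappa = coupling_kappa,
                 phase_dispersion_kappa = phase_dispersion_kappa,
                 reactivation_snr = reactivation_snr,
                 reactivation_window = reactivation_window,
                 reactivation_fraction = reactivation_fraction,
                 so_spindle_fraction = so_spindle_fraction,
                 solitary_spindle_rate = solitary_spindle_rate,
                 behavior_link_strength = behavior_link_strength,
                 noise_sd = noise_sd, so_trough_amp = so_trough_amp,
                 so_peak_amp = so_peak_amp, spindle_amp = spindle_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Coupling-precision gain: 1 at the SO upstate (phase 0), 0 at the
# downstate, raised to the fifth power so that consolidation benefits
# accrue steeply only for tightly upstate-coupled participants. Shared by
# the cohort-level reactivation SNR and the behavior generator so both
# expressions of consolidation derive from the same latent precision.
upstate_gain <- function(phase) ((1 + cos(phase)) / 2)^5

# deterministic per-participant RNG stream seeds
participant_seed <- function(cfg, participant, offset = 0L) {
  (cfg$seed * 100003L + participant * 211L + offset) %% .Machine$integer.max
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform, `kappa = Inf` to a point mass at `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0, may be `Inf`).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  wrap_angle(out)
}

# layout restricted to cfg$n_channels (keeps Cz first and both mastoids)
sim_layout <- function(cfg) {
  lay <- channel_layout_64()
  if (cfg$n_channels < 64L)
    lay <- lay[c(seq_len(cfg$n_channels - 2L), 63L, 64L), ]
  rownames(lay) <- NULL
  lay
}

# smooth spatial gain centered on a channel (chord-distance Gaussian)
topo_gain <- function(lay, center = "Cz", width = 0.8) {
  c0 <- as.numeric(lay[lay$name == center, c("x", "y", "z")])
  d <- sqrt((lay$x - c0[1])^2 + (lay$y - c0[2])^2 + (lay$z - c0[3])^2)
  exp(-(d / width)^2)
}

# fixed category-specific spatial templates per participant (unit norm,
# mutually orthogonal); shared between the localizer and the sleep injector
category_templates <- function(cfg, participant) {
  lay <- sim_layout(cfg)
  nc <- nrow(lay)
  with_seed(participant_seed(cfg, participant, 7L), {
    a <- stats::rnorm(nc)
    b <- stats::rnorm(nc)
    a <- a / sqrt(sum(a^2))
    b <- b - sum(a * b) * a
    b <- b / sqrt(sum(b^2))
    list(A = a, B = b)
  })
}

# spatially correlated 1/f background, channels x samples, per-channel SD
# noise_sd; `rho` is the shared-variance fraction
background_noise <- function(n_ch, n, sfreq, noise_sd, rho = 0.3) {
  shared <- oneoverf_noise(n, sfreq)
  out <- matrix(0, n_ch, n)
  for (i in seq_len(n_ch))
    out[i, ] <- noise_sd * (sqrt(rho) * shared +
                            sqrt(1 - rho) * oneoverf_noise(n, sfreq))
  out
}

# one biphasic SO cycle: -sin with a deeper trough than peak
so_waveform <- function(sfreq, f, trough_amp, peak_amp) {
  n <- as.integer(round(sfreq / f))
  tau <- (seq_len(n) - 1L) / sfreq
  base <- -sin(2 * pi * f * tau)
  amp <- ifelse(base < 0, trough_amp, peak_amp)
  amp * base
}

# Phase timeline of the band-filtered SO template. Planting spindle peaks
# against this timeline (rather than an ideal-sinusoid approximation) makes
# "SO phase" in the ground truth mean exactly what the coupling estimator
# measures: the Hilbert phase of the 0.3-1.25 Hz filtered signal.
so_phase_map <- function(sfreq, f, trough_amp, peak_amp, order = 2L) {
  w <- so_waveform(sfreq, f, trough_amp, peak_amp)
  pad <- as.integer(3 * sfreq)
  x <- c(numeric(pad), w, numeric(pad))
  ph <- Arg(analytic_signal(butter_bandpass(x, sfreq, c(0.3, 1.25), order)))
  ext <- as.integer(0.15 * sfreq)
  i <- (pad - ext + 1L):(pad + length(w) + ext)
  list(tau = (i - pad - 1L) / sfreq, phase = ph[i])
}

# seconds after SO start at which the template phase equals theta
so_peak_offset <- function(map, theta) {
  map$tau[which.min(abs(wrap_angle(map$phase - theta)))]
}

# Gaussian-windowed spindle burst of `dur` seconds, envelope peak centered
spindle_burst <- function(sfreq, f, dur, amp, phi0 = 0) {
  n <- as.integer(round(dur * sfreq))
  tau <- (seq_len(n) - 1L) / sfreq - dur / 2
  env <- exp(-tau^2 / (2 * (dur / 6)^2))
  amp * env * sin(2 * pi * f * tau + phi0)
}

# nap sleep-stage sequence in 30-s scoring epochs
default_stage_sequence <- function(nap_duration) {
  n_ep <- max(1L, as.integer(round(nap_duration / 30)))
  frac <- c(W = 0.10, N1 = 0.067, N2 = 0.30, N3 = 0.333,
            REM = 0.067, N2b = 0.133)
  counts <- round(frac * n_ep)
  counts[["N2b"]] <- max(0L, n_ep - sum(counts[-length(counts)]))
  rep(c("W", "N1", "N2", "N3", "REM", "N2"), times = counts)
}

#' Simulate a nap recording with planted events
#'
#' Generates a multichannel continuous recording (spatially correlated 1/f
#' background plus planted SOs, coupled and solitary spindle bursts, and
#' category-pattern injections after a fraction of SO-spindle complexes), a
#' per-sample hypnogram with two movement-artifact spans, and the ground
#' truth of everything planted.
#'
#' @param cfg a [sim_config()].
#' @param participant participant index (selects the RNG stream and the
#'   category templates).
#' @param category stimulus category learned before this nap (`"A"` or
#'   `"B"`); determines which template is injected.
#' @return list of class `sleep_sim` with elements `eeg`
#'   ([continuous_eeg()]), `mask` ([hypnogram_mask()]) and `truth` (list of
#'   data.frames `so`, `spindles`, `reactivations`).
#' @export
simulate_sleep_recording <- function(cfg, participant = 1L, category = "A") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$nap_duration < 1 / cfg$so_freq) stop("recording too short")
  fs <- cfg$sfreq
  n <- as.integer(round(cfg$nap_duration * fs))
  lay <- sim_layout(cfg)
  nc <- nrow(lay)
  tmpl <- category_templates(cfg, participant)
  with_seed(participant_seed(cfg, participant, 1L), {
    x <- background_noise(nc, n, fs, cfg$noise_sd)
    stages <- default_stage_sequence(cfg$nap_duration)
    movement <- rep(FALSE, n)
    # two 5-s movement spans inside the NREM portion
    stage_per_sample <- rep(stages, each = as.integer(round(30 * fs)))[seq_len(n)]
    nrem_idx <- which(stage_per_sample %in% c("N2", "N3"))
    if (length(nrem_idx) > 20 * fs) {
      for (q in c(0.35, 0.7)) {
        s0 <- nrem_idx[ceiling(q * length(nrem_idx))]
        movement[s0:min(s0 + as.integer(5 * fs) - 1L, n)] <- TRUE
      }
    }
    mask <- expand_hypnogram(stages, fs, n)
    mask$movement <- movement
    usable <- nrem_clean(mask)
    segs <- true_runs(usable)
    margin <- as.integer(3 * fs)
    so_gain <- topo_gain(lay, "Cz", 0.8)
    sp_gain <- topo_gain(lay, "Cz", 0.6)
    so_rows <- list()
    sp_rows <- list()
    re_rows <- list()
    rate_s <- cfg$so_rate / 60
    for (s in seq_len(nrow(segs))) {
      if (rate_s <= 0) break
      seg_end_t <- (segs$end[s] - margin) / fs
      t <- (segs$start[s] + margin) / fs
      repeat {
        t <- t + stats::rexp(1, rate_s)
        f_e <- cfg$so_freq * stats::runif(1, 0.85, 1.15)
        f_e <- pmin(pmax(f_e, 0.5), 1.25)
        T_e <- 1 / f_e
        if (t + T_e + 2 > seg_end_t) break
        wave <- so_waveform(fs, f_e, cfg$so_trough_amp, cfg$so_peak_amp)
        i0 <- as.integer(round(t * fs))
        idx <- i0 + seq_along(wave)          # 1-based columns
        x[, idx] <- x[, idx] + outer(so_gain, wave)
        down_t <- (i0 + as.integer(round(T_e / 4 * fs))) / fs
        has_sp <- stats::runif(1) < cfg$so_spindle_fraction
        so_i <- length(so_rows) + 1L
        so_rows[[so_i]] <- data.frame(start = i0 / fs, downstate = down_t,
                                      duration = T_e, has_spindle = has_sp)
        if (has_sp) {
          theta <- rvonmises(1, cfg$coupling_mu, cfg$coupling_kappa)
          tau_pk <- so_peak_offset(
            so_phase_map(fs, f_e, cfg$so_trough_amp, cfg$so_peak_amp), theta)
          pk_t <- i0 / fs + tau_pk
          dur <- stats::runif(1, 1.1, 1.6)
          f_sp <- cfg$spindle_freq + stats::runif(1, -1, 1)
          burst <- spindle_burst(fs, f_sp, dur, cfg$spindle_amp,
                                 stats::runif(1, 0, 2 * pi))
          j0 <- as.integer(round((pk_t - dur / 2) * fs))
          jdx <- j0 + seq_along(burst)
          jdx_ok <- jdx >= 1L & jdx <= n
          x[, jdx[jdx_ok]] <- x[, jdx[jdx_ok]] +
            outer(sp_gain, burst[jdx_ok])
          sp_rows[[length(sp_rows) + 1L]] <- data.frame(
            peak_time = pk_t, onset = j0 / fs, duration = dur,
            phase = theta, coupled = TRUE, so_index = so_i)
          if (stats::runif(1) < cfg$reactivation_fraction &&
              cfg$reactivation_snr > 0) {
            w0 <- down_t + cfg$reactivation_window[1]
            w1 <- down_t + cfg$reactivation_window[2]
            k <- as.integer(round(w0 * fs)):as.integer(round(w1 * fs))
            k <- k[k >= 1L & k <= n]
            env <- signal::hanning(length(k))
            pat <- tmpl[[category]] * cfg$reactivation_snr * cfg$noise_sd
            x[, k] <- x[, k] + outer(pat, env)
            re_rows[[length(re_rows) + 1L]] <- data.frame(
              so_index = so_i, onset = w0, category = category)
          }
        }
        t <- t + T_e + 2          # refractory gap before the next SO
      }
    }
    # solitary spindles, away from every SO
    so_df <- if (length(so_rows)) do.call(rbind, so_rows) else
      data.frame(start = numeric(0), downstate = numeric(0),
                 duration = numeric(0), has_spindle = logical(0))
    if (cfg$solitary_spindle_rate > 0 && nrow(segs)) {
      nrem_min <- sum(usable) / fs / 60
      n_sol <- stats::rpois(1, cfg$solitary_spindle_rate * nrem_min)
      placed <- 0L
      tries <- 0L
      while (placed < n_sol && tries < 50L * max(n_sol, 1L)) {
        tries <- tries + 1L
        s <- sample.int(nrow(segs), 1L)
        lo <- (segs$start[s] + margin) / fs
        hi <- (segs$end[s] - margin) / fs
        if (hi <= lo) next
        pk_t <- stats::runif(1, lo, hi)
        if (nrow(so_df) &&
            any(abs(pk_t - so_df$downstate) < 3)) next
        dur <- stats::runif(1, 1.1, 1.6)
        f_sp <- cfg$spindle_freq + stats::runif(1, -1, 1)
        burst <- spindle_burst(fs, f_sp, dur, cfg$spindle_amp,
                               stats::runif(1, 0, 2 * pi))
        j0 <- as.integer(round((pk_t - dur / 2) * fs))
        jdx <- j0 + seq_along(burst)
        if (jdx[1] < 1L || jdx[length(jdx)] > n) next
        x[, jdx] <- x[, jdx] + outer(sp_gain, burst)
        sp_rows[[length(sp_rows) + 1L]] <- data.frame(
          peak_time = pk_t, onset = j0 / fs, duration = dur,
          phase = NA_real_, coupled = FALSE, so_index = NA_integer_)
        placed <- placed + 1L
      }
    }
    sp_df <- if (length(sp_rows)) do.call(rbind, sp_rows) else
      data.frame(peak_time = numeric(0), onset = numeric(0),
                 duration = numeric(0), phase = numeric(0),
                 coupled = logical(0), so_index = integer(0))
    re_df <- if (length(re_rows)) do.call(rbind, re_rows) else
      data.frame(so_index = integer(0), onset = numeric(0),
                 category = character(0))
    eeg <- continuous_eeg(x, fs, lay$name, positions = lay,
                          reference = "recording")
    rownames(so_df) <- rownames(sp_df) <- rownames(re_df) <- NULL
    structure(list(eeg = eeg, mask = mask,
                   truth = list(so = so_df, spindles = sp_df,
                                reactivations = re_df)),
              class = "sleep_sim")
  })
}

#' @export
print.sleep_sim <- function(x, ...) {
  cat(sprintf("<sleep_sim> %.1f min, %d channels; planted: %d SOs, %d spindles, %d reactivations\n",
              ncol(x$eeg$data) / x$eeg$sfreq / 60, nrow(x$eeg$data),
              nrow(x$truth$so), nrow(x$truth$spindles),
              nrow(x$truth$reactivations)))
  invisible(x)
}

#' Simulate localizer epochs
#'
#' Balanced two-class stimulus-locked epochs over `[-1, 3]` s: 1/f noise
#' plus the class-specific spatial template modulated by an ERP-like
#' temporal envelope that starts 150 ms after stimulus onset, scaled by
#' `reactivation_snr * noise_sd`.
#'
#' @param cfg a [sim_config()].
#' @param participant participant index.
#' @param n_epochs total number of epochs (split evenly between classes).
#' @param window epoch window in seconds relative to stimulus onset.
#' @return an [epoch_set()] with labels `"A"`/`"B"`.
#' @export
simulate_localizer <- function(cfg, participant = 1L, n_epochs = 120L,
                               window = c(-1, 3)) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$sfreq
  lay <- sim_layout(cfg)
  nc <- nrow(lay)
  n_t <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  times <- seq(window[1], by = 1 / fs, length.out = n_t)
  tmpl <- category_templates(cfg, participant)
  # ERP-like envelope: raised cosine from 150 ms to 1.15 s post onset
  env <- ifelse(times >= 0.15 & times <= 1.15,
                sin(pi * (times - 0.15) / 1.0)^2, 0)
  with_seed(participant_seed(cfg, participant, 2L), {
    labels <- sample(rep(c("A", "B"), length.out = n_epochs))
    dat <- array(0, dim = c(n_epochs, nc, n_t))
    amp <- cfg$reactivation_snr * cfg$noise_sd
    for (e in seq_len(n_epochs)) {
      dat[e, , ] <- background_noise(nc, n_t, fs, cfg$noise_sd) +
        amp * outer(tmpl[[labels[e]]], env)
    }
    epoch_set(dat, times, fs, lay$name, lock = "stimulus-onset",
              labels = labels, participant = participant)
  })
}

#' Simulate downstate-locked SO-spindle complex epochs
#'
#' Generates epochs directly in the downstate-locked frame (background 1/f
#' noise, one SO cycle with its downstate at time 0, a spindle burst whose
#' envelope peak sits at a von Mises-distributed SO phase, and a category
#' pattern injected in the reactivation window for a fraction of events).
#' This is the fast path for validating the coupling estimator and the
#' sleep decoder without detouring through continuous-recording detection.
#'
#' @param cfg a [sim_config()].
#' @param participant participant index.
#' @param n_events number of epochs.
#' @param category learned category injected during reactivation.
#' @param window epoch window around the downstate, seconds.
#' @param channels `"all"` or `"Cz"` (single-channel epochs, much faster
#'   when only coupling phases are needed).
#' @param mu,kappa coupling parameters (default from `cfg`).
#' @param reactivation_fraction fraction of events carrying the pattern
#'   (default from `cfg`).
#' @param snr reactivation pattern amplitude in units of `noise_sd`
#'   (default from `cfg`).
#' @return list with `epochs` (an [epoch_set()], labels = `category`) and
#'   `truth` (data.frame with per-event `phase`, `peak_time`, `reactivated`).
#' @export
simulate_complex_epochs <- function(cfg, participant = 1L, n_events = 100L,
                                    category = "A", window = c(-2.5, 2.5),
                                    channels = c("all", "Cz"),
                                    mu = cfg$coupling_mu,
                                    kappa = cfg$coupling_kappa,
                                    reactivation_fraction =
                                      cfg$reactivation_fraction,
                                    snr = cfg$reactivation_snr) {
  stopifnot(inherits(cfg, "sim_config"))
  channels <- match.arg(channels)
  fs <- cfg$sfreq
  lay <- sim_layout(cfg)
  if (channels == "Cz") {
    ch_idx <- which(lay$name == "Cz")
  } else {
    ch_idx <- seq_len(nrow(lay))
  }
  nc <- length(ch_idx)
  so_gain <- topo_gain(lay, "Cz", 0.8)[ch_idx]
  sp_gain <- topo_gain(lay, "Cz", 0.6)[ch_idx]
  tmpl <- lapply(category_templates(cfg, participant), `[`, ch_idx)
  n_t <- as.integer(round((window[2] - window[1]) * fs)) + 1L
  times <- seq(window[1], by = 1 / fs, length.out = n_t)
  with_seed(participant_seed(cfg, participant, 3L), {
    phases <- rvonmises(n_events, mu, kappa)
    reacted <- stats::runif(n_events) < reactivation_fraction & snr > 0
    dat <- array(0, dim = c(n_events, nc, n_t))
    for (e in seq_len(n_events)) {
      xx <- background_noise(nc, n_t, fs, cfg$noise_sd)
      f_e <- cfg$so_freq * stats::runif(1, 0.85, 1.15)
      f_e <- pmin(pmax(f_e, 0.5), 1.25)
      T_e <- 1 / f_e
      wave <- so_waveform(fs, f_e, cfg$so_trough_amp, cfg$so_peak_amp)
      # SO start such that the downstate (tau = T/4) lands at time 0
      i0 <- which.min(abs(times - (-T_e / 4)))
      idx <- i0 + seq_along(wave) - 1L
      ok <- idx >= 1L & idx <= n_t
      xx[, idx[ok]] <- xx[, idx[ok]] + outer(so_gain, wave[ok])
      tau_pk <- so_peak_offset(
        so_phase_map(fs, f_e, cfg$so_trough_amp, cfg$so_peak_amp), phases[e])
      pk_t <- times[i0] + tau_pk
      dur <- stats::runif(1, 1.1, 1.6)
      f_sp <- cfg$spindle_freq + stats::runif(1, -1, 1)
      burst <- spindle_burst(fs, f_sp, dur, cfg$spindle_amp,
                             stats::runif(1, 0, 2 * pi))
      j0 <- as.integer(round((pk_t - dur / 2 - times[1]) * fs)) + 1L
      jdx <- j0 + seq_along(burst) - 1L
      ok <- jdx >= 1L & jdx <= n_t
      xx[, jdx[ok]] <- xx[, jdx[ok]] + outer(sp_gain, burst[ok])
      if (reacted[e]) {
        k <- which(times >= cfg$reactivation_window[1] &
                   times <= cfg$reactivation_window[2])
        envl <- signal::hanning(length(k))
        xx[, k] <- xx[, k] + outer(tmpl[[category]] * snr * cfg$noise_sd, envl)
      }
      dat[e, , ] <- xx
    }
    truth <- data.frame(phase = phases,
                        peak_time = NA_real_, reactivated = reacted)
    list(epochs = epoch_set(dat, times, fs, lay$name[ch_idx],
                            lock = "SO-downstate",
                            labels = rep(category, n_events),
                            participant = participant),
         truth = truth)
  })
}

#' Simulate recognition and cued-recall behavior
#'
#' Two sessions per participant with `n_old` old and `n_new` new recognition
#' items and cued recall scored out of recognition hits before and after
#' sleep. Expected retention (post/pre recall-of-hits ratio) decreases with
#' the circular distance of the participant's coupling phase from the SO
#' upstate (phase 0), with slope `behavior_link_strength`; all counts are
#' binomial.
#'
#' @param cfg a [sim_config()].
#' @param coupling_precision per-participant coupling phase in radians
#'   (distance from 0 is the precision measure).
#' @param n_old,n_new recognition item counts per session.
#' @return data.frame (one row per participant x session) with columns
#'   `participant`, `session`, `n_old`, `n_new`, `hits`, `false_alarms`,
#'   `recalled_pre`, `hits_pre`, `recalled_post`, `hits_post`.
#' @export
simulate_behavior <- function(cfg, coupling_precision, n_old = 120L,
                              n_new = 120L) {
  stopifnot(inherits(cfg, "sim_config"))
  np <- length(coupling_precision)
  m <- upstate_gain(coupling_precision)      # 1 at upstate, 0 at downstate
  p_pre <- 0.55
  ratio <- pmin(pmax(0.3 + 0.7 * cfg$behavior_link_strength * m, 0), 1)
  with_seed(cfg$seed + 17L, {
    rows <- list()
    for (p in seq_len(np)) {
      for (s in 1:2) {
        hits_pre <- stats::rbinom(1, n_old, 0.8)
        hits_post <- stats::rbinom(1, n_old, 0.8)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, session = s, n_old = n_old, n_new = n_new,
          hits = stats::rbinom(1, n_old, 0.8),
          false_alarms = stats::rbinom(1, n_new, 0.15),
          recalled_pre = stats::rbinom(1, hits_pre, p_pre),
          hits_pre = hits_pre,
          recalled_post = stats::rbinom(1, hits_post, p_pre * ratio[p]),
          hits_post = hits_post)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a full cohort for the end-to-end pipeline
#'
#' For each participant, draws a preferred coupling phase around
#' `coupling_mu` (concentration `phase_dispersion_kappa`), scales the
#' reactivation SNR by coupling precision (`((1 + cos(phase)) / 2)^5`, so
#' participants coupling near the upstate reactivate more strongly),
#' and generates localizer epochs plus two sessions of downstate-locked
#' sleep epochs (session 1 learned category A, session 2 category B) and
#' linked behavior.
#'
#' @param cfg a [sim_config()].
#' @param n_localizer localizer epochs per participant.
#' @param n_sleep sleep complex epochs per session.
#' @param sleep_window epoch window around the downstate, seconds.
#' @return list with `participants` (list of per-participant lists:
#'   `localizer`, `sleep` (pooled over the two sessions, labels = learned
#'   category), `phase`, `snr`), `behavior` (from [simulate_behavior()])
#'   and `truth` (data.frame of per-participant planted phase and SNR).
#' @export
simulate_cohort <- function(cfg, n_localizer = 120L, n_sleep = 60L,
                            sleep_window = c(-2.5, 2.5)) {
  stopifnot(inherits(cfg, "sim_config"))
  phases <- with_seed(cfg$seed + 29L,
                      rvonmises(cfg$n_participants, cfg$coupling_mu,
                                cfg$phase_dispersion_kappa))
  snr_p <- cfg$reactivation_snr * upstate_gain(phases)
  participants <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    loc <- simulate_localizer(cfg, p, n_epochs = n_localizer)
    s1 <- simulate_complex_epochs(cfg, p, n_events = n_sleep, category = "A",
                                  window = sleep_window,
                                  mu = phases[p], snr = snr_p[p])
    cfg2 <- cfg
    cfg2$seed <- cfg$seed + 1000L       # independent stream for session 2
    s2 <- simulate_complex_epochs(cfg2, p, n_events = n_sleep, category = "B",
                                  window = sleep_window,
                                  mu = phases[p], snr = snr_p[p])
    sleep <- epoch_set(
      abind3(s1$epochs$data, s2$epochs$data),
      s1$epochs$times, s1$epochs$sfreq, s1$epochs$ch_names,
      lock = "SO-downstate",
      labels = c(s1$epochs$labels, s2$epochs$labels), participant = p)
    participants[[p]] <- list(localizer = loc, sleep = sleep,
                              phase = phases[p], snr = snr_p[p],
                              event_phases = c(s1$truth$phase, s2$truth$phase))
  }
  behavior <- simulate_behavior(cfg, phases)
  list(participants = participants, behavior = behavior,
       truth = data.frame(participant = seq_len(cfg$n_participants),
                          phase = phases, snr = snr_p))
}

# bind two events x channels x time arrays along the first axis
abind3 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}
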