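# SO-spindle phase coupling and the circular statistics used for inference.
#
# Phase convention (matching the analytic-signal phase of the SO-band
# signal): the SO upstate (signal maximum) is 0, the downstate (trough) is
# +/- pi, and the down-to-upstate zero crossing is -pi/2.

#' Per-event SO phase at the spindle amplitude maximum
#'
#' Each downstate-locked epoch is band-pass filtered in the SO band
#' (two-pass Butterworth) and Hilbert-transformed to obtain the
#' instantaneous SO phase; the same segment is filtered in the spindle band
#' and Hilbert-transformed to obtain the spindle amplitude envelope. Only
#' samples within `restrict` seconds of the lock point are considered (to
#' stay clear of filter edge artifacts), and the SO phase at the sample of
#' maximal spindle amplitude is returned per event.
#'
#' @param epochs an [epoch_set()] locked to SO downstates (typically
#'   +/- 2.5 s at the detection channel).
#' @param channel channel name or index to use.
#' @param so_band,spindle_band filter bands in Hz.
#' @param restrict half-width (s) of the window actually searched.
#' @param order Butterworth order per pass.
#' @return numeric vector of phases in (-pi, pi], one per event; the sample
#'   times of the amplitude maxima are attached as attribute `"peak_time"`.
#' @export
event_coupling_phase <- function(epochs, channel = 1L,
                                 so_band = c(0.3, 1.25),
                                 spindle_band = c(12, 18),
                                 restrict = 1.5, order = 2L) {
  if (is.character(channel)) channel <- match(channel, epochs$ch_names)
  t <- epochs$times
  if (t[1] > -restrict || t[length(t)] < restrict)
    stop("epoch must cover at least +/-", restrict, " s around the lock point")
  sel <- which(abs(t) <= restrict + 1e-9)
  fs <- epochs$sfreq
  n_ev <- dim(epochs$data)[1]
  phases <- numeric(n_ev)
  peak_t <- numeric(n_ev)
  for (e in seq_len(n_ev)) {
    x <- epochs$data[e, channel, ]
    ph <- Arg(analytic_signal(butter_bandpass(x, fs, so_band, order)))
    am <- Mod(analytic_signal(butter_bandpass(x, fs, spindle_band, order)))
    i <- sel[which.max(am[sel])]
    phases[e] <- ph[i]
    peak_t[e] <- t[i]
  }
  structure(wrap_angle(phases), peak_time = peak_t)
}

#' Circular mean and resultant vector length
#'
#' @param phases numeric vector of angles in radians (nonempty).
#' @return list with `mean` (radians in (-pi, pi]), `R` (resultant length in
#'   `[0, 1]`) and `mean_reliable` (`FALSE` when `R` is numerically zero, in
#'   which case the mean direction is undefined).
#' @export
circular_mean_and_R <- function(phases) {
  if (!length(phases)) stop("empty phase vector")
  z <- mean(exp(1i * phases))
  R <- Mod(z)
  reliable <- R > sqrt(.Machine$double.eps)
  list(mean = if (reliable) wrap_angle(Arg(z)) else NA_real_,
       R = R, mean_reliable = reliable)
}

#' Rayleigh test of circular uniformity
#'
#' Computes `z = n * R^2` and the standard small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param phases numeric vector of angles in radians, `n >= 2`.
#' @return list with `z`, `p`, `R` and `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("Rayleigh test needs at least 2 angles")
  R <- Mod(mean(exp(1i * phases)))
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(z = z, p = min(p, 1), R = R, n = n)
}

# correlation helper that errors on degenerate input
.corr_checked <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("degenerate input: constant variable in correlation")
  stats::cor(a, b)
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable `theta` and a linear variable
#' `x`: with `r_cx = cor(cos theta, x)`, `r_sx = cor(sin theta, x)` and
#' `r_cs = cor(cos theta, sin theta)`,
#' `r = sqrt((r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2))`; the
#' p value is the upper tail of a chi-square distribution with 2 df at
#' `n * r^2`.
#'
#' @param phases angles in radians.
#' @param x linear covariate, same length, non-constant.
#' @return list with `r`, `p` and `n`.
#' @export
circ_linear_corr <- function(phases, x) {
  n <- length(phases)
  if (n != length(x)) stop("phases and x must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  ct <- cos(phases)
  st <- sin(phases)
  if (stats::sd(ct) < 1e-12 && stats::sd(st) < 1e-12)
    stop("degenerate input: constant phases")
  r <- .circ_linear_r(ct, st, x)
  list(r = r, p = stats::pchisq(n * r^2, df = 2, lower.tail = FALSE), n = n)
}

.circ_linear_r <- function(ct, st, x) {
  r_cx <- .corr_checked(ct, x)
  r_sx <- .corr_checked(st, x)
  r_cs <- suppressWarnings(stats::cor(ct, st))
  if (!is.finite(r_cs)) r_cs <- 0
  r2 <- (r_cx^2 + r_sx^2 - 2 * r_cx * r_sx * r_cs) / (1 - r_cs^2)
  sqrt(max(min(r2, 1), 0))
}

#' Partial circular-linear correlation
#'
#' Removes a linear covariate before assessing the circular-linear
#' association: `x`, `cos(theta)` and `sin(theta)` are each replaced by
#' their residuals from a least-squares regression on `covariate`
#' (with intercept), and the circular-linear correlation formula is applied
#' to the residual correlations. The p value uses the chi-square
#' approximation with 2 df at `n * r^2`.
#'
#' @param phases angles in radians.
#' @param x linear variable of interest.
#' @param covariate linear nuisance variable, non-constant.
#' @return list with `r`, `p` and `n`.
#' @export
partial_circ_linear_corr <- function(phases, x, covariate) {
  n <- length(phases)
  if (n != length(x) || n != length(covariate))
    stop("phases, x and covariate must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(covariate) < 1e-12)
    stop("degenerate input: constant covariate")
  if (stats::sd(x) < 1e-12) stop("degenerate input: constant x")
  resid_on <- function(v) stats::lm.fit(cbind(1, covariate), v)$residuals
  ct <- resid_on(cos(phases))
  st <- resid_on(sin(phases))
  xr <- resid_on(x)
  if (stats::sd(ct) < 1e-12 && stats::sd(st) < 1e-12)
    stop("degenerate input: constant phases after partialling")
  # x fully explained by the covariate: nothing left to correlate
  if (stats::sd(xr) < 1e-10 * stats::sd(x))
    return(list(r = 0, p = 1, n = n))
  r <- .circ_linear_r(ct, st, xr)
  list(r = r, p = stats::pchisq(n * r^2, df = 2, lower.tail = FALSE), n = n)
}

#' Participant-level coupling summary
#'
#' Convenience wrapper combining the per-event phases with the circular
#' summary statistics reported per participant.
#'
#' @param phases per-event coupling phases in radians.
#' @return list of class `coupling_result` with `event_phases`,
#'   `preferred_phase`, `resultant_length`, `rayleigh_z`, `rayleigh_p`, `n`.
#' @export
coupling_result <- function(phases) {
  m <- circular_mean_and_R(phases)
  ray <- if (length(phases) >= 2L) rayleigh_test(phases)
         else list(z = NA_real_, p = NA_real_)
  structure(list(event_phases = phases, preferred_phase = m$mean,
                 resultant_length = m$R, rayleigh_z = ray$z,
                 rayleigh_p = ray$p, n = length(phases)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling_result> n = %d events; preferred phase = %.3f rad (%.2f deg); R = %.3f; Rayleigh z = %.2f, p = %.3g\n",
    x$n, x$preferred_phase, x$preferred_phase * 180 / pi,
    x$resultant_length, x$rayleigh_z, x$rayleigh_p))
  invisible(x)
}
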