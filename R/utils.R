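# Internal numerical helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; keep the +pi convention instead
  out[out == -pi] <- pi
  out
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)`; `Arg()` of the result is
#' the instantaneous phase (0 at a local signal maximum of a narrowband
#' oscillation), `Mod()` the instantaneous amplitude envelope.
#'
#' @param x real-valued numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Centered moving average with shrinking windows at the edges.
# width is in samples (coerced to an odd integer by rounding up).
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 1/f^alpha noise (power spectral density ~ 1/f^alpha), unit variance.
oneoverf_noise <- function(n, sfreq, alpha = 1, f_min = 0.1) {
  if (n < 4L) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, sfreq, length.out = n + 1L)[seq_len(n)]
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]  # mirror to physical frequency
  # flatten below f_min so the DC region does not dominate the variance
  f <- pmax(f, f_min)
  g <- 1 / f^(alpha / 2)
  g[1L] <- 0
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Zero-phase FFT low-pass with unit passband gain and a raised-cosine
# roll-off between `pass` and `stop` Hz; reflect-padded to suppress
# circular wrap-around at the edges.
fft_lowpass <- function(x, sfreq, pass, stop) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(sfreq)))
  xx <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  m <- length(xx)
  f <- seq(0, sfreq, length.out = m + 1L)[seq_len(m)]
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]
  g <- rep(1, m)
  g[f >= stop] <- 0
  tr <- f > pass & f < stop
  g[tr] <- 0.5 * (1 + cos(pi * (f[tr] - pass) / (stop - pass)))
  y <- Re(stats::fft(stats::fft(xx) * g, inverse = TRUE) / m)
  y[(pad + 1L):(pad + n)]
}

# run-length encoding of a logical vector into start/end sample indices of
# TRUE runs; returns a data.frame with columns start, end (inclusive, 1-based)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Append a step description to the processing history of an object.
add_history <- function(x, step) {
  attr(x, "history") <- c(attr(x, "history"), step)
  x
}

#' Processing history of an object
#'
#' Every transform in the package appends a short description of itself to a
#' `history` attribute, so the order of preprocessing steps actually applied
#' can be audited after the fact.
#'
#' @param x an object produced by this package.
#' @return character vector of processing steps (possibly empty).
#' @export
processing_history <- function(x) {
  h <- attr(x, "history")
  if (is.null(h)) character(0) else h
}

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. Makes simulators reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
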