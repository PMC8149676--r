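# Abstract 64-channel scalp layout used by the simulator and the searchlight.

#' Abstract 64-channel EEG layout on the unit sphere
#'
#' Builds a quasi-uniform 10-10-like grid of 62 scalp positions on the upper
#' part of the unit sphere (vertex channel named `"Cz"`), plus two mastoid
#' channels `"M1"`/`"M2"` below the lowest scalp ring. The geometry only
#' needs to be realistic enough for distance-based searchlight neighborhoods
#' and for smooth spatial topographies in the simulator; it does not claim to
#' reproduce any manufacturer's digitized positions.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z` (unit-sphere
#'   Cartesian coordinates, `z` up, `x` towards the nose).
#' @export
channel_layout_64 <- function() {
  # quasi-uniform Fibonacci spiral over the scalp cap (polar angle <= 100
  # degrees); the first point is pulled to the vertex and named Cz
  n_scalp <- 62L
  ga <- pi * (3 - sqrt(5))
  i <- seq_len(n_scalp) - 1L
  z <- 1 - (1 - cos(100 * pi / 180)) * (i + 0.5) / n_scalp
  z[1L] <- 1                                   # vertex
  th <- acos(z)
  az <- ga * i
  xyz <- cbind(sin(th) * cos(az), sin(th) * sin(az), z)
  name <- c("Cz", sprintf("E%02d", seq_len(n_scalp - 1L)))
  # mastoids: low lateral positions behind the ears
  m_th <- 108 * pi / 180
  m_az <- c(100, 260) * pi / 180
  xyz <- rbind(xyz, cbind(sin(m_th) * cos(m_az), sin(m_th) * sin(m_az),
                          rep(cos(m_th), 2)))
  name <- c(name, "M1", "M2")
  data.frame(name = name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Distance-based searchlight neighborhoods
#'
#' For every channel, the neighborhood is the channel itself plus all other
#' channels within a Euclidean (chord) radius, with sizes bounded to
#' `size_range`: channels with too few in-radius neighbors are topped up
#' with their nearest channels, channels with too many keep only their
#' nearest in-radius neighbors. This keeps the feature count per
#' searchlight within a narrow band even at the cap boundary, where purely
#' radius-based neighborhoods thin out.
#'
#' @param positions data.frame with columns `name`, `x`, `y`, `z` (e.g. from
#'   [channel_layout_64()]), one row per channel.
#' @param radius chord-distance radius (default 0.5, about twice the
#'   inter-channel spacing of the default 64-channel layout).
#' @param size_range admissible neighborhood sizes, center included.
#' @return named list of integer vectors (indices into `positions`, center
#'   first, then neighbors by increasing distance); the radius is attached
#'   as attribute `"radius"`.
#' @export
searchlight_neighborhoods <- function(positions, radius = 0.5,
                                      size_range = c(5L, 9L)) {
  p <- as.matrix(positions[, c("x", "y", "z")])
  n <- nrow(p)
  if (n < size_range[1])
    stop("layout has fewer channels than the minimum neighborhood size")
  d <- as.matrix(stats::dist(p))
  out <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])                    # center first (distance 0)
    ord <- ord[ord != i]
    k <- sum(d[i, ord] <= radius)
    k <- min(max(k, size_range[1] - 1L), size_range[2] - 1L)
    c(i, ord[seq_len(k)])
  })
  names(out) <- positions$name
  attr(out, "radius") <- radius
  out
}
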