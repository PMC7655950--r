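# Shared helpers: angles, smoothing, ordered facies vocabulary.

# Canonical facies codes; order fixed so categorical rasters are stable.
FACIES <- c("LCF", "DCF", "SC", "CR", "S")

# 8-sector compass labels, 45 deg wide, centred on the cardinal/intercardinal
# directions (N covers [337.5, 22.5)).
COMPASS8 <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Compass sector containing an azimuth
#'
#' @param deg azimuth in degrees clockwise from north.
#' @param n number of sectors (8 gives N, NE, ..., NW).
#' @return character sector label (8 sectors) or integer sector index.
#' @export
compass_sector <- function(deg, n = 8) {
  deg <- deg %% 360
  idx <- floor(((deg + 360 / (2 * n)) %% 360) / (360 / n)) + 1
  if (n == 8) COMPASS8[idx] else as.integer(idx)
}

# Smallest absolute angular difference between two azimuths, in [0, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of azimuths
#'
#' Unit-vector average of directions in degrees clockwise from north.
#' Returns `NA` when the resultant length is numerically zero (perfectly
#' balanced directions have no mean).
#'
#' @param deg numeric vector of azimuths in degrees.
#' @param na.rm drop missing values first.
#' @return mean azimuth in `[0, 360)`, or `NA`.
#' @export
circular_mean <- function(deg, na.rm = TRUE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  if (length(deg) == 0) return(NA_real_)
  th <- deg * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  (atan2(s, c) * 180 / pi) %% 360
}

# Separable Gaussian smoothing of a matrix with edge renormalisation
# (kernel mass falling outside the grid is redistributed, so a constant
# field stays constant). sigma in cells; sigma <= 0 is the identity.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(n) {
    # n x n banded convolution matrix with row renormalisation
    K <- matrix(0, n, n)
    for (j in seq(-half, half)) {
      idx <- seq_len(n)
      tgt <- idx + j
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[j + half + 1]
    }
    K / rowSums(K)
  }
  Kr <- conv1(nrow(m))
  Kc <- if (ncol(m) == nrow(m)) Kr else conv1(ncol(m))
  Kr %*% m %*% t(Kc)
}

# Deterministic child seed: mixes a base seed with a small tag, staying
# inside R's 32-bit integer range.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 69069 + tag) %% .Machine$integer.max)
}
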