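#' Sample points on a 3D torus
#'
#' Points on the torus of revolution
#' `x = (c + a cos v) cos u`, `y = (c + a cos v) sin u`, `z = a sin v`
#' with angles `(u, v)` drawn i.i.d. uniform on `[0, 2 pi)^2` (by default) or
#' area-uniform on the surface.
#'
#' @param n number of points.
#' @param a minor radius; `c` major radius (`0 < a < c`).
#' @param c major radius.
#' @param seed optional RNG seed.
#' @param areaUniform draw `v` from the surface-area measure instead of
#'   uniformly (angle-uniform sampling is the default).
#' @return an `n x 3` matrix.
#' @examples
#' x <- sampleTorus3D(100, a = 5, c = 10, seed = 1)
#' range((sqrt(x[,1]^2 + x[,2]^2) - 10)^2 + x[,3]^2 - 25)  # ~0
#' @export
sampleTorus3D <- function(n, a = 5, c = 10, seed = NULL, areaUniform = FALSE) {
  stopifnot(n >= 1, a > 0, c > a)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n, 0, 2 * pi)
  if (areaUniform) {
    # rejection sampling with density (c + a cos v) / (c + a)
    v <- numeric(n)
    got <- 0
    while (got < n) {
      m <- (n - got) * 2 + 10
      cand <- stats::runif(m, 0, 2 * pi)
      acc <- cand[stats::runif(m) < (c + a * cos(cand)) / (c + a)]
      take <- min(length(acc), n - got)
      if (take > 0) v[(got + 1):(got + take)] <- acc[seq_len(take)]
      got <- got + take
    }
  } else {
    v <- stats::runif(n, 0, 2 * pi)
  }
  cbind(x = (c + a * cos(v)) * cos(u),
        y = (c + a * cos(v)) * sin(u),
        z = a * sin(v))
}

#' Sample points on a flat torus embedded in 6D
#'
#' Points on the 6-dimensional embedding
#' `(C1 cos(a1 u + b1 v), C1 sin(a1 u + b1 v), C2 cos(a2 u + b2 v),
#'   C2 sin(a2 u + b2 v), C3 cos(b3 v), C3 sin(b3 v))`
#' with angles uniform on `[0, 2 pi)^2`. Defaults: `ai = 1`, `b1 = 1/3`,
#' `b2 = -1/3`, `b3 = 1`, `Ci = 1`.
#'
#' @param n number of points.
#' @param C radii of the three circles (length 3).
#' @param afreq `u`-frequencies `(a1, a2)`.
#' @param bfreq `v`-frequencies `(b1, b2, b3)`.
#' @param seed optional RNG seed.
#' @return an `n x 6` matrix; every row satisfies
#'   `p1^2 + p2^2 = C1^2` etc.
#' @export
sampleTorus6D <- function(n, C = c(1, 1, 1), afreq = c(1, 1),
                          bfreq = c(1 / 3, -1 / 3, 1), seed = NULL) {
  stopifnot(n >= 1, all(C > 0), length(C) == 3, length(afreq) == 2,
            length(bfreq) == 3)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n, 0, 2 * pi)
  v <- stats::runif(n, 0, 2 * pi)
  cbind(C[1] * cos(afreq[1] * u + bfreq[1] * v),
        C[1] * sin(afreq[1] * u + bfreq[1] * v),
        C[2] * cos(afreq[2] * u + bfreq[2] * v),
        C[2] * sin(afreq[2] * u + bfreq[2] * v),
        C[3] * cos(bfreq[3] * v),
        C[3] * sin(bfreq[3] * v))
}

#' Corrupt a point cloud with isotropic Gaussian noise
#'
#' Adds i.i.d. `N(0, delta^2)` noise to every coordinate of every point;
#' `delta = 0` returns the input unchanged.
#'
#' @param points numeric matrix (points in rows).
#' @param delta noise standard deviation (same units as the coordinates).
#' @param seed optional RNG seed.
#' @return matrix of the same shape.
#' @export
addGaussianNoise <- function(points, delta, seed = NULL) {
  stopifnot(delta >= 0)
  points <- as.matrix(points)
  if (delta == 0) return(points)
  if (!is.null(seed)) set.seed(seed)
  points + matrix(stats::rnorm(length(points), 0, delta), nrow(points))
}

#' Toroidality versus noise on a sampled torus
#'
#' A single clean sample of `n` torus points is drawn once; for each noise
#' level `delta`, independent Gaussian noise realizations are added to those
#' same points, Rips persistence is run to `H2`, and toroidality is scored
#' against the data-mode reference built from the clean sample. Reports mean
#' and standard deviation of `Gamma1` and `Gamma2` over the noise
#' realizations (the `delta = 0` entry is deterministic). With increasing
#' noise both components decay sigmoidally.
#'
#' @param deltas ascending noise standard deviations.
#' @param n number of clean torus points.
#' @param realizations noise realizations per level.
#' @param torus `"3d"` or `"6d"`.
#' @param a,c 3D torus radii (ignored for `"6d"`).
#' @param seed master RNG seed.
#' @return data.frame with columns `delta`, `meanGamma1`, `sdGamma1`,
#'   `meanGamma2`, `sdGamma2`.
#' @export
noiseSweep <- function(deltas, n = 1200, realizations = 20,
                       torus = c("3d", "6d"), a = 5, c = 10, seed = 1) {
  torus <- match.arg(torus)
  stopifnot(!is.unsorted(deltas))
  clean <- if (torus == "3d") sampleTorus3D(n, a, c, seed = seed) else
    sampleTorus6D(n, seed = seed)
  ref <- makeReference(ripsPersistence(clean, maxdim = 2), "data")
  out <- data.frame()
  for (di in seq_along(deltas)) {
    nr <- if (deltas[di] == 0) 1L else realizations
    g1 <- g2 <- numeric(nr)
    for (r in seq_len(nr)) {
      pts <- addGaussianNoise(clean, deltas[di], seed = seed + 1000 * di + r)
      sc <- toroidality(ripsPersistence(pts, maxdim = 2), reference = ref)
      g1[r] <- sc@gamma1
      g2[r] <- sc@gamma2
    }
    out <- rbind(out, data.frame(delta = deltas[di],
      meanGamma1 = mean(g1), sdGamma1 = stats::sd(g1),
      meanGamma2 = mean(g2), sdGamma2 = stats::sd(g2)))
  }
  out
}
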