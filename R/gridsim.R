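#' Field centers on a (shifted) lattice
#'
#' All lattice points falling inside the arena expanded by `margin` on every
#' side. Hexagonal lattices use basis vectors `(s, 0)` and
#' `(s/2, s sqrt(3)/2)`; square lattices `(s, 0)` and `(0, s)`. A per-neuron
#' random shift (uniform over one unit cell) is applied by the population
#' constructor.
#'
#' @param spacing lattice spacing (m).
#' @param kind `"hexagonal"` or `"square"`.
#' @param shift length-2 offset (m) applied to all points.
#' @param orientation lattice rotation (radians; default 0).
#' @param arena arena side (m).
#' @param margin border width included beyond the arena (m); use at least the
#'   field truncation radius `x0` so wall fields keep their tails.
#' @return two-column matrix of centers (m).
#' @export
makeCenters <- function(spacing, kind = c("hexagonal", "square"),
                        shift = c(0, 0), orientation = 0, arena = 1.5,
                        margin = 0.4) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, margin >= 0)
  b1 <- spacing * c(1, 0)
  b2 <- if (kind == "hexagonal") spacing * c(0.5, sqrt(3) / 2) else spacing * c(0, 1)
  if (orientation != 0) {
    R <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2)
    b1 <- as.vector(R %*% b1)
    b2 <- as.vector(R %*% b2)
  }
  # integer ranges generously covering the padded arena
  ext <- arena + 2 * margin
  nmax <- ceiling(ext / spacing) + 2
  ij <- as.matrix(expand.grid(i = -nmax:nmax, j = -nmax:nmax))
  pts <- cbind(shift[1] + ij[, 1] * b1[1] + ij[, 2] * b2[1],
               shift[2] + ij[, 1] * b1[2] + ij[, 2] * b2[2])
  keep <- pts[, 1] >= -margin & pts[, 1] <= arena + margin &
          pts[, 2] >= -margin & pts[, 2] <= arena + margin
  pts[keep, , drop = FALSE]
}

#' Construct a simulated grid-cell population
#'
#' `N` Poisson-spiking grid cells sharing a lattice geometry and field-shape
#' parameters. Each neuron's field centers are the lattice shifted by an
#' independent uniform offset within one unit cell (orientation is shared
#' and fixed). Defaults match a module with spacing comparable to R852:
#' `N = 75`, spacing 0.85 m, `sigma = 0.12`, `lambda0 = 0.05`, `G0 = 1.5`,
#' `x0 = 0.4`, 1.5 m arena.
#'
#' @param N number of neurons.
#' @param spacing lattice spacing (m).
#' @param kind `"hexagonal"` or `"square"`.
#' @param sigma field width (m).
#' @param lambda0 baseline rate (Hz).
#' @param G0 field gain (Hz m^2).
#' @param x0 field truncation radius (m); must exceed `sigma`.
#' @param arena arena side (m).
#' @param seed optional RNG seed for the per-neuron shifts.
#' @return A [GridPopulation-class].
#' @export
gridPopulation <- function(N = 75, spacing = 0.85,
                           kind = c("hexagonal", "square"), sigma = 0.12,
                           lambda0 = 0.05, G0 = 1.5, x0 = 0.4, arena = 1.5,
                           seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  b1 <- spacing * c(1, 0)
  b2 <- if (kind == "hexagonal") spacing * c(0.5, sqrt(3) / 2) else spacing * c(0, 1)
  centers <- vector("list", N)
  for (i in seq_len(N)) {
    uu <- stats::runif(2)
    sh <- uu[1] * b1 + uu[2] * b2
    centers[[i]] <- makeCenters(spacing, kind, shift = sh, arena = arena,
                                margin = x0)
  }
  new("GridPopulation", centers = centers, lambda0 = lambda0, G0 = G0,
      sigma = sigma, x0 = x0, spacing = spacing, latticeKind = kind,
      arena = arena)
}

# truncated-Gaussian field profile G(x) summed over one neuron's centers,
# evaluated at positions xy (matrix); returns lambda0 + sum_k G(|r - r_k|)
.spatial_rate <- function(pop, i, xy) {
  ctr <- pop@centers[[i]]
  peak <- pop@G0 / (2 * pi * pop@sigma^2)
  out <- rep(pop@lambda0, nrow(xy))
  for (k in seq_len(nrow(ctr))) {
    d2 <- (xy[, 1] - ctr[k, 1])^2 + (xy[, 2] - ctr[k, 2])^2
    w <- d2 < pop@x0^2
    if (any(w)) out[w] <- out[w] + peak * exp(-d2[w] / (2 * pop@sigma^2))
  }
  out
}

# oscillatory factor c1 + c2 sum_mu A cos(2 pi omega t) at times t
.temporal_factor <- function(bank, t) {
  if (length(bank@omegas) == 0 || bank@c2 == 0) return(rep(bank@c1, length(t)))
  s <- numeric(length(t))
  for (mu in seq_along(bank@omegas))
    s <- s + bank@amps[mu] * cos(2 * pi * bank@omegas[mu] * t)
  bank@c1 + bank@c2 * s
}

#' Instantaneous firing rate of one simulated neuron
#'
#' `lambda_i(r, t) = [(lambda0 + sum_k G(|r - r_ik|)) *
#' (c1 + c2 sum_mu A(omega_mu) cos(2 pi omega_mu t))]_+`, with `G` the
#' truncated-Gaussian field profile. The rectification keeps rates
#' nonnegative.
#'
#' @param pop a [GridPopulation-class].
#' @param bank an [OscillatorBank-class].
#' @param i neuron index.
#' @param r position: length-2 vector or two-column matrix (m).
#' @param t time(s) (s); recycled against positions.
#' @return numeric vector of rates (Hz).
#' @export
firingRate <- function(pop, bank, i, r, t) {
  if (is.vector(r)) r <- matrix(r, ncol = 2)
  n <- max(nrow(r), length(t))
  if (nrow(r) == 1) r <- r[rep(1, n), , drop = FALSE]
  t <- rep_len(t, n)
  pmax(.spatial_rate(pop, i, r) * .temporal_factor(bank, t), 0)
}

#' Calibrate the oscillatory normalization constant c2
#'
#' `1 / c2` is the long-time average of the rectified oscillator sum,
#' `(1/T) integral_0^T [sum_mu A(omega_mu) sin(2 pi omega_mu t)]_+ dt`,
#' evaluated on a discrete grid. Setting `c2` this way makes the mean of the
#' oscillatory rate factor equal one, so the expected spike count of a
#' simulated neuron is the same with and without oscillations.
#'
#' @param bank an [OscillatorBank-class] with at least one nonzero amplitude.
#' @param T averaging window (s).
#' @param dt integration step (s).
#' @param waveform `"sin"` (as in the defining time average) or `"cos"` (the
#'   waveform used by the simulator); for incommensurate banks and large `T`
#'   the two agree.
#' @return scalar `c2`.
#' @export
calibrateC2 <- function(bank, T = 36, dt = 0.001, waveform = c("sin", "cos")) {
  waveform <- match.arg(waveform)
  if (length(bank@amps) == 0 || all(bank@amps == 0)) stop("non-modulated bank")
  t <- seq(0, T, by = dt)
  s <- numeric(length(t))
  f <- if (waveform == "sin") sin else cos
  for (mu in seq_along(bank@omegas))
    s <- s + bank@amps[mu] * f(2 * pi * bank@omegas[mu] * t)
  m <- mean(pmax(s, 0))
  if (m <= 0) stop("non-modulated bank")
  1 / m
}

#' Build an oscillator bank preset
#'
#' Presets for the temporal modulation of the simulator:
#' \describe{
#'   \item{`"none"`}{no oscillations: empty bank, `c1 = 1`, `c2 = 0` (the
#'     temporal factor is identically one).}
#'   \item{`"methods_default"`}{`m = 200` frequencies logarithmically spaced
#'     in `[1, 50]` Hz with `A(omega) = 0.25 omega^(-1/2)`; the grid points
#'     nearest 4 and 8 Hz are snapped to exactly 4 and 8 Hz with amplitudes
#'     `0.5 omega^(-1/2)` and `0.8 omega^(-1/2)` (dominant eta and theta
#'     lines); `c1 = 0` and `c2` from [calibrateC2()].}
#'   \item{`"single"`}{`methods_default` with the eta (4 Hz) line silenced
#'     and the remaining dominant line moved to `freq` Hz (amplitude
#'     `0.8 freq^(-1/2)`); used for single-oscillator frequency sweeps.}
#' }
#'
#' @param preset `"methods_default"`, `"single"` or `"none"`.
#' @param freq dominant frequency (Hz) for `preset = "single"`.
#' @param m number of oscillators.
#' @param range frequency range (Hz) of the logarithmic grid.
#' @param calibrate compute `c2` via [calibrateC2()] (default); otherwise
#'   `c2` is left at 1 for `"methods_default"`/`"single"`.
#' @param calibrationT averaging window (s) for the `c2` calibration of this
#'   bank. The bank's nearest frequency pairs beat on ~50 s periods, so the
#'   window must span many beats for the rectified average to converge;
#'   the default matches the default 30-minute session, making the expected
#'   spike count of a session equal with and without oscillations. The
#'   calibration uses the simulator's cosine waveform.
#' @return An [OscillatorBank-class].
#' @examples
#' buildOscillatorBank("none")
#' bk <- buildOscillatorBank("methods_default")
#' length(bk@omegas)  # 200
#' @export
buildOscillatorBank <- function(preset = c("methods_default", "single", "none"),
                                freq = NULL, m = 200, range = c(1, 50),
                                calibrate = TRUE, calibrationT = 1800) {
  preset <- match.arg(preset)
  if (preset == "none")
    return(new("OscillatorBank", omegas = numeric(0), amps = numeric(0),
               c1 = 1, c2 = 0))
  om <- 10^seq(log10(range[1]), log10(range[2]), length.out = m)
  amps <- 0.25 * om^(-0.5)
  i4 <- which.min(abs(om - 4))
  i8 <- which.min(abs(om - 8))
  om[i4] <- 4; om[i8] <- 8
  amps[i4] <- 0.5 * 4^(-0.5)
  amps[i8] <- 0.8 * 8^(-0.5)
  if (preset == "single") {
    if (is.null(freq)) stop("preset 'single' needs a frequency")
    if (freq <= 0 || freq >= 50) stop("frequency outside (0, 50) Hz (simulation Nyquist)")
    amps[i4] <- 0  # silence the eta line
    om[i8] <- freq
    amps[i8] <- 0.8 * freq^(-0.5)
    o <- order(om)
    om <- om[o]; amps <- amps[o]
  }
  bank <- new("OscillatorBank", omegas = om, amps = amps, c1 = 0, c2 = 1)
  if (calibrate)
    bank@c2 <- calibrateC2(bank, T = calibrationT, waveform = "cos")
  bank
}

#' Simulate Poisson spiking of a grid-cell population
#'
#' Divides time into bins of `dt`, evaluates each neuron's rate
#' `lambda_i(r(t), t)` at the trajectory position of each bin, draws
#' independent Poisson spike counts with mean `lambda dt`, and places spike
#' times uniformly within their bins. The trajectory is resampled to `dt`
#' when its step differs.
#'
#' @param pop a [GridPopulation-class].
#' @param traj a [Trajectory-class].
#' @param bank an [OscillatorBank-class]; `buildOscillatorBank("none")` for
#'   oscillation-free simulations.
#' @param dt simulation bin (s).
#' @param seed optional RNG seed.
#' @return A [SpikeTrains-class] spanning the trajectory.
#' @export
simulateGridModule <- function(pop, traj, bank = buildOscillatorBank("none"),
                               dt = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- .resample_trajectory(traj, dt)
  nb <- length(traj@times) - 1
  tmid <- traj@times[seq_len(nb)] + dt / 2
  xy <- traj@xy[seq_len(nb), , drop = FALSE]
  tf <- pmax(.temporal_factor(bank, tmid), 0)
  N <- length(pop@centers)
  spikes <- vector("list", N)
  for (i in seq_len(N)) {
    lam <- .spatial_rate(pop, i, xy) * tf
    mu <- lam * dt
    counts <- stats::rpois(nb, mu)
    tot <- sum(counts)
    if (tot == 0) {
      spikes[[i]] <- numeric(0)
    } else {
      idx <- rep.int(seq_len(nb), counts)
      spikes[[i]] <- sort(traj@times[idx] + stats::runif(tot) * dt)
    }
  }
  SpikeTrains(spikes, span = range(traj@times))
}

#' Displace field centers by a fraction of the lattice spacing
#'
#' Every field center of every neuron is moved by a vector of magnitude
#' `fraction * spacing` in an independent uniform random direction
#' (`mode = "fixed"`, matching a single relative-displacement level), or by
#' an isotropic Gaussian offset with that standard deviation
#' (`mode = "gaussian"`). `fraction = 0` is the identity.
#'
#' @param pop a [GridPopulation-class].
#' @param fraction displacement as a fraction of the spacing (e.g. 0.12 for
#'   12 percent).
#' @param mode `"fixed"` magnitude with random direction, or `"gaussian"`.
#' @param seed optional RNG seed.
#' @return A displaced [GridPopulation-class].
#' @export
displaceFields <- function(pop, fraction, mode = c("fixed", "gaussian"),
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0)
  if (fraction == 0) return(pop)
  if (!is.null(seed)) set.seed(seed)
  mag <- fraction * pop@spacing
  pop@centers <- lapply(pop@centers, function(ctr) {
    nk <- nrow(ctr)
    if (mode == "fixed") {
      th <- stats::runif(nk, 0, 2 * pi)
      ctr + mag * cbind(cos(th), sin(th))
    } else {
      ctr + matrix(stats::rnorm(2 * nk, 0, mag), nk)
    }
  })
  pop
}
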