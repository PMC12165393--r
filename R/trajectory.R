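#' Synthetic open-field foraging trajectory
#'
#' Smooth random foraging of a rat in a square arena: the velocity follows a
#' mean-reverting (Ornstein-Uhlenbeck) process whose stationary speed
#' distribution is Rayleigh with the requested mean speed, and positions are
#' reflected at the walls. Over a 30-minute session the trajectory covers
#' essentially the whole arena, emulating the open-field recordings used for
#' grid-cell topology analyses (arena 1.5 m, mean running speeds around
#' 13-16 cm/s).
#'
#' @param duration session length (s).
#' @param arena side of the square arena (m).
#' @param meanSpeed target mean running speed (m/s).
#' @param dt sampling step (s).
#' @param tau velocity autocorrelation time (s); controls path smoothness.
#' @param seed optional RNG seed.
#' @return A [Trajectory-class].
#' @examples
#' tr <- synthTrajectory(60, seed = 1)
#' mean(sqrt(rowSums(apply(tr@xy, 2, diff)^2)) / 0.01)  # ~0.15 m/s
#' @export
synthTrajectory <- function(duration = 1800, arena = 1.5, meanSpeed = 0.15,
                            dt = 0.01, tau = 0.7, seed = NULL) {
  stopifnot(duration > 0, arena > 0, meanSpeed > 0, dt > 0, tau > 0)
  if (!is.null(seed)) set.seed(seed)
  nstep <- ceiling(duration / dt)
  rho <- exp(-dt / tau)
  sigc <- meanSpeed / sqrt(pi / 2)  # per-component stationary sd
  innov_sd <- sigc * sqrt(1 - rho^2)
  vx <- stats::rnorm(1, 0, sigc)
  vy <- stats::rnorm(1, 0, sigc)
  ex <- stats::rnorm(nstep, 0, innov_sd)
  ey <- stats::rnorm(nstep, 0, innov_sd)
  xy <- matrix(0, nstep + 1, 2)
  xy[1, ] <- stats::runif(2, 0.25 * arena, 0.75 * arena)
  x <- xy[1, 1]; y <- xy[1, 2]
  for (i in seq_len(nstep)) {
    vx <- rho * vx + ex[i]
    vy <- rho * vy + ey[i]
    x <- x + vx * dt
    y <- y + vy * dt
    if (x < 0) { x <- -x; vx <- -vx } else if (x > arena) { x <- 2 * arena - x; vx <- -vx }
    if (y < 0) { y <- -y; vy <- -vy } else if (y > arena) { y <- 2 * arena - y; vy <- -vy }
    xy[i + 1, ] <- c(x, y)
  }
  new("Trajectory", times = seq(0, by = dt, length.out = nstep + 1),
      xy = xy, arena = arena)
}

#' Running speed along a trajectory
#'
#' Finite-difference speed at each sample (the last value is repeated so the
#' result aligns with the position samples).
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector of speeds (m/s), one per sample.
#' @export
trajectorySpeed <- function(traj) {
  dt <- diff(traj@times[1:2])
  v <- sqrt(rowSums(diff(traj@xy)^2)) / dt
  c(v, v[length(v)])
}

#' Fraction of spatial bins visited
#'
#' Coverage diagnostic: the fraction of `binSize`-sided spatial bins of the
#' arena visited at least once.
#'
#' @param traj a [Trajectory-class].
#' @param binSize spatial bin side (m).
#' @return scalar in `[0, 1]`.
#' @export
trajectoryCoverage <- function(traj, binSize = 0.05) {
  nb <- ceiling(traj@arena / binSize)
  ix <- pmin(pmax(floor(traj@xy[, 1] / binSize), 0), nb - 1)
  iy <- pmin(pmax(floor(traj@xy[, 2] / binSize), 0), nb - 1)
  length(unique(ix * nb + iy)) / (nb * nb)
}

# resample a trajectory to step dt by linear interpolation
.resample_trajectory <- function(traj, dt) {
  cur <- diff(traj@times[1:2])
  if (abs(cur - dt) < 1e-12) return(traj)
  tt <- seq(traj@times[1], traj@times[length(traj@times)], by = dt)
  new("Trajectory", times = tt,
      xy = cbind(stats::approx(traj@times, traj@xy[, 1], tt)$y,
                 stats::approx(traj@times, traj@xy[, 2], tt)$y),
      arena = traj@arena)
}
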