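#' Fit a sigmoid to toroidality-versus-perturbation data
#'
#' Least-squares fit of `s(x) = L / (1 + exp(-k (x - xc))) + b` via
#' Levenberg-Marquardt. For decaying data the fitted amplitude `L` is
#' negative (with `k > 0`) or equivalently `k` is negative with `L > 0`;
#' the inflection point `xc` and the slope there, `L k / 4`, are reported.
#' Initialization: `b` from the early plateau, `L` from the plateau
#' difference, `xc` at the half-crossing, `k` from the steepest empirical
#' slope; `xc` is kept within the sampled range.
#'
#' @param x perturbation magnitudes (ascending).
#' @param y response values (e.g. a Gamma component).
#' @return A [SigmoidFit-class].
#' @examples
#' x <- seq(0, 500, by = 25)
#' y <- -0.6 / (1 + exp(-0.02 * (x - 250))) + 0.8
#' fitSigmoid(x, y)
#' @export
fitSigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (stats::sd(y) < 1e-8) stop("degenerate fit: response is constant")
  lowConf <- length(x) < 5
  nh <- max(1L, floor(length(x) / 4))
  b0 <- mean(y[seq_len(nh)])
  yend <- mean(y[seq(length(y) - nh + 1, length(y))])
  L0 <- yend - b0
  if (abs(L0) < 1e-8) L0 <- -(max(y) - min(y))
  half <- b0 + L0 / 2
  xc0 <- x[which.min(abs(y - half))]
  slopes <- diff(y) / pmax(diff(x), 1e-12)
  smax <- slopes[which.max(abs(slopes))]
  k0 <- 4 * smax / L0
  if (!is.finite(k0) || k0 == 0) k0 <- 1 / (diff(range(x)) / 4)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - xc))) + b, data = dat,
      start = list(L = L0, k = k0, xc = xc0, b = b0),
      lower = c(-Inf, -Inf, min(x), -Inf),
      upper = c(Inf, Inf, max(x), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit did not converge: ", conditionMessage(e)))
  p <- stats::coef(fit)
  new("SigmoidFit", L = unname(p["L"]), k = unname(p["k"]),
      xc = unname(p["xc"]), b = unname(p["b"]),
      slopeAtInflection = unname(p["L"] * p["k"] / 4),
      residuals = as.numeric(stats::resid(fit)), lowConfidence = lowConf)
}

#' Critical timescale from two sigmoid fits
#'
#' The minimum of the two inflection points of the sigmoid fits of `Gamma1`
#' and `Gamma2` against the perturbation magnitude -- a lower bound on the
#' perturbation scale that destroys toroidality.
#'
#' @param fit1,fit2 [SigmoidFit-class] objects (for `Gamma1` and `Gamma2`).
#' @return scalar, `min(xc1, xc2)` (units of the fitted x axis).
#' @examples
#' # inflection points 160 and 103 ms give a critical timescale of 103 ms
#' @export
criticalTimescale <- function(fit1, fit2) {
  min(fit1@xc, fit2@xc)
}

#' Average behavioral timescale of a grid module
#'
#' The ratio between grid spacing and the animal's average running speed:
#' the (straight-line) time to travel from one grid field to the next.
#'
#' @param spacing grid spacing (any length unit).
#' @param meanSpeed average speed (same length unit per second).
#' @return time in seconds.
#' @examples
#' behavioralTimescale(61, 16.1)   # ~3.8 s
#' behavioralTimescale(105, 13.1)  # ~8.0 s
#' @export
behavioralTimescale <- function(spacing, meanSpeed) {
  stopifnot(meanSpeed > 0)
  spacing / meanSpeed
}

#' Occupancy-normalized ratemap of one neuron
#'
#' Spatial firing-rate map: smoothed spike-count map divided by the smoothed
#' occupancy map, on square bins of side `bin`. Samples with running speed
#' below `speedMin` are excluded from both maps; never-visited bins are NA.
#'
#' @param spikeTimes numeric vector of one neuron's spike times (s).
#' @param traj a [Trajectory-class] covering the spikes.
#' @param bin spatial bin (m).
#' @param smoothSigma Gaussian smoothing width (m).
#' @param speedMin speed filter (m/s).
#' @return list with `rate` (matrix, Hz), `x`, `y` bin centers, and
#'   `occupancy` (s).
#' @export
rateMap <- function(spikeTimes, traj, bin = 0.03, smoothSigma = 0.05,
                    speedMin = 0.025) {
  dt <- diff(traj@times[1:2])
  sp <- trajectorySpeed(traj)
  ok <- sp >= speedMin
  nb <- ceiling(traj@arena / bin)
  bx <- function(v) pmin(pmax(floor(v / bin), 0), nb - 1) + 1
  occ <- matrix(0, nb, nb)
  tab <- table(factor(bx(traj@xy[ok, 1]), levels = 1:nb),
               factor(bx(traj@xy[ok, 2]), levels = 1:nb))
  occ <- occ + as.numeric(tab) * dt
  dim(occ) <- c(nb, nb)
  # spike positions by interpolation; apply the same speed filter
  st <- spikeTimes[spikeTimes >= traj@times[1] & spikeTimes <= traj@times[length(traj@times)]]
  sxy <- cbind(stats::approx(traj@times, traj@xy[, 1], st)$y,
               stats::approx(traj@times, traj@xy[, 2], st)$y)
  sok <- stats::approx(traj@times, as.numeric(ok), st, method = "constant",
                       rule = 2)$y > 0.5
  sxy <- sxy[sok, , drop = FALSE]
  cnt <- matrix(0, nb, nb)
  if (nrow(sxy)) {
    tabs <- table(factor(bx(sxy[, 1]), levels = 1:nb),
                  factor(bx(sxy[, 2]), levels = 1:nb))
    cnt <- matrix(as.numeric(tabs), nb, nb)
  }
  g <- .gauss2d_smooth
  occ_s <- g(occ, smoothSigma / bin)
  cnt_s <- g(cnt, smoothSigma / bin)
  rate <- cnt_s / occ_s
  rate[occ_s < 1e-9] <- NA
  ctr <- (seq_len(nb) - 0.5) * bin
  list(rate = rate, x = ctr, y = ctr, occupancy = occ)
}

# separable 2D Gaussian smoothing of a matrix (sigma in bins)
.gauss2d_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm_vec <- function(v) {
    out <- as.numeric(stats::filter(v, k, sides = 2))
    # renormalize near the edges (truncated kernel)
    w <- as.numeric(stats::filter(rep(1, length(v)), k, sides = 2))
    out[is.na(out)] <- 0; w[is.na(w)] <- 1
    out / w
  }
  m2 <- apply(m, 2, sm_vec)
  t(apply(m2, 1, sm_vec))
}

#' Spatial autocorrelogram of a ratemap
#'
#' Pearson correlation of the map with itself at every 2D offset, using only
#' overlapping valid bins per offset (offsets with fewer than `minOverlap`
#' bins are NA). Computed with FFT-based sums.
#'
#' @param rate ratemap matrix (NAs allowed).
#' @param minOverlap minimal number of overlapping bins.
#' @return autocorrelation matrix of size `(2 nrow - 1) x (2 ncol - 1)`.
#' @export
spatialAutocorrelogram <- function(rate, minOverlap = 20) {
  m <- rate
  valid <- is.finite(m) * 1
  m[!is.finite(m)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  pr <- 2 * nr - 1; pc <- 2 * nc - 1
  pad <- function(a) {
    out <- matrix(0, pr, pc)
    out[1:nr, 1:nc] <- a
    out
  }
  xcorr <- function(a, b) {
    # full 2D cross-correlation sum_{s} a(s) b(s + lag)
    fa <- stats::fft(pad(a))
    fb <- stats::fft(pad(b))
    re <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
    # reorder so the zero lag is centered
    re[c((nr + 1):pr, 1:nr), c((nc + 1):pc, 1:nc)]
  }
  nol <- xcorr(valid, valid)
  sx <- xcorr(m, valid)
  sy <- xcorr(valid, m)
  sxy <- xcorr(m, m)
  sxx <- xcorr(m * m, valid)
  syy <- xcorr(valid, m * m)
  nol_r <- round(nol)
  num <- nol * sxy - sx * sy
  den <- sqrt(pmax(nol * sxx - sx^2, 0) * pmax(nol * syy - sy^2, 0))
  ac <- num / den
  ac[nol_r < minOverlap | den < 1e-12] <- NA
  ac
}

#' Grid score of a ratemap
#'
#' Rotational-symmetry statistic of the spatial autocorrelogram: on an
#' annulus around the central peak, the minimum of the correlations of the
#' autocorrelogram with its 60- and 120-degree rotations minus the maximum
#' of the correlations with the 30-, 90- and 150-degree rotations. Hexagonal
#' maps score high (the 60/120 rotations match), square lattices score
#' negative (the 90-degree rotation matches instead). Range `[-2, 2]`.
#'
#' The annulus extends from the first trough of the radial autocorrelation
#' profile to 1.25 times the first peak radius beyond it.
#'
#' @param rm a ratemap as returned by [rateMap()], or a plain matrix.
#' @return scalar grid score.
#' @export
gridScore <- function(rm) {
  rate <- if (is.list(rm)) rm$rate else rm
  ac <- spatialAutocorrelogram(rate)
  n <- nrow(ac)
  c0 <- (n + 1) / 2
  # radial profile
  maxr <- floor((n - 1) / 2)
  rr <- seq_len(maxr)
  prof <- vapply(rr, function(r) {
    th <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * r)))
    vals <- .bilinear(ac, c0 + r * cos(th), c0 + r * sin(th))
    mean(vals, na.rm = TRUE)
  }, 0)
  # first trough then first peak after it
  trough <- NA
  for (i in 2:(length(prof) - 1)) {
    if (!is.na(prof[i]) && prof[i] <= prof[i - 1] && prof[i] <= prof[i + 1]) {
      trough <- i; break
    }
  }
  if (is.na(trough)) stop("degenerate autocorrelogram: no trough found")
  peak <- NA
  i <- trough + 1
  while (i < length(prof)) {
    if (!is.na(prof[i]) && prof[i] >= prof[i - 1] && prof[i] >= prof[i + 1]) {
      peak <- i; break
    }
    i <- i + 1
  }
  if (is.na(peak)) peak <- min(length(prof), 2 * trough)
  r_in <- trough
  r_out <- min(maxr - 1, ceiling(1.25 * peak))
  if (r_out <= r_in) r_out <- min(maxr - 1, r_in + 2)
  # annulus sample points
  pts <- do.call(rbind, lapply(seq(r_in, r_out), function(r) {
    th <- seq(0, 2 * pi, length.out = max(24, ceiling(2 * pi * r)) + 1)[-1]
    cbind(r * cos(th), r * sin(th))
  }))
  base <- .bilinear(ac, c0 + pts[, 1], c0 + pts[, 2])
  corr_at <- function(deg) {
    a <- deg * pi / 180
    rx <- pts[, 1] * cos(a) - pts[, 2] * sin(a)
    ry <- pts[, 1] * sin(a) + pts[, 2] * cos(a)
    rot <- .bilinear(ac, c0 + rx, c0 + ry)
    ok <- is.finite(base) & is.finite(rot)
    if (sum(ok) < 10) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }
  min(corr_at(60), corr_at(120)) - max(corr_at(30), corr_at(90), corr_at(150))
}

# bilinear interpolation of matrix values at fractional (row, col) positions
.bilinear <- function(m, ri, ci) {
  n <- nrow(m); p <- ncol(m)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  val <- function(r, c) {
    out <- rep(NA_real_, length(r))
    ok <- r >= 1 & r <= n & c >= 1 & c <= p
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  v00 <- val(r0, c0); v10 <- val(r0 + 1, c0)
  v01 <- val(r0, c0 + 1); v11 <- val(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Power spectral density of a spike train
#'
#' Spike counts are binned at `1/fs`, Fourier transformed, and the power
#' normalized so that it sums to one over the frequency range `[0.1, 500]`
#' Hz (compensating rate differences between neurons). A homogeneous Poisson
#' train yields a flat spectrum; oscillatory rate modulation produces peaks
#' at the modulating frequencies.
#'
#' @param spikeTimes numeric vector of spike times (s), or a
#'   [SpikeTrains-class] (neurons are averaged after normalization).
#' @param fs sampling rate (Hz) of the count series.
#' @param duration analysis span (s); defaults to the full span.
#' @param normRange frequency range (Hz) over which power is normalized.
#' @return list with `freq` (Hz) and `power` (normalized), class
#'   `spectralResult`.
#' @export
spikePSD <- function(spikeTimes, fs = 1000, duration = NULL,
                     normRange = c(0.1, 500)) {
  if (is(spikeTimes, "SpikeTrains")) {
    specs <- lapply(spikeTimes@spikes, spikePSD, fs = fs,
                    duration = duration %||% diff(spikeTimes@span),
                    normRange = normRange)
    specs <- specs[!vapply(specs, is.null, TRUE)]
    if (!length(specs)) stop("no nonempty spike trains")
    pw <- rowMeans(do.call(cbind, lapply(specs, `[[`, "power")))
    out <- list(freq = specs[[1]]$freq, power = pw / sum(pw))
    class(out) <- "spectralResult"
    return(out)
  }
  if (!length(spikeTimes)) return(NULL)
  if (is.null(duration)) duration <- max(spikeTimes)
  if (duration <= 10) stop("need more than 10 s of data")
  nb <- floor(duration * fs)
  ix <- floor(spikeTimes[spikeTimes < duration] * fs) + 1
  cnt <- tabulate(ix, nbins = nb)
  X <- stats::fft(cnt - mean(cnt))
  nf <- floor(nb / 2)
  freq <- (seq_len(nf)) * fs / nb
  pw <- Mod(X[seq_len(nf) + 1])^2
  inr <- freq >= normRange[1] & freq <= normRange[2]
  tot <- sum(pw[inr])
  if (tot <= 0) stop("empty spectrum")
  out <- list(freq = freq[inr], power = pw[inr] / tot)
  class(out) <- "spectralResult"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band power of a normalized spectrum
#'
#' Sum of the normalized power within `[band[1], band[2])` Hz. Disjoint
#' bands partition the total power additively.
#'
#' @param spec result of [spikePSD()].
#' @param band length-2 frequency range (Hz).
#' @return scalar band power.
#' @export
bandPower <- function(spec, band) {
  stopifnot(length(band) == 2, band[2] > band[1])
  sel <- spec$freq >= band[1] & spec$freq < band[2]
  if (!any(sel)) stop("empty band")
  sum(spec$power[sel])
}

#' Eta-to-theta band-power ratio
#'
#' `A_eta / A_theta` with default bands `[2.5, 5.9)` Hz (eta) and
#' `[5.9, 11)` Hz (theta); band edges are dataset-specific and configurable.
#'
#' @param spec result of [spikePSD()].
#' @param etaBand,thetaBand band edges (Hz).
#' @return scalar ratio.
#' @export
etaThetaRatio <- function(spec, etaBand = c(2.5, 5.9), thetaBand = c(5.9, 11)) {
  bandPower(spec, etaBand) / bandPower(spec, thetaBand)
}

#' Toroidality under increasing spike-time jitter
#'
#' Runs the TDA pipeline on jittered copies of the spike trains for each
#' jitter magnitude, scores toroidality against the data-mode reference of
#' the unjittered barcodes, fits sigmoids to `Gamma1` and `Gamma2` versus
#' jitter, and reports the critical timescale (minimum inflection point).
#'
#' @param spikes a [SpikeTrains-class].
#' @param deltaTs jitter magnitudes (s), ascending; 0 is added if missing.
#' @param nJitterSeeds jitter realizations per magnitude.
#' @param config pipeline parameters ([tdaConfig()]).
#' @param seed master RNG seed.
#' @return list with `table` (data.frame: deltaT, seed, gamma1, gamma2),
#'   `fit1`, `fit2` ([SigmoidFit-class]), and `deltaTC` (s).
#' @export
jitterSweep <- function(spikes, deltaTs = 10^seq(log10(0.01), log10(2),
                                                 length.out = 10),
                        nJitterSeeds = 3, config = tdaConfig(), seed = 1) {
  deltaTs <- sort(unique(c(0, deltaTs)))
  base <- runTDA(spikes, config, seed = seed)
  ref <- makeReference(base, "data")
  rows <- list()
  for (di in seq_along(deltaTs)) {
    dt <- deltaTs[di]
    ns <- if (dt == 0) 1 else nJitterSeeds
    for (s in seq_len(ns)) {
      sj <- if (dt == 0) spikes else
        jitterSpikes(spikes, dt, seed = seed + 7919 * di + s)
      bs <- if (dt == 0) base else runTDA(sj, config, seed = seed)
      sc <- toroidality(bs, reference = ref)
      rows[[length(rows) + 1]] <- data.frame(deltaT = dt, seed = s,
        gamma1 = sc@gamma1, gamma2 = sc@gamma2)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(gamma1, gamma2) ~ deltaT, tab, mean)
  fit1 <- tryCatch(fitSigmoid(agg$deltaT, agg$gamma1), error = function(e) NULL)
  fit2 <- tryCatch(fitSigmoid(agg$deltaT, agg$gamma2), error = function(e) NULL)
  dtc <- if (!is.null(fit1) && !is.null(fit2)) criticalTimescale(fit1, fit2) else NA_real_
  list(table = tab, fit1 = fit1, fit2 = fit2, deltaTC = dtc)
}

#' Toroidality versus population size
#'
#' Draws `reps` random neuron subsets of each size, runs the pipeline on
#' each subset and averages the toroidality (data-mode reference from each
#' subset's own barcodes; subsets whose barcodes cannot support a reference
#' yield NA and are dropped from the average).
#'
#' @param spikes a [SpikeTrains-class].
#' @param sizes subset sizes (at most the population size).
#' @param reps subsets per size (the full population is run once).
#' @param config pipeline parameters.
#' @param seed master RNG seed.
#' @return data.frame: `nCells`, `meanGamma1`, `meanGamma2`, `nValid`.
#' @export
subsampleCurve <- function(spikes, sizes, reps = 30, config = tdaConfig(),
                           seed = 1) {
  N <- nNeurons(spikes)
  stopifnot(all(sizes >= 1), all(sizes <= N))
  out <- data.frame()
  for (sz in sizes) {
    rp <- if (sz == N) 1 else reps
    g1 <- g2 <- rep(NA_real_, rp)
    for (r in seq_len(rp)) {
      set.seed(seed + 131 * sz + r)
      sel <- sort(sample.int(N, sz))
      sub <- new("SpikeTrains", spikes = spikes@spikes[sel], span = spikes@span)
      sc <- tryCatch({
        bs <- runTDA(sub, config, seed = seed + r)
        toroidality(bs, referenceMode = "data")
      }, error = function(e) NULL)
      if (!is.null(sc)) { g1[r] <- sc@gamma1; g2[r] <- sc@gamma2 }
    }
    out <- rbind(out, data.frame(nCells = sz,
      meanGamma1 = mean(g1, na.rm = TRUE), meanGamma2 = mean(g2, na.rm = TRUE),
      nValid = sum(is.finite(g1))))
  }
  out
}

# shared runner: simulate one population realization and score toroidality
.simulate_and_score <- function(seed, bank, N = 75, spacing = 0.85,
                                kind = "hexagonal", sigma = 0.12, G0 = 1.5,
                                displacement = 0, duration = 1800,
                                referenceMode = "self", config = tdaConfig(),
                                arena = 1.5) {
  pop <- gridPopulation(N = N, spacing = spacing, kind = kind, sigma = sigma,
                        G0 = G0, arena = arena, seed = seed)
  if (displacement > 0) pop <- displaceFields(pop, displacement, seed = seed + 1)
  traj <- synthTrajectory(duration, arena = arena, seed = seed + 2)
  spikes <- simulateGridModule(pop, traj, bank, seed = seed + 3)
  bs <- runTDA(spikes, config, seed = seed + 4)
  sc <- toroidality(bs, referenceMode = referenceMode)
  gap <- tryCatch(h1h2Gap(bs), error = function(e) NA_real_)
  list(score = sc, gap = gap, barcodes = bs, spikes = spikes)
}

#' Toroidality versus grid-field displacement
#'
#' For each displacement level (fraction of the grid spacing), simulates
#' `nSeeds` oscillation-modulated populations with displaced field centers,
#' runs the TDA pipeline and reports mean and sd of the toroidality
#' components (self-mode reference).
#'
#' @param fractions displacement levels (fractions of spacing, e.g.
#'   `c(0, 0.06, 0.12, 0.18, 0.24)`).
#' @param nSeeds simulated realizations per level.
#' @param bank oscillator bank (default the dominant-eta/theta bank).
#' @param duration session length (s).
#' @param config pipeline parameters.
#' @param seed master RNG seed.
#' @param ... further simulator arguments passed to the runner.
#' @return data.frame: `fraction`, `meanGamma1`, `sdGamma1`, `meanGamma2`,
#'   `sdGamma2`.
#' @export
displacementSweep <- function(fractions = c(0, 0.06, 0.12, 0.18, 0.24),
                              nSeeds = 3,
                              bank = buildOscillatorBank("methods_default"),
                              duration = 1800, config = tdaConfig(),
                              seed = 1, ...) {
  out <- data.frame()
  for (fi in seq_along(fractions)) {
    g1 <- g2 <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
      r <- .simulate_and_score(seed + 100 * fi + s, bank,
        displacement = fractions[fi], duration = duration, config = config, ...)
      g1[s] <- r$score@gamma1; g2[s] <- r$score@gamma2
    }
    out <- rbind(out, data.frame(fraction = fractions[fi],
      meanGamma1 = mean(g1), sdGamma1 = stats::sd(g1),
      meanGamma2 = mean(g2), sdGamma2 = stats::sd(g2)))
  }
  out
}

#' Toroidality versus single-oscillator frequency
#'
#' Simulates populations modulated by a single dominant oscillator of
#' varying frequency (plus the background bank) and reports the mean and
#' variance of the toroidality components across realizations. The variance
#' of `Gamma2` dips when the dominant frequency falls in the eta-theta
#' range.
#'
#' @param freqs dominant frequencies (Hz).
#' @param nSeeds realizations per frequency.
#' @param duration session length (s).
#' @param config pipeline parameters.
#' @param seed master RNG seed.
#' @param ... further simulator arguments.
#' @return data.frame: `freq`, mean/sd/var of `Gamma1` and `Gamma2`.
#' @export
frequencySweep <- function(freqs, nSeeds = 3, duration = 1800,
                           config = tdaConfig(), seed = 1, ...) {
  out <- data.frame()
  for (fi in seq_along(freqs)) {
    bank <- buildOscillatorBank("single", freq = freqs[fi])
    g1 <- g2 <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
      r <- .simulate_and_score(seed + 1000 * fi + s, bank,
        duration = duration, config = config, ...)
      g1[s] <- r$score@gamma1; g2[s] <- r$score@gamma2
    }
    out <- rbind(out, data.frame(freq = freqs[fi],
      meanGamma1 = mean(g1), sdGamma1 = stats::sd(g1),
      meanGamma2 = mean(g2), sdGamma2 = stats::sd(g2),
      varGamma2 = stats::var(g2)))
  }
  out
}

#' Toroidality versus field gain, with and without oscillations
#'
#' Sweeps the field gain `G0` (which controls the mean firing rate) for
#' oscillation-modulated and oscillation-free populations.
#'
#' @param G0s field-gain values.
#' @param nSeeds realizations per condition.
#' @param duration session length (s).
#' @param config pipeline parameters.
#' @param seed master RNG seed.
#' @param ... further simulator arguments.
#' @return data.frame: `G0`, `oscillations`, mean/sd of the components.
#' @export
gainSweep <- function(G0s, nSeeds = 3, duration = 1800, config = tdaConfig(),
                      seed = 1, ...) {
  bank_on <- buildOscillatorBank("methods_default")
  bank_off <- buildOscillatorBank("none")
  out <- data.frame()
  for (gi in seq_along(G0s)) {
    for (osc in c(TRUE, FALSE)) {
      bank <- if (osc) bank_on else bank_off
      g1 <- g2 <- numeric(nSeeds)
      for (s in seq_len(nSeeds)) {
        r <- .simulate_and_score(seed + 5000 * gi + 500 * osc + s, bank,
          G0 = G0s[gi], duration = duration, config = config, ...)
        g1[s] <- r$score@gamma1; g2[s] <- r$score@gamma2
      }
      out <- rbind(out, data.frame(G0 = G0s[gi], oscillations = osc,
        meanGamma1 = mean(g1), sdGamma1 = stats::sd(g1),
        meanGamma2 = mean(g2), sdGamma2 = stats::sd(g2)))
    }
  }
  out
}
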