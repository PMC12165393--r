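test_that("sigmoid parameters are recovered on noiseless synthetic data", {
  x <- seq(0, 500, by = 20)
  y <- -0.6 / (1 + exp(-0.02 * (x - 250))) + 0.8
  f <- fitSigmoid(x, y)
  expect_equal(f@L, -0.6, tolerance = 0.01)
  expect_equal(f@k, 0.02, tolerance = 0.01)
  expect_equal(f@xc, 250, tolerance = 0.01)
  expect_equal(f@b, 0.8, tolerance = 0.01)
  expect_equal(f@slopeAtInflection, -0.6 * 0.02 / 4, tolerance = 0.01)
  expect_error(fitSigmoid(x, rep(0.5, length(x))), "degenerate")
})

test_that("sigmoid inflection recovery survives noise (Monte Carlo)", {
  set.seed(21)
  x <- seq(0, 500, by = 25)
  ok <- 0
  n_trials <- 50
  for (i in seq_len(n_trials)) {
    y <- -0.6 / (1 + exp(-0.02 * (x - 250))) + 0.8 + rnorm(length(x), 0, 0.02)
    f <- tryCatch(fitSigmoid(x, y), error = function(e) NULL)
    if (!is.null(f) && abs(f@xc - 250) / 250 < 0.1) ok <- ok + 1
  }
  expect_gte(ok / n_trials, 0.9)
})

test_that("critical timescale is the smaller inflection point", {
  mk <- function(xc) new("SigmoidFit", L = -0.5, k = 0.02, xc = xc, b = 0.8,
                         slopeAtInflection = -0.0025, residuals = 0,
                         lowConfidence = FALSE)
  expect_equal(criticalTimescale(mk(160), mk(103)), 103)
  expect_equal(criticalTimescale(mk(484), mk(625)), 484)
  expect_equal(criticalTimescale(mk(300), mk(300)), 300)
})

test_that("behavioral timescale is spacing over speed", {
  expect_equal(round(behavioralTimescale(61, 16.1), 1), 3.8)
  expect_equal(round(behavioralTimescale(105, 13.1), 1), 8.0)
  expect_equal(behavioralTimescale(0, 10), 0)
  expect_error(behavioralTimescale(61, 0))
})

test_that("ratemaps are occupancy-normalized and peak at planted fields", {
  # homogeneous Poisson spikes on a covering trajectory -> flat map near lambda
  traj <- synthTrajectory(600, seed = 31)
  set.seed(32)
  lam <- 12
  spk <- sort(runif(rpois(1, lam * 600), 0, 600))
  rm1 <- rateMap(spk, traj, bin = 0.15, smoothSigma = 0.15)
  vals <- rm1$rate[is.finite(rm1$rate)]
  expect_equal(median(vals), lam, tolerance = 0.2)
  # no spikes -> all-zero map
  rm0 <- rateMap(numeric(0), traj)
  expect_true(all(rm0$rate[is.finite(rm0$rate)] == 0))
  # simulated grid cell peaks near its planted centers
  pop <- gridPopulation(N = 1, spacing = 0.85, sigma = 0.12, seed = 33)
  sp <- simulateGridModule(pop, traj, buildOscillatorBank("none"), seed = 34)
  rm2 <- rateMap(sp@spikes[[1]], traj)
  peak <- which(rm2$rate == max(rm2$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ppos <- c(rm2$x[peak[1]], rm2$y[peak[2]])
  dctr <- sqrt(min(colSums((t(pop@centers[[1]]) - ppos)^2)))
  expect_lt(dctr, 0.12 / 2 + 0.03)
})

test_that("grid score separates hexagonal from square field maps", {
  mkmap <- function(kind) {
    ctr <- makeCenters(0.4, kind, shift = c(0.2, 0.2), arena = 1.5, margin = 0.2)
    g <- expand.grid(x = seq(0.015, 1.485, by = 0.03),
                     y = seq(0.015, 1.485, by = 0.03))
    z <- rep(0, nrow(g))
    for (k in seq_len(nrow(ctr)))
      z <- z + exp(-((g$x - ctr[k, 1])^2 + (g$y - ctr[k, 2])^2) / (2 * 0.08^2))
    matrix(z, 50, 50)
  }
  gs_hex <- gridScore(mkmap("hexagonal"))
  gs_sq <- gridScore(mkmap("square"))
  expect_gt(gs_hex, 0.5)
  expect_lt(gs_sq, 0)
  expect_gte(gs_hex, -2); expect_lte(gs_hex, 2)
})

test_that("PSD is flat for Poisson trains and peaked for rate-modulated ones", {
  set.seed(41)
  Tdur <- 200
  # homogeneous Poisson: flat spectrum, band power ~ band width
  spk <- sort(runif(rpois(1, 25 * Tdur), 0, Tdur))
  ps <- spikePSD(spk, duration = Tdur)
  w1 <- bandPower(ps, c(2.5, 5.9)) / ((5.9 - 2.5) / (500 - 0.1))
  expect_equal(w1, 1, tolerance = 0.25)
  # partition of the normalized range sums to one
  edges <- c(0.1, 2, 8, 50, 200, 500.0001)
  parts <- vapply(seq_len(5), function(i) bandPower(ps, edges[i:(i + 1)]), 0)
  expect_equal(sum(parts), 1, tolerance = 1e-9)
  # 8 Hz cosine-modulated train peaks at 8 Hz
  tt <- seq(0, Tdur, by = 1e-3)
  lam <- 20 * (1 + 0.9 * cos(2 * pi * 8 * tt)) * 1e-3
  spk8 <- tt[runif(length(tt)) < lam]
  ps8 <- spikePSD(spk8, duration = Tdur)
  expect_equal(ps8$freq[which.max(ps8$power)], 8, tolerance = 0.02)
  # eta/theta ratio rises when the 4 Hz line is boosted relative to 8 Hz
  lam4 <- 20 * (1 + 0.9 * cos(2 * pi * 4 * tt)) * 1e-3
  spk4 <- tt[runif(length(tt)) < lam4]
  expect_gt(etaThetaRatio(spikePSD(spk4, duration = Tdur)),
            etaThetaRatio(ps8))
})

test_that("simulated oscillatory cells express eta and theta spectral peaks", {
  bank <- buildOscillatorBank("methods_default")
  pop <- gridPopulation(N = 6, spacing = 0.85, sigma = 0.12, seed = 42)
  traj <- synthTrajectory(600, seed = 43)
  sp <- simulateGridModule(pop, traj, bank, seed = 44)
  ps <- spikePSD(sp, duration = 600)
  # the planted lines sit on exact Fourier bins; compare the line power to
  # the local median level (max of ~25 bins of a flat spectrum stays ~6x
  # its median, so 12 separates lines from floor)
  peak_ratio <- function(f0)
    max(ps$power[abs(ps$freq - f0) <= 0.02]) /
      median(ps$power[abs(ps$freq - f0) <= 1])
  expect_gt(peak_ratio(4), 12)
  expect_gt(peak_ratio(8), 12)
})

test_that("sub-critical jitter leaves grid scores essentially unchanged", {
  bank <- buildOscillatorBank("methods_default")
  pop <- gridPopulation(N = 5, spacing = 0.85, sigma = 0.12, seed = 900)
  traj <- synthTrajectory(1800, seed = 901)
  sp <- simulateGridModule(pop, traj, bank, seed = 902)
  gs <- function(spk) mean(vapply(seq_len(5), function(i)
    gridScore(rateMap(spk@spikes[[i]], traj)), 0))
  g0 <- gs(sp)
  gj <- gs(jitterSpikes(sp, 0.125, seed = 904))
  expect_gt(g0, 0.5)                 # hexagonal fields score high
  expect_lt(abs(gj - g0), 0.05)      # 125 ms jitter barely moves them
})

test_that("jitter sweep bookkeeping matches its definition", {
  # small, fast configuration: fewer vectors and points
  pop <- gridPopulation(N = 30, spacing = 0.85, sigma = 0.12, seed = 51)
  traj <- synthTrajectory(420, seed = 52)
  sp <- simulateGridModule(pop, traj, buildOscillatorBank("methods_default"),
                           seed = 53)
  cfg <- tdaConfig(k = 4000, nPoints = 400)
  js <- jitterSweep(sp, deltaTs = c(0.05, 5), nJitterSeeds = 2, config = cfg,
                    seed = 54)
  tab <- js$table
  # the zero-jitter entry equals the unjittered pipeline score against the
  # data-mode reference of the unjittered barcodes
  base <- runTDA(sp, cfg, seed = 54)
  sc0 <- toroidality(base, reference = makeReference(base, "data"))
  expect_equal(tab$gamma1[tab$deltaT == 0], gamma1(sc0))
  expect_equal(tab$gamma2[tab$deltaT == 0], gamma2(sc0))
  expect_equal(nrow(tab), 1 + 2 * 2)
  expect_true(all(tab$gamma1 >= 0 & tab$gamma1 <= 1))
})

test_that("large spike-time jitter collapses the H1/H2 coexistence gap", {
  # the torus signature (long H2 cavity born while the long H1 loops are
  # alive) survives 100 ms jitter and is destroyed by 1.5 s jitter
  pop <- gridPopulation(N = 75, spacing = 0.85, sigma = 0.12, seed = 700)
  traj <- synthTrajectory(1800, seed = 701)
  sp <- simulateGridModule(pop, traj, buildOscillatorBank("methods_default"),
                           seed = 702)
  gap0 <- h1h2Gap(runTDA(sp, seed = 703))
  gap_small <- h1h2Gap(runTDA(jitterSpikes(sp, 0.1, seed = 704), seed = 703))
  gap_big <- h1h2Gap(runTDA(jitterSpikes(sp, 1.5, seed = 704), seed = 703))
  expect_gt(gap0, 0.03)
  expect_gt(gap_small, 0.05)
  expect_lt(gap_big, 0.02)
})
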