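test_that("lattice centers have the right neighbour geometry", {
  for (kind in c("hexagonal", "square")) {
    ctr <- makeCenters(0.85, kind, shift = c(0.1, 0.2), arena = 1.5,
                       margin = 0.4)
    D <- as.matrix(dist(ctr))
    diag(D) <- Inf
    expect_equal(min(D), 0.85, tolerance = 1e-9)
    # an interior point has 6 (hex) or 4 (square) nearest neighbours
    interior <- which(ctr[, 1] > 0.4 & ctr[, 1] < 1.1 &
                      ctr[, 2] > 0.4 & ctr[, 2] < 1.1)[1]
    nn <- sum(abs(D[interior, ] - 0.85) < 1e-9)
    expect_equal(nn, if (kind == "hexagonal") 6 else 4)
  }
  # shifting by one lattice vector reproduces the interior center set
  a <- makeCenters(0.5, "hexagonal", shift = c(0, 0), arena = 1.5, margin = 0.5)
  b <- makeCenters(0.5, "hexagonal", shift = c(0.5, 0), arena = 1.5, margin = 0.5)
  inA <- a[a[, 1] > 0 & a[, 1] < 1.5 & a[, 2] > 0 & a[, 2] < 1.5, ]
  match_ok <- apply(inA, 1, function(p) min(colSums((t(b) - p)^2)) < 1e-18)
  expect_true(all(match_ok))
})

test_that("firing rate follows the truncated-Gaussian field model", {
  # a single neuron with one isolated field at a known position
  pop <- gridPopulation(N = 1, spacing = 0.85, sigma = 0.12, x0 = 0.4,
                        lambda0 = 0.05, G0 = 1.5, arena = 1.5, seed = 1)
  pop@centers[[1]] <- matrix(c(0.75, 0.75), 1, 2)
  none <- buildOscillatorBank("none")
  # far from the field: baseline only
  expect_equal(firingRate(pop, none, 1, c(0.05, 0.05), 0), 0.05)
  # at the field center: lambda0 + G0 / (2 pi sigma^2) ~ 16.63 Hz
  at_ctr <- firingRate(pop, none, 1, c(0.75, 0.75), 0)
  expect_equal(at_ctr, 0.05 + 1.5 / (2 * pi * 0.12^2), tolerance = 1e-9)
  expect_equal(at_ctr, 16.63, tolerance = 1e-3)
  # the Heaviside truncation kills contributions beyond x0
  expect_equal(firingRate(pop, none, 1, c(0.75 + 0.401, 0.75), 0), 0.05,
               tolerance = 1e-9)
  # rectification keeps rates nonnegative under strong negative modulation
  neg <- new("OscillatorBank", omegas = 2, amps = 10, c1 = 0, c2 = 1)
  expect_gte(min(firingRate(pop, neg, 1, c(0.75, 0.75),
                            seq(0, 1, by = 0.01))), 0)
})

test_that("oscillator bank presets match their stated structure", {
  none <- buildOscillatorBank("none")
  expect_equal(length(none@omegas), 0)
  expect_equal(gridtorus:::.temporal_factor(none, seq(0, 1, 0.01)),
               rep(1, 101))
  bk <- buildOscillatorBank("methods_default")
  expect_equal(length(bk@omegas), 200)
  expect_true(all(c(4, 8) %in% bk@omegas))
  a4 <- bk@amps[bk@omegas == 4]
  a8 <- bk@amps[bk@omegas == 8]
  # amplitude laws: 0.5 w^-1/2 at 4 Hz, 0.8 w^-1/2 at 8 Hz
  expect_equal(a8 / a4, (0.8 / 0.5) * (8 / 4)^(-0.5), tolerance = 1e-12)
  expect_equal(bk@c1, 0)
  sg <- buildOscillatorBank("single", freq = 11)
  expect_equal(length(sg@omegas), 200)
  expect_equal(sg@amps[sg@omegas == 4], 0)  # eta line silenced
  expect_equal(sg@amps[abs(sg@omegas - 11) < 1e-9], 0.8 * 11^(-0.5))
  expect_error(buildOscillatorBank("single", freq = 60), "Nyquist|outside")
})

test_that("c2 calibration has the analytic single-oscillator value and scaling", {
  one <- new("OscillatorBank", omegas = 7, amps = 0.4, c1 = 0, c2 = 1)
  # mean of a rectified sinusoid of amplitude A is A / pi
  expect_equal(calibrateC2(one, T = 100, dt = 5e-4), pi / 0.4, tolerance = 1e-3)
  two <- one; two@amps <- 0.8
  expect_equal(calibrateC2(two, T = 100, dt = 5e-4),
               calibrateC2(one, T = 100, dt = 5e-4) / 2, tolerance = 1e-9)
  empty <- buildOscillatorBank("none")
  expect_error(calibrateC2(empty), "non-modulated")
})

test_that("poisson spiking matches its rate at a stationary position", {
  pop <- gridPopulation(N = 1, spacing = 0.85, sigma = 0.12, seed = 2)
  pop@centers[[1]] <- matrix(c(0.75, 0.75), 1, 2)
  # stationary trajectory at the field center
  Tdur <- 200
  traj <- new("Trajectory", times = seq(0, Tdur, by = 0.01),
              xy = matrix(rep(c(0.75, 0.75), each = Tdur * 100 + 1),
                          ncol = 2), arena = 1.5)
  lam <- gridtorus:::.spatial_rate(pop, 1, traj@xy[1, , drop = FALSE])
  sp <- simulateGridModule(pop, traj, buildOscillatorBank("none"), seed = 3)
  expected <- lam * Tdur
  expect_lt(abs(spikeCounts(sp) - expected), 3.5 * sqrt(expected))
  # zero-rate population emits nothing
  pop0 <- pop; pop0@lambda0 <- 1e-12; pop0@G0 <- 1e-12
  sp0 <- simulateGridModule(pop0, traj, buildOscillatorBank("none"), seed = 4)
  expect_equal(sum(spikeCounts(sp0)), 0)
})

test_that("c2 calibration conserves mean spike counts under oscillations", {
  # paired over seeds, each with its own trajectory, so the finite-session
  # covariance between position and oscillation phase averages out; the bank
  # is calibrated over the session length used here
  on <- buildOscillatorBank("methods_default", calibrationT = 240)
  off <- buildOscillatorBank("none")
  nseeds <- 10
  counts_on <- counts_off <- numeric(nseeds)
  for (s in seq_len(nseeds)) {
    pop <- gridPopulation(N = 6, spacing = 0.85, sigma = 0.12, seed = 300 + s)
    traj <- synthTrajectory(240, seed = 600 + s)
    counts_on[s] <- sum(spikeCounts(simulateGridModule(pop, traj, on,
                                                       seed = 10 + s)))
    counts_off[s] <- sum(spikeCounts(simulateGridModule(pop, traj, off,
                                                        seed = 40 + s)))
  }
  expect_lt(abs(mean(counts_on) - mean(counts_off)) / mean(counts_off), 0.03)
  # and the paired differences are consistent with zero
  tt <- t.test(counts_on, counts_off, paired = TRUE)
  expect_gt(tt$p.value, 0.001)
})

test_that("field displacement moves every center by the stated magnitude", {
  pop <- gridPopulation(N = 4, spacing = 0.85, seed = 7)
  expect_identical(displaceFields(pop, 0), pop)
  d <- displaceFields(pop, 0.12, seed = 8)
  for (i in 1:4) {
    shifts <- sqrt(rowSums((d@centers[[i]] - pop@centers[[i]])^2))
    expect_equal(shifts, rep(0.12 * 0.85, length(shifts)), tolerance = 1e-12)
  }
})

test_that("synthetic trajectories meet the foraging contracts", {
  tr <- synthTrajectory(1800, seed = 9)
  expect_true(all(tr@xy >= 0 & tr@xy <= 1.5))
  sp <- trajectorySpeed(tr)
  expect_gt(mean(sp), 0.12)
  expect_lt(mean(sp), 0.18)
  expect_gt(mean(sp > 0.025), 0.9)     # mirrors the 2.5 cm/s speed filter
  expect_gt(trajectoryCoverage(tr), 0.95)
})
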