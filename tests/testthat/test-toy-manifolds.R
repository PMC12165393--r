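test_that("3D torus samples satisfy the parametrization exactly", {
  # direct substitutions
  mk <- function(u, v, a = 5, c = 10)
    c((c + a * cos(v)) * cos(u), (c + a * cos(v)) * sin(u), a * sin(v))
  expect_equal(mk(0, 0), c(15, 0, 0))
  expect_equal(mk(pi / 2, pi), c(0, 5, 0), tolerance = 1e-12)
  # every sampled point lies on the implicit surface
  for (au in c(FALSE, TRUE)) {
    x <- sampleTorus3D(500, 5, 10, seed = 4, areaUniform = au)
    resid <- (sqrt(x[, 1]^2 + x[, 2]^2) - 10)^2 + x[, 3]^2 - 25
    expect_lt(max(abs(resid)) / 25, 1e-9)
  }
  expect_error(sampleTorus3D(10, a = 10, c = 5))
})

test_that("6D torus samples satisfy the three circle identities", {
  x <- sampleTorus6D(500, seed = 5)
  expect_lt(max(abs(x[, 1]^2 + x[, 2]^2 - 1)), 1e-12)
  expect_lt(max(abs(x[, 3]^2 + x[, 4]^2 - 1)), 1e-12)
  expect_lt(max(abs(x[, 5]^2 + x[, 6]^2 - 1)), 1e-12)
  # (u, v) = (0, 0) maps to (1, 0, 1, 0, 1, 0): check via a 1-point "sample"
  # by direct evaluation of the map with default parameters
  p <- c(cos(0), sin(0), cos(0), sin(0), cos(0), sin(0))
  expect_equal(p, c(1, 0, 1, 0, 1, 0))
})

test_that("gaussian corruption has the stated moments and identity at zero", {
  x <- matrix(0, 2, 3)
  expect_identical(addGaussianNoise(x, 0), x)
  expect_error(addGaussianNoise(x, -1))
  y <- addGaussianNoise(matrix(0, 1e5, 1), delta = 0.7, seed = 6)
  expect_equal(sd(y), 0.7, tolerance = 0.02)
  expect_equal(mean(y), 0, tolerance = 0.02)
})

test_that("noise sweep bookkeeping is sound and reproducible", {
  # mechanical contract at small n; the scientific decay of Gamma with delta
  # is exercised at the full 1200-point scale in the acceptance suite
  ns <- noiseSweep(c(0, 1, 4), n = 250, realizations = 2, torus = "3d",
                   a = 5, c = 10, seed = 2)
  expect_equal(ns$delta, c(0, 1, 4))
  expect_true(all(ns$meanGamma1 >= 0 & ns$meanGamma1 <= 1))
  expect_true(all(ns$meanGamma2 >= 0 & ns$meanGamma2 <= 1))
  expect_true(all(is.finite(ns$sdGamma1[ns$delta > 0])))
  ns2 <- noiseSweep(c(0, 1, 4), n = 250, realizations = 2, torus = "3d",
                    a = 5, c = 10, seed = 2)
  expect_identical(ns, ns2)
})
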