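test_that("bar distance is the sup norm on intervals", {
  expect_equal(barDistance(c(0, 1), c(0, 1)), 0)
  expect_equal(barDistance(c(0, 1), c(0.2, 1.5)), 0.5)
  expect_equal(barDistance(c(1, 3), c(0.4, 2.1)), barDistance(c(0.4, 2.1), c(1, 3)))
  expect_gt(barDistance(c(0, 1), c(0, 1.001)), 0)
})

test_that("bottleneck distance matches hand-derivable cases", {
  expect_equal(bottleneckDistance(rbind(c(0, 1)), rbind(c(0, 1))), 0)
  # direct match costs 0.5, all-diagonal would cost 0.75
  expect_equal(bottleneckDistance(rbind(c(0, 1)), rbind(c(0, 1.5))), 0.5)
  # only option is the diagonal at (2 - 0) / 2
  expect_equal(bottleneckDistance(rbind(c(0, 2)), matrix(numeric(0), 0, 2)), 1)
  # identical multi-bar barcodes
  P <- rbind(c(0, 1), c(0.5, 2), c(1, 1.2))
  expect_equal(bottleneckDistance(P, P), 0)
  # strict-bijection mode refuses unequal cardinalities
  expect_error(bottleneckDistance(P, P[1:2, ], allowDiagonal = FALSE),
               "cardinality mismatch")
})

test_that("bottleneck agrees exactly with exhaustive matching enumeration", {
  set.seed(20)
  for (trial in 1:40) {
    n <- sample(0:5, 1); m <- sample(0:5, 1)
    P <- cbind(runif(n), 0) + cbind(0, runif(n, 0.01, 2))
    P <- cbind(P[, 1], P[, 1] + runif(n, 0.01, 2))
    Q <- cbind(runif(m), 0)
    Q <- cbind(Q[, 1], Q[, 1] + runif(m, 0.01, 2))
    if (n == 0) P <- matrix(numeric(0), 0, 2)
    if (m == 0) Q <- matrix(numeric(0), 0, 2)
    expect_equal(bottleneckDistance(P, Q), bottleneck_enum(P, Q),
                 tolerance = 1e-12)
    if (n == m && n > 0)
      expect_equal(bottleneckDistance(P, Q, allowDiagonal = FALSE),
                   bottleneck_enum(P, Q, allowDiagonal = FALSE),
                   tolerance = 1e-12)
  }
})

test_that("barcode scale factor follows the pairwise sup-norm definition", {
  expect_equal(scaleFactor(rbind(c(0, 1), c(0, 3))), 2)
  expect_equal(scaleFactor(rbind(c(0, 1))), 1)  # single bar: its persistence
  expect_equal(scaleFactor(rbind(c(0, 1), c(0.5, 2), c(3, 4))), 3)
  expect_error(scaleFactor(matrix(numeric(0), 0, 2)), "degenerate")
  expect_error(scaleFactor(rbind(c(1, 2), c(1, 2))), "zero scale")
})

test_that("normalized bottleneck is scale-invariant, symmetric and in [0,1]", {
  P <- rbind(c(0, 1), c(0, 3))
  Q <- rbind(c(0, 2), c(0, 6))  # Q = 2 * P, same normalized barcode
  expect_equal(as.numeric(normalizedBottleneck(P, Q)), 0)
  set.seed(3)
  for (trial in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    P <- cbind(runif(n), 0); P <- cbind(P[, 1], P[, 1] + runif(n, 0.05, 2))
    Q <- cbind(runif(m), 0); Q <- cbind(Q[, 1], Q[, 1] + runif(m, 0.05, 2))
    d1 <- as.numeric(normalizedBottleneck(P, Q))
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(d1, as.numeric(normalizedBottleneck(Q, P)))
    lam <- runif(1, 0.1, 10)
    expect_equal(d1, as.numeric(normalizedBottleneck(lam * P, Q)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(normalizedBottleneck(P, P)), 0)
  }
})

test_that("reference construction keeps top bars and floors the rest", {
  h1 <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.5), c(0.4, 0.45))
  h2 <- rbind(c(0.5, 0.7), c(0.55, 0.58))
  bs <- BarcodeSet(h1 = h1, h2 = h2)
  ref <- makeReference(bs, "data")
  # min length in H1 is 0.05; non-retained bars floored to it
  expect_equal(unname(bars(barcode(ref, 1))),
               rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.35), c(0.4, 0.45)))
  # H2: longest kept, other floored to min length 0.03
  expect_equal(unname(bars(barcode(ref, 2))),
               rbind(c(0.5, 0.7), c(0.55, 0.58)), tolerance = 1e-12)

  # self mode: second-longest H1 stretched to the longest's length
  bs2 <- BarcodeSet(h1 = rbind(c(0.1, 0.9), c(0.2, 0.4)), h2 = rbind(c(0.5, 0.7)))
  ref2 <- makeReference(bs2, "self")
  expect_equal(unname(bars(barcode(ref2, 1))), rbind(c(0.1, 0.9), c(0.2, 1.0)))

  expect_error(makeReference(BarcodeSet(h1 = rbind(c(0, 1)), h2 = h2)),
               "insufficient bars")
})

test_that("reference construction is idempotent in both modes", {
  set.seed(11)
  for (mode in c("data", "self")) {
    for (trial in 1:10) {
      n1 <- sample(3:8, 1); n2 <- sample(1:4, 1)
      h1 <- cbind(runif(n1), 0); h1 <- cbind(h1[, 1], h1[, 1] + runif(n1, 0.05, 1))
      h2 <- cbind(runif(n2), 0); h2 <- cbind(h2[, 1], h2[, 1] + runif(n2, 0.05, 1))
      bs <- BarcodeSet(h1 = h1, h2 = h2)
      r1 <- makeReference(bs, mode)
      r2 <- makeReference(r1, mode)
      expect_equal(bars(barcode(r1, 1)), bars(barcode(r2, 1)), tolerance = 1e-12)
      expect_equal(bars(barcode(r1, 2)), bars(barcode(r2, 2)), tolerance = 1e-12)
    }
  }
})

test_that("toroidality of a reference against itself is (1, 1)", {
  h1 <- rbind(c(0.1, 0.9), c(0.15, 0.85), c(0.3, 0.42), c(0.5, 0.61))
  h2 <- rbind(c(0.5, 0.8), c(0.52, 0.6))
  ref <- makeReference(BarcodeSet(h1 = h1, h2 = h2), "data")
  sc <- toroidality(ref, reference = ref)
  expect_equal(gamma1(sc), 1)
  expect_equal(gamma2(sc), 1)
  expect_true(sc@defined)
})

test_that("toroidality degrades monotonically (on average) with bar noise", {
  set.seed(5)
  h1 <- rbind(c(0.1, 0.9), c(0.12, 0.88), c(0.3, 0.4), c(0.32, 0.41), c(0.5, 0.55))
  h2 <- rbind(c(0.45, 0.8), c(0.5, 0.55))
  base <- BarcodeSet(h1 = h1, h2 = h2)
  ref <- makeReference(base, "data")
  noisy_gamma <- function(eps) {
    g <- replicate(12, {
      jit <- function(m) {
        mm <- m + matrix(runif(length(m), -eps, eps), nrow(m))
        cbind(pmax(mm[, 1], 0), pmax(mm[, 2], mm[, 1]))
      }
      sc <- toroidality(BarcodeSet(h1 = jit(h1), h2 = jit(h2)), reference = ref)
      c(gamma1(sc), gamma2(sc))
    })
    rowMeans(g)
  }
  g_small <- noisy_gamma(0.02)
  g_big <- noisy_gamma(0.3)
  expect_gt(g_small[1], g_big[1])
  expect_gt(g_small[2], g_big[2])
})

test_that("H1-death/H2-birth gap and relative difference follow their definitions", {
  bs <- BarcodeSet(h1 = rbind(c(0.2, 0.8), c(0.25, 0.5)),
                   h2 = rbind(c(0.5, 0.7)))
  expect_equal(h1h2Gap(bs), 0.8 - 0.5)
  bs2 <- BarcodeSet(h1 = rbind(c(0.2, 0.5)), h2 = rbind(c(0.5, 0.7)))
  expect_equal(h1h2Gap(bs2), 0)
  expect_error(h1h2Gap(BarcodeSet(h1 = rbind(c(0, 1)))), "empty")

  mk <- function(g1, g2) new("ToroidalityScore", gamma1 = g1, gamma2 = g2,
                             referenceMode = "data", defined = TRUE)
  expect_equal(unname(relativeDifference(mk(0.5, 0.5), mk(0.5, 0.5))), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(relativeDifference(mk(0.8, 0.8), mk(0.4, 0.4))),
               c(1 / 3, 1 / 3), ignore_attr = TRUE)
  expect_equal(unname(relativeDifference(mk(0.3, 0.9), mk(0, 0))), c(1, 1),
               ignore_attr = TRUE)
  rd <- relativeDifference(mk(0, 0), mk(0, 0))
  expect_false(attr(rd, "defined"))
})
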