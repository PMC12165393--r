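test_that("rips engine matches a brute-force reduction oracle on tiny clouds", {
  set.seed(77)
  for (trial in 1:8) {
    n <- sample(7:12, 1)
    x <- switch(sample(1:3, 1),
      matrix(rnorm(n * 3), n),
      matrix(runif(n * 2), n),
      { th <- runif(n, 0, 2 * pi); cbind(cos(th), sin(th)) + matrix(rnorm(n * 2, 0, 0.1), n) })
    D <- as.matrix(dist(x))
    thr <- unname(quantile(D[upper.tri(D)], runif(1, 0.7, 1)))
    oracle <- rips_oracle(D, thr, 2)
    for (app in c(TRUE, FALSE)) {
      got <- ripsPersistence(D, maxdim = 2, threshold = thr, isDistance = TRUE,
                             useApparent = app)
      for (d in 0:2) {
        expect_equal(barcode_to_canon(barcode(got, d), thr),
                     canon_bars(oracle[[d + 1]], thr), tolerance = 1e-12,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("apparent-pair shortcut does not change barcodes on larger clouds", {
  set.seed(8)
  x <- sampleTorus3D(150, 5, 10, seed = 8)
  a <- ripsPersistence(x, maxdim = 2, useApparent = TRUE)
  b <- ripsPersistence(x, maxdim = 2, useApparent = FALSE)
  thr <- attr(a, "threshold")
  for (d in 0:2)
    expect_equal(barcode_to_canon(barcode(a, d), thr),
                 barcode_to_canon(barcode(b, d), thr), tolerance = 1e-12,
                 ignore_attr = TRUE)
  # exact ties in the distance matrix (regular polygon) are handled too
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  y <- cbind(cos(th), sin(th))
  a2 <- ripsPersistence(y, maxdim = 2, useApparent = TRUE)
  b2 <- ripsPersistence(y, maxdim = 2, useApparent = FALSE)
  thr2 <- attr(a2, "threshold")
  for (d in 0:2)
    expect_equal(barcode_to_canon(barcode(a2, d), thr2),
                 barcode_to_canon(barcode(b2, d), thr2), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("a circle sample yields one dominant H1 bar at the known radii", {
  n <- 30
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  bs <- ripsPersistence(cbind(cos(th), sin(th)), maxdim = 2)
  h1 <- bars(barcode(bs, 1))
  expect_equal(nrow(h1), 1)
  # birth at the nearest-neighbour spacing, death at sqrt(3) (inscribed
  # equilateral triangle of the unit circle)
  expect_equal(unname(h1[1, 1]), 2 * sin(pi / n), tolerance = 1e-12)
  expect_equal(unname(h1[1, 2]), sqrt(3), tolerance = 1e-3)
  # H0: n-1 merge deaths at the spacing, one essential bar
  h0 <- barcode(bs, 0)
  expect_equal(nBars(h0), n)
  expect_equal(sum(h0@truncated), 1)
})

test_that("torus samples show two dominant H1 bars and one dominant H2 bar", {
  x <- sampleTorus3D(400, 5, 10, seed = 2)
  bs <- ripsPersistence(x, maxdim = 2)
  p1 <- sort(persistences(barcode(bs, 1)), decreasing = TRUE)
  p2 <- sort(persistences(barcode(bs, 2)), decreasing = TRUE)
  expect_gt(p1[2], 1.5 * p1[3])  # clear gap after the two loop classes
  expect_gt(p2[1], 2 * p2[2])    # single dominant cavity
})

test_that("degenerate inputs produce the expected barcodes", {
  # a single point: one essential H0 bar, empty H1/H2
  bs <- ripsPersistence(matrix(0, 1, 3), maxdim = 2, threshold = 1)
  expect_equal(nBars(barcode(bs, 0)), 1)
  expect_true(all(barcode(bs, 0)@truncated))
  expect_equal(nBars(barcode(bs, 1)), 0)
  expect_equal(nBars(barcode(bs, 2)), 0)
  # two clusters below the cap: two essential H0 bars
  x <- rbind(matrix(rnorm(20, sd = 0.01), 10, 2),
             matrix(rnorm(20, mean = 10, sd = 0.01), 10, 2))
  bs2 <- ripsPersistence(x, maxdim = 1, threshold = 1)
  expect_equal(sum(barcode(bs2, 0)@truncated), 2)
})

test_that("cosine metric and threshold capping behave as documented", {
  set.seed(9)
  x <- matrix(rnorm(60 * 3), 60)
  bs <- ripsPersistence(x, maxdim = 1, metric = "cosine")
  expect_s4_class(bs, "BarcodeSet")
  expect_lte(attr(bs, "threshold"), 2 + 1e-12)
  # capping the threshold truncates but never invents bars
  y <- sampleTorus3D(200, 5, 10, seed = 3)
  full <- ripsPersistence(y, maxdim = 1)
  capped <- ripsPersistence(y, maxdim = 1, threshold = 4)
  pf <- bars(barcode(full, 1))
  pc <- bars(barcode(capped, 1))
  finite_caps <- pc[!barcode(capped, 1)@truncated, , drop = FALSE]
  # every non-truncated capped bar appears identically in the full barcode
  for (i in seq_len(nrow(finite_caps)))
    expect_true(any(abs(pf[, 1] - finite_caps[i, 1]) < 1e-12 &
                    abs(pf[, 2] - finite_caps[i, 2]) < 1e-12))
})
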