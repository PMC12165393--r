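#' @import methods
NULL

#' Persistence barcode for one homology dimension
#'
#' A multiset of persistence intervals (bars) for a single homology
#' dimension. Each bar is a `(birth, death)` pair of filtration radii with
#' `death >= birth`. Bars that were truncated at the filtration cap (features
#' still alive at the maximal radius considered) carry a `truncated` flag.
#'
#' @slot dimension integer, homology dimension (0, 1 or 2).
#' @slot bars two-column numeric matrix (`birth`, `death`).
#' @slot truncated logical vector, one flag per bar.
#'
#' @export
setClass("Barcode",
  representation(dimension = "integer", bars = "matrix", truncated = "logical"),
  prototype(dimension = 0L, bars = matrix(numeric(0), 0, 2,
    dimnames = list(NULL, c("birth", "death"))), truncated = logical(0))
)

setValidity("Barcode", function(object) {
  b <- object@bars
  if (ncol(b) != 2) return("bars must have two columns (birth, death)")
  if (nrow(b) != length(object@truncated)) return("truncated flag length mismatch")
  if (length(object@dimension) != 1 || object@dimension < 0 || object@dimension > 2)
    return("dimension must be a single integer in 0..2")
  if (nrow(b) > 0) {
    if (any(!is.finite(b))) return("bars must be finite (truncate infinite deaths at ingest)")
    if (any(b[, 2] < b[, 1])) return("death must be >= birth")
    if (any(b[, 1] < 0)) return("births must be nonnegative")
  }
  TRUE
})

#' Construct a Barcode
#'
#' @param dimension homology dimension (0, 1 or 2).
#' @param bars two-column matrix of `(birth, death)` pairs, or a vector of
#'   length 2 for a single bar.
#' @param truncated logical vector flagging bars cut at the filtration cap;
#'   recycled to the number of bars.
#' @return A [Barcode-class] object.
#' @examples
#' Barcode(1, rbind(c(0.1, 0.9), c(0.2, 0.8)))
#' @export
Barcode <- function(dimension, bars = matrix(numeric(0), 0, 2), truncated = FALSE) {
  if (is.vector(bars) && length(bars) == 2) bars <- matrix(bars, 1, 2)
  bars <- as.matrix(bars)[, 1:2, drop = FALSE]
  storage.mode(bars) <- "double"
  colnames(bars) <- c("birth", "death")
  new("Barcode", dimension = as.integer(dimension), bars = bars,
      truncated = rep_len(as.logical(truncated), nrow(bars)))
}

#' @describeIn Barcode-class number of bars
#' @param x a `Barcode`
#' @export
nBars <- function(x) nrow(x@bars)

#' Extract the bar matrix of a Barcode
#' @param x a [Barcode-class]
#' @return two-column numeric matrix (`birth`, `death`).
#' @export
bars <- function(x) x@bars

#' Bar persistences (death - birth)
#' @param x a [Barcode-class]
#' @export
persistences <- function(x) x@bars[, 2] - x@bars[, 1]

setMethod("show", "Barcode", function(object) {
  cat(sprintf("Barcode (H%d): %d bars\n", object@dimension, nBars(object)))
  if (nBars(object) > 0) {
    p <- persistences(object)
    o <- order(p, decreasing = TRUE)
    k <- min(3, length(o))
    cat(sprintf("  longest: %s\n", paste(sprintf("[%.3g, %.3g)",
      object@bars[o[1:k], 1], object@bars[o[1:k], 2]), collapse = " ")))
    if (any(object@truncated)) cat(sprintf("  %d bar(s) truncated at filtration cap\n",
      sum(object@truncated)))
  }
})

#' Barcodes in dimensions 0, 1 and 2
#'
#' Container holding the `H0`, `H1` and `H2` persistence barcodes of one
#' point cloud, as produced by [ripsPersistence()].
#'
#' @slot h0,h1,h2 [Barcode-class] objects of dimensions 0, 1, 2.
#' @export
setClass("BarcodeSet",
  representation(h0 = "Barcode", h1 = "Barcode", h2 = "Barcode"))

setValidity("BarcodeSet", function(object) {
  if (object@h0@dimension != 0L) return("h0 must have dimension 0")
  if (object@h1@dimension != 1L) return("h1 must have dimension 1")
  if (object@h2@dimension != 2L) return("h2 must have dimension 2")
  TRUE
})

#' Construct a BarcodeSet
#' @param h0,h1,h2 [Barcode-class] objects (dimensions 0, 1, 2); a plain
#'   matrix is accepted and wrapped.
#' @return A [BarcodeSet-class].
#' @export
BarcodeSet <- function(h0 = Barcode(0), h1 = Barcode(1), h2 = Barcode(2)) {
  if (is.matrix(h0)) h0 <- Barcode(0, h0)
  if (is.matrix(h1)) h1 <- Barcode(1, h1)
  if (is.matrix(h2)) h2 <- Barcode(2, h2)
  new("BarcodeSet", h0 = h0, h1 = h1, h2 = h2)
}

#' Extract one dimension's barcode from a BarcodeSet
#' @param x a [BarcodeSet-class]
#' @param dimension 0, 1 or 2
#' @export
barcode <- function(x, dimension) {
  switch(as.character(dimension), "0" = x@h0, "1" = x@h1, "2" = x@h2,
         stop("dimension must be 0, 1 or 2"))
}

setMethod("show", "BarcodeSet", function(object) {
  cat("BarcodeSet\n")
  show(object@h0); show(object@h1); show(object@h2)
})

#' Degree of toroidality
#'
#' The pair (Gamma1, Gamma2): per dimension d in {1, 2},
#' `Gamma_d = 1 - normalized bottleneck distance` between a barcode and a
#' toroidal reference barcode. Values lie in `[0, 1]`; both close to 1
#' indicates toroidal topology.
#'
#' @slot gamma1,gamma2 numeric scores in `[0, 1]` (NA when undefined).
#' @slot referenceMode `"data"` or `"self"` (provenance of the reference).
#' @slot defined logical; FALSE when a degenerate barcode made the score
#'   undefined.
#' @export
setClass("ToroidalityScore",
  representation(gamma1 = "numeric", gamma2 = "numeric",
                 referenceMode = "character", defined = "logical"),
  prototype(gamma1 = NA_real_, gamma2 = NA_real_, referenceMode = "data",
            defined = TRUE))

setValidity("ToroidalityScore", function(object) {
  if (!object@referenceMode %in% c("data", "self", "external"))
    return("referenceMode must be 'data', 'self' or 'external'")
  ok <- function(g) is.na(g) || (g >= 0 && g <= 1)
  if (!ok(object@gamma1) || !ok(object@gamma2))
    return("gamma components must lie in [0, 1] (or NA)")
  TRUE
})

#' @rdname ToroidalityScore-class
#' @param x a `ToroidalityScore`
#' @export
gamma1 <- function(x) x@gamma1

#' @rdname ToroidalityScore-class
#' @export
gamma2 <- function(x) x@gamma2

setMethod("show", "ToroidalityScore", function(object) {
  cat(sprintf("ToroidalityScore (reference: %s)\n  Gamma1 = %.4f, Gamma2 = %.4f%s\n",
      object@referenceMode, object@gamma1, object@gamma2,
      if (!object@defined) "  [undefined]" else ""))
})

#' Bank of rate-modulating oscillators
#'
#' Temporal modulation of the simulator's firing rates: the factor
#' `c1 + c2 * sum_mu A(omega_mu) cos(2 pi omega_mu t)` (rectified together
#' with the spatial rate). An empty bank with `c1 = 1, c2 = 0` means no
#' oscillatory modulation.
#'
#' @slot omegas oscillator frequencies (Hz), ascending.
#' @slot amps nonnegative amplitudes `A(omega_mu)` (dimensionless).
#' @slot c1,c2 modulation constants.
#' @export
setClass("OscillatorBank",
  representation(omegas = "numeric", amps = "numeric", c1 = "numeric", c2 = "numeric"),
  prototype(omegas = numeric(0), amps = numeric(0), c1 = 1, c2 = 0))

setValidity("OscillatorBank", function(object) {
  if (length(object@omegas) != length(object@amps))
    return("omegas and amps must have equal length")
  if (length(object@omegas) && any(object@omegas <= 0))
    return("frequencies must be positive")
  if (is.unsorted(object@omegas)) return("frequencies must be ascending")
  if (length(object@amps) && any(object@amps < 0))
    return("amplitudes must be nonnegative")
  TRUE
})

setMethod("show", "OscillatorBank", function(object) {
  m <- length(object@omegas)
  cat(sprintf("OscillatorBank: %d oscillator(s), c1 = %.4g, c2 = %.4g\n",
      m, object@c1, object@c2))
  if (m > 0) {
    dom <- order(object@amps * sqrt(object@omegas), decreasing = TRUE)[1:min(2, m)]
    cat(sprintf("  range [%.3g, %.3g] Hz; dominant line(s) at %s Hz\n",
        min(object@omegas), max(object@omegas),
        paste(signif(object@omegas[dom], 3), collapse = ", ")))
  }
})

#' 2D foraging trajectory
#'
#' Position samples of an animal (or the synthetic random forager) in a
#' square arena, at a uniform time step.
#'
#' @slot times sample times (s), uniform step.
#' @slot xy two-column matrix of positions (m) within `[0, arena]^2`.
#' @slot arena side length of the square arena (m).
#' @export
setClass("Trajectory",
  representation(times = "numeric", xy = "matrix", arena = "numeric"))

setValidity("Trajectory", function(object) {
  if (nrow(object@xy) != length(object@times)) return("times/positions length mismatch")
  if (ncol(object@xy) != 2) return("positions must be 2D")
  if (length(object@times) >= 2) {
    dts <- diff(object@times)
    if (max(dts) - min(dts) > 1e-6 * mean(dts)) return("time step must be uniform")
  }
  if (any(object@xy < -1e-9) || any(object@xy > object@arena + 1e-9))
    return("positions must lie within the arena")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  dt <- if (length(object@times) >= 2) diff(object@times[1:2]) else NA
  cat(sprintf("Trajectory: %d samples, dt = %.4g s, span %.1f s, arena %.2g m\n",
      length(object@times), dt, diff(range(object@times)), object@arena))
})

#' Spike trains of a neural population
#'
#' Per-neuron sorted spike times (seconds) over a common recording span.
#'
#' @slot spikes list of numeric vectors, one sorted vector of spike times per
#'   neuron.
#' @slot span numeric length-2, recording span (s).
#' @export
setClass("SpikeTrains",
  representation(spikes = "list", span = "numeric"))

setValidity("SpikeTrains", function(object) {
  if (length(object@span) != 2 || object@span[2] < object@span[1])
    return("span must be an increasing length-2 numeric")
  for (s in object@spikes) {
    if (length(s) && (is.unsorted(s) ||
        s[1] < object@span[1] - 1e-9 || s[length(s)] > object@span[2] + 1e-9))
      return("spike times must be sorted and lie within the span")
  }
  TRUE
})

#' Construct a SpikeTrains object
#' @param spikes list of per-neuron spike-time vectors (s); sorted on input.
#' @param span recording span `c(t0, t1)` (s); defaults to `[0, max spike]`.
#' @return A [SpikeTrains-class].
#' @export
SpikeTrains <- function(spikes, span = NULL) {
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  if (is.null(span)) {
    hi <- suppressWarnings(max(0, unlist(spikes)))
    span <- c(0, hi)
  }
  new("SpikeTrains", spikes = spikes, span = as.numeric(span))
}

#' @rdname SpikeTrains
#' @param x a `SpikeTrains`
#' @export
nNeurons <- function(x) length(x@spikes)

#' @rdname SpikeTrains
#' @export
spikeCounts <- function(x) vapply(x@spikes, length, 0L)

setMethod("show", "SpikeTrains", function(object) {
  cat(sprintf("SpikeTrains: %d neurons, %d spikes, span [%.1f, %.1f] s\n",
      nNeurons(object), sum(spikeCounts(object)), object@span[1], object@span[2]))
})

#' Population of Poisson-spiking grid cells
#'
#' Field geometry of a simulated grid-cell module: per-neuron spatial field
#' centers on a randomly shifted hexagonal (or square) lattice, plus the
#' shared field-shape parameters of the truncated-Gaussian rate profile.
#'
#' @slot centers list of two-column matrices (m), the field centers of each
#'   neuron within the arena plus a margin.
#' @slot lambda0 baseline rate (Hz).
#' @slot G0 field gain (Hz m^2).
#' @slot sigma field width (m).
#' @slot x0 truncation radius of the field profile (m).
#' @slot spacing lattice spacing (m).
#' @slot latticeKind `"hexagonal"` or `"square"`.
#' @slot arena arena side (m).
#' @export
setClass("GridPopulation",
  representation(centers = "list", lambda0 = "numeric", G0 = "numeric",
                 sigma = "numeric", x0 = "numeric", spacing = "numeric",
                 latticeKind = "character", arena = "numeric"))

setValidity("GridPopulation", function(object) {
  if (!object@latticeKind %in% c("hexagonal", "square"))
    return("latticeKind must be 'hexagonal' or 'square'")
  if (any(c(object@lambda0, object@G0, object@sigma, object@x0,
            object@spacing, object@arena) <= 0))
    return("all rate/geometry parameters must be positive")
  if (object@x0 <= object@sigma) return("x0 must exceed sigma")
  for (m in object@centers) if (!is.matrix(m) || ncol(m) != 2)
    return("centers must be two-column matrices")
  TRUE
})

setMethod("show", "GridPopulation", function(object) {
  cat(sprintf(paste0("GridPopulation: %d neurons, %s lattice, spacing %.2f m\n",
      "  fields: sigma = %.3g m, x0 = %.3g m, G0 = %.3g, lambda0 = %.3g Hz\n"),
      length(object@centers), object@latticeKind, object@spacing,
      object@sigma, object@x0, object@G0, object@lambda0))
})

#' Smoothed, binned population activity
#'
#' Matrix of smoothed population activity: rows are retained time samples,
#' columns are neurons; produced by [smoothAndBin()].
#'
#' @slot mat nonnegative numeric matrix (time x neurons).
#' @slot times sample times (s) of the retained rows.
#' @export
setClass("PopulationMatrix",
  representation(mat = "matrix", times = "numeric"))

setValidity("PopulationMatrix", function(object) {
  if (nrow(object@mat) != length(object@times)) return("row/time mismatch")
  if (nrow(object@mat) && min(object@mat) < 0) return("activity must be nonnegative")
  TRUE
})

setMethod("show", "PopulationMatrix", function(object) {
  cat(sprintf("PopulationMatrix: %d time samples x %d neurons\n",
      nrow(object@mat), ncol(object@mat)))
})

#' Sigmoid fit of toroidality against a perturbation magnitude
#'
#' Least-squares fit of `s(x) = L / (1 + exp(-k (x - xc))) + b`. The
#' inflection point `xc` is the critical scale of the fitted decay and
#' `L k / 4` is the slope there.
#'
#' @slot L,k,xc,b fitted parameters.
#' @slot slopeAtInflection `L k / 4`.
#' @slot residuals fit residuals.
#' @slot lowConfidence TRUE when fewer than 5 points or plateaus not spanned.
#' @export
setClass("SigmoidFit",
  representation(L = "numeric", k = "numeric", xc = "numeric", b = "numeric",
                 slopeAtInflection = "numeric", residuals = "numeric",
                 lowConfidence = "logical"))

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit: L = %.4g, k = %.4g, xc = %.4g, b = %.4g (slope at xc = %.4g)%s\n",
      object@L, object@k, object@xc, object@b, object@slopeAtInflection,
      if (object@lowConfidence) "  [low confidence]" else ""))
})
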