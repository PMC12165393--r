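#' Sup-norm distance between two bars
#'
#' The distance between bars `p` and `q` is the larger of the differences
#' between their starting points and between their end points,
#' `max(|birth_p - birth_q|, |death_p - death_q|)` -- the standard sup-norm
#' on persistence intervals.
#'
#' @param p,q bars: numeric length-2 `(birth, death)`.
#' @return nonnegative scalar; zero iff the bars are identical.
#' @examples
#' barDistance(c(0, 1), c(0.2, 1.5))  # 0.5
#' @export
barDistance <- function(p, q) {
  stopifnot(length(p) == 2, length(q) == 2, p[2] >= p[1], q[2] >= q[1])
  max(abs(p[1] - q[1]), abs(p[2] - q[2]))
}

.as_bar_matrix <- function(P) {
  if (is(P, "Barcode")) return(P@bars)
  if (is.vector(P) && length(P) == 2) return(matrix(P, 1, 2))
  as.matrix(P)
}

#' Bottleneck distance between two barcodes
#'
#' The minimum over matchings of the maximal matched-pair sup-norm cost.
#' With `allowDiagonal = TRUE` (the standard bottleneck distance) unmatched
#' bars may be paired with the diagonal at cost `(death - birth) / 2`;
#' with `allowDiagonal = FALSE` only bijections between equal-cardinality
#' barcodes are considered.
#'
#' The implementation binary-searches the candidate radii (all pairwise and
#' diagonal costs) with a Hopcroft-Karp feasibility matching, so the result
#' is exact.
#'
#' @param P,Q [Barcode-class] objects or bar matrices of the same dimension.
#' @param allowDiagonal allow matching bars to the diagonal (default TRUE).
#' @return nonnegative scalar distance.
#' @examples
#' bottleneckDistance(rbind(c(0, 1)), rbind(c(0, 1.5)))  # 0.5
#' bottleneckDistance(rbind(c(0, 2)), matrix(0, 0, 2))   # 1  (diagonal)
#' @export
bottleneckDistance <- function(P, Q, allowDiagonal = TRUE) {
  if (is(P, "Barcode") && is(Q, "Barcode") && P@dimension != Q@dimension)
    stop("barcodes must share the homology dimension")
  pm <- .as_bar_matrix(P)
  qm <- .as_bar_matrix(Q)
  if (!allowDiagonal && nrow(pm) != nrow(qm)) stop("cardinality mismatch")
  .bottleneck_cpp(pm, qm, allowDiagonal)
}

#' Internal scale of a barcode
#'
#' `u(P)`: the maximum over pairs of bars in `P` of their sup-norm distance
#' ([barDistance()]) -- the largest difference in starting or end points
#' within the barcode. Dividing all births and deaths by `u(P)` rescales the
#' barcode so that its maximal internal distance is one. For a single-bar
#' barcode the bar's persistence is returned.
#'
#' @param P a [Barcode-class] or bar matrix.
#' @return positive scalar.
#' @examples
#' scaleFactor(rbind(c(0, 1), c(0, 3)))  # 2
#' @export
scaleFactor <- function(P) {
  pm <- .as_bar_matrix(P)
  n <- nrow(pm)
  if (n == 0) stop("degenerate barcode")
  if (n == 1) {
    u <- pm[1, 2] - pm[1, 1]
    if (u <= 0) stop("zero scale")
    return(u)
  }
  u <- max(abs(outer(pm[, 1], pm[, 1], "-")), abs(outer(pm[, 2], pm[, 2], "-")))
  if (u <= 0) stop("zero scale")
  u
}

#' Normalized bottleneck distance
#'
#' Bottleneck distance after rescaling each barcode by its own internal
#' scale ([scaleFactor()]): `dhat_B(P, Q) = d_B(P / u(P), Q / u(Q))`, where
#' division rescales every birth and death. The result is invariant to
#' multiplying either barcode by a positive constant and is clipped to
#' `[0, 1]` (clipping can only trigger through diagonal costs of bars far
#' from the barcode's own scale; an attribute records it).
#'
#' @inheritParams bottleneckDistance
#' @param pruneEps optional pruning tolerance: bars with persistence
#'   `<= 2 * pruneEps` (on the normalized scale) are dropped from both
#'   barcodes before matching, perturbing the distance by at most
#'   `pruneEps`. Default 0 (exact).
#' @return scalar in `[0, 1]`.
#' @export
normalizedBottleneck <- function(P, Q, allowDiagonal = TRUE, pruneEps = 0) {
  pm <- .as_bar_matrix(P)
  qm <- .as_bar_matrix(Q)
  pm <- pm / scaleFactor(pm)
  qm <- qm / scaleFactor(qm)
  if (pruneEps > 0) {
    pm <- pm[pm[, 2] - pm[, 1] > 2 * pruneEps, , drop = FALSE]
    qm <- qm[qm[, 2] - qm[, 1] > 2 * pruneEps, , drop = FALSE]
  }
  d <- .bottleneck_cpp(pm, qm, allowDiagonal)
  clipped <- d > 1
  d <- min(d, 1)
  attr(d, "clipped") <- clipped
  d
}

# order bars by decreasing persistence, ties by earlier birth then input order
.bar_order <- function(bm) order(-(bm[, 2] - bm[, 1]), bm[, 1], seq_len(nrow(bm)))

.reference_barcode <- function(bc, keep, mode) {
  bm <- bc@bars
  n <- nrow(bm)
  if (n < keep) stop("insufficient bars for reference")
  o <- .bar_order(bm)
  lens <- bm[, 2] - bm[, 1]
  minlen <- min(lens)
  out <- bm
  retained <- o[seq_len(keep)]
  others <- setdiff(seq_len(n), retained)
  out[others, 2] <- out[others, 1] + minlen
  if (mode == "self" && keep == 2) {
    # second-longest bar stretched to the longest bar's length (birth kept)
    out[o[2], 2] <- out[o[2], 1] + lens[o[1]]
  }
  Barcode(bc@dimension, out, bc@truncated)
}

#' Idealized toroidal reference barcode
#'
#' Builds the reference barcode set of an idealized torus from any barcode
#' set. In `"data"` mode the two longest bars in `H1` and the single longest
#' bar in `H2` are retained verbatim; every other bar keeps its birth and its
#' length is set to the minimum bar length in its dimension. In `"self"` mode
#' the longest `H1` bar is kept, the second-longest `H1` bar's length is set
#' equal to the longest's (same birth), the longest `H2` bar is kept, and all
#' other bars are set to the minimum length as before. Ties in "longest" are
#' broken by earlier birth, then input order. `H0` is passed through
#' unchanged (it plays no role in the toroidality measure).
#'
#' The construction is idempotent in both modes.
#'
#' @param bset a [BarcodeSet-class] with at least two `H1` bars and one `H2`
#'   bar.
#' @param mode `"data"` or `"self"`.
#' @return A [BarcodeSet-class] reference.
#' @export
makeReference <- function(bset, mode = c("data", "self")) {
  mode <- match.arg(mode)
  if (nBars(bset@h1) < 2 || nBars(bset@h2) < 1)
    stop("insufficient bars for reference")
  h1 <- .reference_barcode(bset@h1, 2L, mode)
  h2 <- .reference_barcode(bset@h2, 1L, "data")
  BarcodeSet(h0 = bset@h0, h1 = h1, h2 = h2)
}

#' Degree of toroidality of a barcode set
#'
#' `Gamma_d = 1 - dhat_B(tau_d, tau_d_ref)` for d in {1, 2}, where `dhat_B`
#' is the normalized bottleneck distance ([normalizedBottleneck()]) and
#' `tau_d_ref` is the barcode of an idealized torus. When no reference is
#' supplied it is constructed from `bset` itself via [makeReference()] in the
#' requested mode. Both components lie in `[0, 1]`; values jointly above
#' about 0.6 indicate barcodes consistent with toroidal topology.
#'
#' @param bset a [BarcodeSet-class].
#' @param reference optional [BarcodeSet-class] used as the torus reference
#'   (e.g. the reference built from unperturbed data).
#' @param referenceMode `"data"` or `"self"`; used when `reference` is NULL,
#'   and recorded in the score.
#' @param pruneEps pruning tolerance passed to [normalizedBottleneck()].
#' @return A [ToroidalityScore-class].
#' @examples
#' bs <- BarcodeSet(h1 = rbind(c(0.1, 0.9), c(0.15, 0.85), c(0.3, 0.4)),
#'                  h2 = rbind(c(0.5, 0.8), c(0.55, 0.6)))
#' toroidality(makeReference(bs, "data"), reference = makeReference(bs, "data"))
#' @export
toroidality <- function(bset, reference = NULL, referenceMode = c("data", "self"),
                        pruneEps = 0) {
  referenceMode <- match.arg(referenceMode)
  mode <- if (is.null(reference)) referenceMode else "external"
  if (is.null(reference)) reference <- makeReference(bset, referenceMode)
  g <- rep(NA_real_, 2)
  defined <- TRUE
  for (d in 1:2) {
    P <- barcode(bset, d)
    Q <- barcode(reference, d)
    if (nBars(P) == 0 || nBars(Q) == 0) {
      defined <- FALSE
      next
    }
    dd <- tryCatch(normalizedBottleneck(P, Q, pruneEps = pruneEps),
                   error = function(e) NA_real_)
    if (is.na(dd)) defined <- FALSE else g[d] <- max(0, 1 - as.numeric(dd))
  }
  new("ToroidalityScore", gamma1 = g[1], gamma2 = g[2],
      referenceMode = mode, defined = defined)
}

#' Gap between the longest H1 death and the longest H2 birth
#'
#' The difference between the death radius of the longest (most persistent)
#' bar in `H1` and the birth radius of the longest bar in `H2`. In barcodes
#' with toroidal structure the long `H2` cavity coexists with the two long
#' `H1` loops, giving a large positive gap; when the `H2` bar only appears
#' after the `H1` loops have died the gap is near zero or negative.
#'
#' @param bset a [BarcodeSet-class] with nonempty `H1` and `H2`.
#' @return scalar gap (same units as the filtration radii).
#' @export
h1h2Gap <- function(bset) {
  if (nBars(bset@h1) == 0 || nBars(bset@h2) == 0)
    stop("empty barcode: gap undefined")
  o1 <- .bar_order(bset@h1@bars)[1]
  o2 <- .bar_order(bset@h2@bars)[1]
  unname(bset@h1@bars[o1, 2] - bset@h2@bars[o2, 1])
}

#' Componentwise relative difference of two toroidality scores
#'
#' `(a - b) / (a + b)` per component, each in `[-1, 1]`; used to compare the
#' toroidality of two analyses of the same data (e.g. all cells vs a cell
#' subset). A zero denominator yields NA with `defined = FALSE` attribute.
#'
#' @param a,b [ToroidalityScore-class] objects.
#' @return numeric length-2 `(deltaGamma1, deltaGamma2)` with attribute
#'   `defined`.
#' @export
relativeDifference <- function(a, b) {
  num <- c(a@gamma1 - b@gamma1, a@gamma2 - b@gamma2)
  den <- c(a@gamma1 + b@gamma1, a@gamma2 + b@gamma2)
  out <- ifelse(den == 0, NA_real_, num / den)
  names(out) <- c("deltaGamma1", "deltaGamma2")
  attr(out, "defined") <- !anyNA(out)
  out
}
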