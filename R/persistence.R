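#' Vietoris-Rips persistence barcodes of a point cloud
#'
#' Computes persistence barcodes in dimensions 0..`maxdim` (`maxdim` up to 2)
#' of the Vietoris-Rips filtration of a point cloud, using the package's
#' persistent-cohomology engine (coboundary reduction with clearing,
#' emergent-pair shortcut and apparent-pair skipping).
#'
#' The filtration is computed up to `threshold`; by default the enclosing
#' radius `min_i max_j d(i, j)` is used, beyond which the complex is a cone
#' and no feature in dimensions >= 1 survives, so all finite bars are exact.
#' Features still alive at the cap are truncated there and flagged. Bars of
#' zero persistence are dropped.
#'
#' @param x numeric matrix (points in rows), a `dist` object, or a square
#'   distance matrix (`isDistance = TRUE`).
#' @param maxdim maximal homology dimension (0, 1 or 2).
#' @param threshold filtration cap; `NULL` for the enclosing radius.
#' @param metric `"euclidean"` or `"cosine"` (ignored for distance input).
#' @param isDistance treat `x` as a precomputed square distance matrix.
#' @param useApparent use the apparent-pair shortcut (identical output,
#'   faster; `FALSE` retains the plain reduction for cross-checking).
#' @return A [BarcodeSet-class]; for `maxdim < 2` the higher barcodes are
#'   empty.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 41)[-41]
#' bs <- ripsPersistence(cbind(cos(theta), sin(theta)), maxdim = 1)
#' bars(barcode(bs, 1))  # one dominant loop
#' @export
ripsPersistence <- function(x, maxdim = 2, threshold = NULL,
                            metric = c("euclidean", "cosine"),
                            isDistance = FALSE, useApparent = TRUE) {
  metric <- match.arg(metric)
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else if (isDistance) {
    D <- as.matrix(x)
    if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  } else {
    x <- as.matrix(x)
    if (!all(is.finite(x))) stop("point cloud must be finite")
    D <- switch(metric,
      euclidean = as.matrix(stats::dist(x)),
      cosine = {
        nrm <- sqrt(rowSums(x^2))
        if (any(nrm == 0)) stop("cosine metric undefined for zero vectors")
        s <- tcrossprod(x / nrm)
        d <- 1 - pmin(pmax(s, -1), 1)
        d[d < 0] <- 0
        diag(d) <- 0
        d
      })
  }
  if (is.null(threshold)) threshold <- min(apply(D, 1, max))
  res <- .rips_cpp(D, as.numeric(threshold), as.integer(maxdim), isTRUE(useApparent))
  mk <- function(d) {
    if (d + 1 > length(res)) return(Barcode(d))
    m <- res[[d + 1]]
    keep <- m[, 2] > m[, 1] | m[, 3] == 1
    Barcode(d, m[keep, 1:2, drop = FALSE], m[keep, 3] == 1)
  }
  out <- BarcodeSet(h0 = mk(0), h1 = mk(1), h2 = mk(2))
  attr(out, "threshold") <- threshold
  out
}
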