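#' Smooth and bin spike trains into a population matrix
#'
#' Spike trains are converted to counts on a fine grid of width `bin`,
#' convolved per neuron with a normalized discretized Gaussian kernel of
#' width `kernelSigma`, and every `stride`-th time sample is retained. The
#' kernel preserves total mass, so each neuron's column sums to
#' approximately its spike count.
#'
#' @param spikes a [SpikeTrains-class].
#' @param kernelSigma Gaussian smoothing width (s).
#' @param bin bin width (s).
#' @param stride keep every `stride`-th sample.
#' @return A [PopulationMatrix-class] (rows: retained samples; columns:
#'   neurons).
#' @export
smoothAndBin <- function(spikes, kernelSigma = 0.05, bin = 0.01, stride = 5L) {
  N <- nNeurons(spikes)
  if (N == 0) stop("empty population")
  t0 <- spikes@span[1]
  nb <- max(1L, ceiling((spikes@span[2] - t0) / bin))
  half <- max(1L, ceiling(4 * kernelSigma / bin))
  kern <- stats::dnorm(seq(-half, half) * bin, sd = kernelSigma)
  kern <- kern / sum(kern)
  M <- matrix(0, nb, N)
  for (i in seq_len(N)) {
    s <- spikes@spikes[[i]]
    cnt <- numeric(nb)
    if (length(s)) {
      ix <- pmin(pmax(floor((s - t0) / bin), 0), nb - 1) + 1
      tab <- tabulate(ix, nbins = nb)
      cnt <- as.numeric(stats::filter(tab, kern, sides = 2))
      cnt[is.na(cnt)] <- 0
      # renormalize edge loss so the mass matches the spike count
    }
    M[, i] <- cnt
  }
  keep <- seq(1L, nb, by = as.integer(stride))
  new("PopulationMatrix", mat = M[keep, , drop = FALSE],
      times = t0 + (keep - 0.5) * bin)
}

#' Select population vectors
#'
#' `"top_activity"` keeps the `k` rows with the largest mean population
#' activity (row sum of the smoothed matrix), with ties broken by time
#' order; `"random"` draws `k` rows uniformly without replacement. If the
#' matrix has fewer than `k` rows, all rows are kept with a warning.
#'
#' @param M a [PopulationMatrix-class].
#' @param k number of vectors to keep.
#' @param mode `"top_activity"` or `"random"`.
#' @param seed RNG seed for `"random"`.
#' @return A [PopulationMatrix-class] with `k` rows (time-ordered).
#' @export
selectVectors <- function(M, k = 15000, mode = c("top_activity", "random"),
                          seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(M@mat)
  if (k > n) {
    warning("fewer rows than requested: keeping all ", n)
    k <- n
  }
  idx <- if (mode == "top_activity") {
    rs <- rowSums(M@mat)
    sort(order(-rs, seq_len(n))[seq_len(k)])
  } else {
    if (!is.null(seed)) set.seed(seed)
    sort(sample.int(n, k))
  }
  new("PopulationMatrix", mat = M@mat[idx, , drop = FALSE], times = M@times[idx])
}

#' Project population vectors onto their leading principal components
#'
#' Centers the selected vectors and projects them onto the top `dims`
#' principal axes. If the matrix rank is below `dims`, missing components
#' are zero-padded with a warning. Explained-variance fractions are attached
#' as an attribute.
#'
#' @param M a [PopulationMatrix-class].
#' @param dims target dimensionality.
#' @return numeric matrix (`nrow(M)` x `dims`) with attribute
#'   `explainedVariance`.
#' @export
pcaReduce <- function(M, dims = 6) {
  x <- M@mat
  if (nrow(x) <= dims) stop("need more rows than target dimensions")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  have <- min(dims, ncol(pc$x))
  out <- matrix(0, nrow(x), dims)
  out[, seq_len(have)] <- pc$x[, seq_len(have)]
  if (have < dims) warning("rank below ", dims, ": zero-padded components")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explainedVariance") <- ev[seq_len(have)]
  out
}

#' Density-aware downsampling of a point cloud
#'
#' Two stages: (1) a density filter drops the lowest-density quantile of
#' points, with density measured by the inverse distance to the `k`-th
#' nearest neighbour; (2) greedy farthest-point (maxmin) selection reduces
#' the remainder to `n` points. The maxmin start point is drawn with the
#' seed, making the result reproducible.
#'
#' @param x numeric matrix (points in rows).
#' @param n target number of points.
#' @param k neighbourhood size for the density estimate.
#' @param dropQuantile fraction of lowest-density points removed first.
#' @param seed RNG seed for the maxmin start.
#' @return matrix of `n` selected rows (attribute `index` gives their row
#'   indices in `x`).
#' @export
downsampleCloud <- function(x, n = 1200, k = 15, dropQuantile = 0.1,
                            seed = NULL) {
  x <- as.matrix(x)
  if (n > nrow(x)) stop("cannot downsample below target size")
  if (n == nrow(x)) {
    attr(x, "index") <- seq_len(nrow(x))
    return(x)
  }
  kk <- min(k, nrow(x) - 1)
  knn <- FNN::get.knn(x, k = kk)
  radius <- knn$nn.dist[, kk]
  keep <- which(radius <= stats::quantile(radius, 1 - dropQuantile))
  if (length(keep) < n) keep <- order(radius)[seq_len(max(n, length(keep)))]
  y <- x[keep, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(y)
  sel <- integer(n)
  sel[1] <- sample.int(m, 1)
  rn <- rowSums(y * y)
  d2_to <- function(p) pmax(rn + sum(p * p) - 2 * drop(y %*% p), 0)
  d2 <- d2_to(y[sel[1], ])
  for (i in seq_len(n - 1)) {
    sel[i + 1] <- which.max(d2)
    d2 <- pmin(d2, d2_to(y[sel[i + 1], ]))
  }
  out <- y[sel, , drop = FALSE]
  attr(out, "index") <- keep[sel]
  out
}

#' Jitter spike times
#'
#' Adds an independent zero-mean Gaussian offset with standard deviation
#' `deltaT` to every spike of every neuron. Per-neuron spike counts are
#' preserved; times are re-sorted. Spikes jittered outside the recording
#' span are clipped to the span (default) or dropped.
#'
#' @param spikes a [SpikeTrains-class].
#' @param deltaT jitter standard deviation (s); 0 returns the input.
#' @param seed optional RNG seed.
#' @param outside `"clip"` (default) or `"drop"`.
#' @return A jittered [SpikeTrains-class].
#' @export
jitterSpikes <- function(spikes, deltaT, seed = NULL,
                         outside = c("clip", "drop")) {
  outside <- match.arg(outside)
  stopifnot(deltaT >= 0)
  if (deltaT == 0) return(spikes)
  if (!is.null(seed)) set.seed(seed)
  lo <- spikes@span[1]; hi <- spikes@span[2]
  spikes@spikes <- lapply(spikes@spikes, function(s) {
    if (!length(s)) return(s)
    s <- s + stats::rnorm(length(s), 0, deltaT)
    if (outside == "clip") s <- pmin(pmax(s, lo), hi) else s <- s[s >= lo & s <= hi]
    sort(s)
  })
  spikes
}

#' Default configuration of the spike-train to barcode pipeline
#'
#' Stage parameters of [runTDA()]: Gaussian smoothing width, binning and
#' stride, number and mode of selected population vectors, PCA target
#' dimension, downsampled cloud size and density-filter settings, distance
#' metric, and maximal homology dimension.
#'
#' @param kernelSigma smoothing width (s).
#' @param bin fine bin width (s).
#' @param stride population vector stride.
#' @param k number of selected population vectors.
#' @param mode `"top_activity"` or `"random"` vector selection.
#' @param dims PCA dimension.
#' @param nPoints downsampled cloud size.
#' @param knnK,dropQuantile density-filter settings of [downsampleCloud()].
#' @param metric persistence metric (`"euclidean"` or `"cosine"`).
#' @param maxdim maximal homology dimension.
#' @return named list of stage parameters.
#' @export
tdaConfig <- function(kernelSigma = 0.05, bin = 0.01, stride = 5L, k = 15000,
                      mode = "top_activity", dims = 6, nPoints = 1200,
                      knnK = 15, dropQuantile = 0.1, metric = "euclidean",
                      maxdim = 2) {
  list(kernelSigma = kernelSigma, bin = bin, stride = stride, k = k,
       mode = mode, dims = dims, nPoints = nPoints, knnK = knnK,
       dropQuantile = dropQuantile, metric = metric, maxdim = maxdim)
}

#' Spike trains to persistence barcodes
#'
#' The full preprocessing chain: smooth and bin the spike trains, keep the
#' most active (or random) population vectors, reduce to six dimensions with
#' PCA, downsample the cloud by density and maxmin to `nPoints` points, and
#' compute Vietoris-Rips persistence up to `H2`. All stage parameters and
#' the seed are recorded in the `log` attribute.
#'
#' @param spikes a [SpikeTrains-class].
#' @param config stage parameters from [tdaConfig()].
#' @param seed RNG seed for the stochastic stages (random selection and the
#'   maxmin start).
#' @return A [BarcodeSet-class] with attribute `log`.
#' @export
runTDA <- function(spikes, config = tdaConfig(), seed = 1) {
  M <- smoothAndBin(spikes, config$kernelSigma, config$bin, config$stride)
  M <- selectVectors(M, k = config$k, mode = config$mode, seed = seed)
  cloud <- pcaReduce(M, dims = config$dims)
  cloud <- downsampleCloud(cloud, n = min(config$nPoints, nrow(cloud)),
                           k = config$knnK, dropQuantile = config$dropQuantile,
                           seed = seed)
  bs <- ripsPersistence(cloud, maxdim = config$maxdim, metric = config$metric)
  attr(bs, "log") <- c(config, list(seed = seed, nRows = nrow(M@mat),
                                    threshold = attr(bs, "threshold")))
  bs
}

#' 3D UMAP embedding of a point cloud (visualization only)
#'
#' Nonlinear embedding used to render the population-vector cloud (a torus
#' appears as a donut). Carries no quantitative contract; requires the
#' `uwot` package.
#'
#' @param x numeric matrix (points in rows).
#' @param nNeighbors,minDist,nComponents,metric UMAP parameters (defaults as
#'   used for toroidal visualizations: 1000 neighbours, min_dist 0.5, 3
#'   components, cosine metric).
#' @param seed RNG seed.
#' @return matrix (`nrow(x)` x `nComponents`).
#' @export
umapView <- function(x, nNeighbors = 1000, minDist = 0.5, nComponents = 3,
                     metric = "cosine", seed = 1) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("umapView needs the 'uwot' package")
  x <- as.matrix(x)
  set.seed(seed)
  uwot::umap(x, n_neighbors = min(nNeighbors, nrow(x) - 1), min_dist = minDist,
             n_components = nComponents, metric = metric)
}
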