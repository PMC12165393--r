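#' Read and write spike trains
#'
#' Columnar text with header `neuron_id,spike_time_s`, one row per spike.
#' Neuron ids are 1-based and contiguous on write; neurons without spikes
#' are preserved through the `n_neurons` header comment.
#'
#' @param file path.
#' @param spikes a [SpikeTrains-class].
#' @return `readSpikeData` returns a [SpikeTrains-class].
#' @export
writeSpikeData <- function(spikes, file) {
  ids <- rep.int(seq_along(spikes@spikes), spikeCounts(spikes))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d span=%.17g,%.17g", nNeurons(spikes),
                     spikes@span[1], spikes@span[2]), con)
  utils::write.csv(data.frame(neuron_id = ids,
    spike_time_s = unlist(spikes@spikes, use.names = FALSE)), con,
    row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeSpikeData
#' @export
readSpikeData <- function(file) {
  first <- readLines(file, n = 1)
  n <- NA; span <- NULL
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    n <- as.integer(sub(".*n_neurons=(\\d+).*", "\\1", first))
    sp <- sub(".*span=([^ ]+).*", "\\1", first)
    span <- as.numeric(strsplit(sp, ",")[[1]])
  }
  df <- tryCatch(utils::read.csv(file, skip = skip),
                 error = function(e) stop("malformed spike file: ", conditionMessage(e)))
  if (!all(c("neuron_id", "spike_time_s") %in% names(df)))
    stop("spike file must have columns neuron_id, spike_time_s")
  if (is.na(n)) n <- max(df$neuron_id)
  spl <- split(df$spike_time_s, factor(df$neuron_id, levels = seq_len(n)))
  SpikeTrains(lapply(spl, as.numeric), span = span)
}

#' Read and write trajectories
#'
#' Columnar text with header `t,x,y` (seconds, meters). On read, a
#' nonuniform time step is resampled to its median step with a message.
#'
#' @param file path.
#' @param traj a [Trajectory-class].
#' @param arena arena side (m) when reading (default from the data extent).
#' @return `readTrajectory` returns a [Trajectory-class].
#' @export
writeTrajectory <- function(traj, file) {
  utils::write.csv(data.frame(t = traj@times, x = traj@xy[, 1],
                              y = traj@xy[, 2]), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(file, arena = NULL) {
  df <- utils::read.csv(file)
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("trajectory file must have columns t, x, y")
  if (is.null(arena)) arena <- max(df$x, df$y)
  dts <- diff(df$t)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * stats::median(dts)) {
    dt <- stats::median(dts)
    message("nonuniform time step: resampling at dt = ", signif(dt, 4), " s")
    tt <- seq(df$t[1], df$t[nrow(df)], by = dt)
    df <- data.frame(t = tt, x = stats::approx(df$t, df$x, tt)$y,
                     y = stats::approx(df$t, df$y, tt)$y)
  }
  new("Trajectory", times = df$t, xy = cbind(df$x, df$y), arena = arena)
}

#' Read and write barcode sets
#'
#' Columnar text with header `dimension,birth,death,truncated`, one row per
#' bar. Readers accept `inf`/`Inf` deaths: such bars are truncated to the
#' largest finite death in the file (or their birth) with a warning. A JSON
#' serialization with the same fields is selected by the file extension.
#'
#' @param file path (`.csv` or `.json`).
#' @param bset a [BarcodeSet-class].
#' @return `readBarcodeSet` returns a [BarcodeSet-class].
#' @export
writeBarcodeSet <- function(bset, file) {
  rows <- do.call(rbind, lapply(0:2, function(d) {
    bc <- barcode(bset, d)
    if (nBars(bc) == 0) return(NULL)
    data.frame(dimension = d, birth = bc@bars[, 1], death = bc@bars[, 2],
               truncated = as.integer(bc@truncated))
  }))
  if (is.null(rows))
    rows <- data.frame(dimension = integer(0), birth = numeric(0),
                       death = numeric(0), truncated = integer(0))
  rownames(rows) <- NULL
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(rows, file, digits = NA)
  } else {
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname writeBarcodeSet
#' @export
readBarcodeSet <- function(file) {
  df <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    utils::read.csv(file)
  }
  if (!all(c("dimension", "birth", "death") %in% names(df)))
    stop("barcode file must have columns dimension, birth, death")
  df$death <- suppressWarnings(as.numeric(df$death))
  df$birth <- as.numeric(df$birth)
  if (is.null(df$truncated)) df$truncated <- 0L
  inf <- !is.finite(df$death)
  if (any(inf)) {
    cap <- if (any(!inf)) max(df$death[!inf]) else max(df$birth)
    warning(sum(inf), " infinite bar(s) truncated at ", signif(cap, 6))
    df$death[inf] <- pmax(cap, df$birth[inf])
    df$truncated[inf] <- 1L
  }
  mk <- function(d) {
    sub <- df[df$dimension == d, , drop = FALSE]
    Barcode(d, cbind(sub$birth, sub$death), sub$truncated == 1)
  }
  BarcodeSet(h0 = mk(0), h1 = mk(1), h2 = mk(2))
}

#' Read and write point clouds
#'
#' Columnar text, one row per point, columns `x1, x2, ...`.
#'
#' @param x numeric matrix (points in rows).
#' @param file path.
#' @return `readPointCloud` returns a numeric matrix.
#' @export
writePointCloud <- function(x, file) {
  x <- as.matrix(x)
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePointCloud
#' @export
readPointCloud <- function(file) {
  as.matrix(utils::read.csv(file))
}

#' Read and write run configurations
#'
#' JSON round-trip of a named parameter list (e.g. [tdaConfig()] plus
#' simulator settings and the master seed). `load -> save -> load` is the
#' identity.
#'
#' @param config named list.
#' @param file path.
#' @return `readRunConfig` returns the named list.
#' @export
writeRunConfig <- function(config, file) {
  jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
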