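# Independent oracles used to validate the compiled engines.

# Brute-force bottleneck distance: enumerate every matching between P and Q,
# allowing any subset of bars on either side to go to the diagonal
# (cost pers/2); the remaining bars are matched bijectively in every
# possible permutation. Exponential; for barcodes with <= 6 bars only.
bottleneck_enum <- function(P, Q, allowDiagonal = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P); m <- nrow(Q)
  cost <- function(p, q) max(abs(p[1] - q[1]), abs(p[2] - q[2]))
  diagc <- function(b) (b[2] - b[1]) / 2
  best <- Inf
  if (!allowDiagonal) {
    stopifnot(n == m)
    if (n == 0) return(0)
    for (perm in asplit(perms(n), 1)) {
      worst <- 0
      for (i in seq_len(n)) worst <- max(worst, cost(P[i, ], Q[perm[i], ]))
      best <- min(best, worst)
    }
    return(best)
  }
  subsets <- function(k) {
    if (k == 0) return(list(integer(0)))
    unlist(lapply(0:(2^k - 1), function(mask) list(which(bitwAnd(mask, 2^(0:(k - 1))) > 0))),
           recursive = FALSE)
  }
  for (sp in subsets(n)) {        # P bars sent to the diagonal
    for (sq in subsets(m)) {      # Q bars sent to the diagonal
      rp <- setdiff(seq_len(n), sp)
      rq <- setdiff(seq_len(m), sq)
      if (length(rp) != length(rq)) next
      base <- 0
      for (i in sp) base <- max(base, diagc(P[i, ]))
      for (j in sq) base <- max(base, diagc(Q[j, ]))
      if (length(rp) == 0) {
        best <- min(best, base)
      } else {
        for (perm in asplit(perms(length(rp)), 1)) {
          worst <- base
          for (i in seq_along(rp)) worst <- max(worst, cost(P[rp[i], ], Q[rq[perm[i]], ]))
          best <- min(best, worst)
        }
      }
    }
  }
  best
}

perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub))
    )
  }))
}

# Pure-R Vietoris-Rips persistence by boundary-matrix reduction over Z/2
# (simplices ordered by ascending diameter, ties by descending
# combinatorial index, matching the engine's total order). Tiny clouds only.
rips_oracle <- function(D, threshold, maxdim = 2) {
  n <- nrow(D)
  simplices <- lapply(1:n, function(i) list(v = i, d = 0, diam = 0))
  for (k in 2:(maxdim + 2)) {
    cc <- utils::combn(n, k)
    for (ci in seq_len(ncol(cc))) {
      v <- cc[, ci]
      diam <- max(D[v, v])
      if (diam <= threshold)
        simplices[[length(simplices) + 1]] <- list(v = v, d = k - 1, diam = diam)
    }
  }
  idx_of <- function(v) { v0 <- sort(v) - 1; sum(choose(v0, seq_along(v0))) }
  key_idx <- vapply(simplices, function(s) idx_of(s$v), 0)
  diams <- vapply(simplices, function(s) s$diam, 0)
  dims <- vapply(simplices, function(s) s$d, 0)
  ord <- order(diams, -key_idx)
  simplices <- simplices[ord]; diams <- diams[ord]; dims <- dims[ord]
  N <- length(simplices)
  pos_of <- new.env(parent = emptyenv())
  for (i in seq_len(N))
    assign(paste(sort(simplices[[i]]$v), collapse = ","), i, envir = pos_of)
  cols <- vector("list", N)
  for (i in seq_len(N)) {
    s <- simplices[[i]]
    if (s$d == 0) { cols[[i]] <- integer(0); next }
    cols[[i]] <- sort(vapply(seq_along(s$v), function(drop)
      get(paste(sort(s$v[-drop]), collapse = ","), envir = pos_of), 0L))
  }
  pivot_owner <- integer(N)
  pairs <- list()
  for (j in seq_len(N)) {
    col <- cols[[j]]
    repeat {
      l <- if (length(col)) max(col) else 0L
      if (l == 0L || pivot_owner[l] == 0L) break
      other <- cols[[pivot_owner[l]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    l <- if (length(col)) max(col) else 0L
    if (l > 0L) {
      pivot_owner[l] <- j
      pairs[[length(pairs) + 1]] <- c(l, j)
    }
  }
  paired <- unlist(pairs)
  out <- lapply(0:maxdim, function(d) matrix(numeric(0), 0, 2))
  for (p in pairs) {
    d <- dims[p[1]]
    if (d > maxdim) next
    if (diams[p[2]] > diams[p[1]])
      out[[d + 1]] <- rbind(out[[d + 1]], c(diams[p[1]], diams[p[2]]))
  }
  for (i in setdiff(seq_len(N), paired)) {
    d <- dims[i]
    if (d <= maxdim) out[[d + 1]] <- rbind(out[[d + 1]], c(diams[i], Inf))
  }
  out
}

# canonical sorted finite bar representation for comparisons
canon_bars <- function(m, threshold) {
  if (nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  b <- m[, 1]; d <- m[, 2]
  d[is.infinite(d)] <- threshold
  keep <- d > b
  mm <- cbind(b[keep], d[keep])
  mm[order(mm[, 1], mm[, 2]), , drop = FALSE]
}

barcode_to_canon <- function(bc, threshold) {
  canon_bars(bars(bc), threshold)
}
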