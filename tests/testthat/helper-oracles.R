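# Independent oracles used to check the implementation. These deliberately
# avoid the package's own code paths (and stats::cor) where they stand in
# judgment of them.

# Pearson correlation on the positive-overlap mask by the direct
# covariance / sigma formula
oraclePearson <- function(a, b) {
  mask <- a > 0 & b > 0
  x <- as.numeric(a[mask]); y <- as.numeric(b[mask])
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# zero-fill integer translation written independently of shiftFrame()
oracleShift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      sr <- r - dy; sc <- cc - dx
      if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc) out[r, cc] <- m[sr, sc]
    }
  }
  out
}

# exhaustive correlation-maximizing search over an integer shift window;
# works on the explicit overlap submatrices, which is equivalent to shifting
# with zero fill and masking (vacated pixels are exactly the non-overlap)
oracleExhaustiveAlign <- function(ref, moving, window) {
  nr <- nrow(ref); nc <- ncol(ref)
  best <- -Inf; bestShift <- c(0L, 0L)
  for (dx in -window:window) {
    for (dy in -window:window) {
      rA <- max(1, 1 + dy):min(nr, nr + dy)
      cA <- max(1, 1 + dx):min(nc, nc + dx)
      a <- ref[rA, cA, drop = FALSE]
      b <- moving[rA - dy, cA - dx, drop = FALSE]
      r <- tryCatch(oraclePearson(a, b), error = function(e) -Inf)
      if (is.finite(r) && r > best) { best <- r; bestShift <- c(dx, dy) }
    }
  }
  list(shift = bestShift, r = best)
}

# connected components (4-neighbour flood fill) of a logical mask
oracleFloodFillCount <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nComp <- 0L
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc] && lab[r, cc] == 0L) {
        nComp <- nComp + 1L
        queue <- list(c(r, cc))
        lab[r, cc] <- nComp
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
                q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- nComp
              queue <- c(queue, list(q))
            }
          }
        }
      }
    }
  }
  nComp
}

# optimal frame-to-frame assignment by brute force over permutations
# (positions as n x 2 matrices); returns total-distance-minimizing matching
# as indices into cur for each prev row (NA = unmatched), for small n only
oracleAssignment <- function(prev, cur, maxDist) {
  nP <- nrow(prev); nC <- nrow(cur)
  stopifnot(nP <= 7, nC <= 7)
  dmat <- sqrt(outer(prev[, 1], cur[, 1], "-")^2 +
               outer(prev[, 2], cur[, 2], "-")^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  k <- min(nP, nC)
  best <- Inf; bestMatch <- rep(NA_integer_, nP)
  for (rows in utils::combn(nP, k, simplify = FALSE)) {
    for (colsPerm in perms(seq_len(nC))) {
      cols <- colsPerm[seq_len(k)]
      dd <- dmat[cbind(rows, cols)]
      if (any(dd > maxDist)) next
      tot <- sum(dd)
      if (tot < best) {
        best <- tot
        bestMatch <- rep(NA_integer_, nP)
        bestMatch[rows] <- cols
      }
    }
  }
  bestMatch
}

# match detected tracks to ground-truth cells by first-window mean position
matchTracksToTruth <- function(tracks, truth) {
  ids <- sort(unique(tracks$track_id))
  vapply(ids, function(id) {
    d <- tracks[tracks$track_id == id, ]
    d <- d[order(d$frame), ]
    cells <- unique(truth$trajectories$cell_id)
    dists <- vapply(cells, function(ci) {
      tt <- truth$trajectories[truth$trajectories$cell_id == ci, ]
      tt <- tt[match(d$frame, tt$frame), ]
      mean(sqrt((tt$x_um - d$x_um)^2 + (tt$y_um - d$y_um)^2))
    }, numeric(1))
    cells[which.min(dists)]
  }, numeric(1))
}
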