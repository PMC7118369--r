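# Gaussian smoothing via EBImage; coerce back to a plain matrix
.gblur <- function(m, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma)))
}

# 3x3 maximum filter (used for spatial local-maximum detection)
.maxFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in 0:2) {
    for (dc in 0:2) {
      out <- pmax(out, pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
    }
  }
  out
}

# 1D Otsu threshold: maximizes between-class variance over value midpoints
.otsu1d <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) stop("otsu threshold needs at least two distinct values")
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; th <- cand[1]
  for (ct in cand) {
    below <- v <= ct
    w1 <- mean(below)
    if (w1 == 0 || w1 == 1) next
    bc <- w1 * (1 - w1) * (mean(v[below]) - mean(v[!below]))^2
    if (bc > best) { best <- bc; th <- ct }
  }
  th
}

#' Detect cells in a registered two-channel frame
#'
#' Scale-space blob detection on the RFP channel: a difference-of-Gaussian
#' pyramid is built over geometrically spaced scales spanning the expected
#' diameter range, and detections are local maxima of the response in space
#' and scale above a response threshold. The blob scale is refined by
#' parabolic interpolation over log-scale; since cells are modelled as
#' Gaussian intensity profiles with sigma = diameter / 4, the reported
#' diameter is 4 x the refined profile sigma. Centroids are response-weighted
#' and sub-pixel. Mean channel intensities are measured in a disk of half the
#' estimated diameter around the centroid.
#'
#' @param rfp,gfp numeric matrices (one registered frame per channel).
#' @param pixelSizeUm micrometres per pixel.
#' @param diameterRangeUm expected cell diameter range in micrometres.
#' @param responseThreshold minimum difference-of-Gaussian response (counts);
#'   guards against noise maxima.
#' @param nScales number of scales spanning the diameter range.
#' @return A data.frame with one row per detection: `x_um`, `y_um`,
#'   `diameter_um`, `mean_rfp`, `mean_gfp`, `response`. A blank frame yields
#'   zero rows, not an error.
#' @export
detectCells <- function(rfp, gfp, pixelSizeUm, diameterRangeUm = c(8, 30),
                        responseThreshold = 25, nScales = 8L) {
  stopifnot(identical(dim(rfp), dim(gfp)), pixelSizeUm > 0)
  sigLo <- diameterRangeUm[1] / 4 / pixelSizeUm
  sigHi <- diameterRangeUm[2] / 4 / pixelSizeUm
  logs <- seq(log(sigLo), log(sigHi), length.out = nScales)
  dlog <- logs[2] - logs[1]
  logs <- c(logs[1] - dlog, logs, logs[nScales] + dlog)
  sigmas <- exp(logs)
  rho <- exp(dlog)
  blurred <- lapply(sigmas, function(s) .gblur(rfp, s))
  resp <- lapply(seq_len(length(sigmas) - 1L),
                 function(k) blurred[[k]] - blurred[[k + 1L]])
  peaks <- NULL
  for (k in 2:(length(resp) - 1L)) {
    Rk <- resp[[k]]
    is_peak <- Rk > responseThreshold & Rk >= .maxFilter3(Rk) &
      Rk >= resp[[k - 1L]] & Rk >= resp[[k + 1L]]
    if (any(is_peak)) {
      idx <- which(is_peak, arr.ind = TRUE)
      peaks <- rbind(peaks, cbind(idx, k = k, resp = Rk[idx]))
    }
  }
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric(), mean_rfp = numeric(),
                      mean_gfp = numeric(), response = numeric())
  if (is.null(peaks)) return(empty)
  peaks <- peaks[order(-peaks[, "resp"]), , drop = FALSE]
  kept <- NULL
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    sigmaB <- exp(logs[p["k"]]) * sqrt(rho)   # DoG peak scale -> blob sigma
    if (!is.null(kept)) {
      dd <- sqrt((kept[, "row"] - p["row"])^2 + (kept[, "col"] - p["col"])^2)
      if (any(dd < 2 * sigmaB)) next          # duplicate of a stronger peak
    }
    kept <- rbind(kept, p)
  }
  nr <- nrow(rfp); nc <- ncol(rfp)
  out <- lapply(seq_len(nrow(kept)), function(i) {
    p <- kept[i, ]
    k <- p[["k"]]; r0 <- p[["row"]]; c0 <- p[["col"]]
    # parabolic log-scale refinement using the responses at this pixel
    r3 <- c(resp[[k - 1L]][r0, c0], resp[[k]][r0, c0], resp[[k + 1L]][r0, c0])
    den <- r3[1] - 2 * r3[2] + r3[3]
    delta <- if (den < 0) min(max(0.5 * (r3[1] - r3[3]) / den, -1), 1) else 0
    sigmaB <- exp(logs[k] + delta * dlog) * sqrt(rho)
    diameterUm <- 4 * sigmaB * pixelSizeUm
    # response-weighted sub-pixel centroid
    w <- ceiling(2 * sigmaB)
    rows <- max(1L, r0 - w):min(nr, r0 + w)
    cols <- max(1L, c0 - w):min(nc, c0 + w)
    wts <- pmax(resp[[k]][rows, cols, drop = FALSE], 0)
    sw <- sum(wts)
    rowC <- sum(wts * matrix(rows, length(rows), length(cols))) / sw
    colC <- sum(wts * matrix(cols, length(rows), length(cols), byrow = TRUE)) / sw
    # mean intensities in a disk of radius diameter/2
    rad <- 2 * sigmaB
    rows2 <- max(1L, floor(rowC - rad)):min(nr, ceiling(rowC + rad))
    cols2 <- max(1L, floor(colC - rad)):min(nc, ceiling(colC + rad))
    inDisk <- outer((rows2 - rowC)^2, (cols2 - colC)^2, "+") <= rad^2
    data.frame(x_um = (colC - 1) * pixelSizeUm, y_um = (rowC - 1) * pixelSizeUm,
               diameter_um = diameterUm,
               mean_rfp = mean(rfp[rows2, cols2][inDisk]),
               mean_gfp = mean(gfp[rows2, cols2][inDisk]),
               response = p[["resp"]])
  })
  do.call(rbind, out)
}

#' Detect cells in every frame of a registered movie
#'
#' @param movie a registered [MovieStack-class].
#' @param ... passed to [detectCells()].
#' @return A data.frame of detections with a `frame` column prepended.
#' @export
detectMovie <- function(movie, ...) {
  psz <- pixelSize(movie)
  out <- lapply(seq_len(nFrames(movie)), function(t) {
    d <- detectCells(getChannel(movie, "rfp", t), getChannel(movie, "gfp", t),
                     psz, ...)
    if (nrow(d)) cbind(frame = t, d) else cbind(frame = integer(), d)
  })
  do.call(rbind, out)
}

#' Classify the Lgr5 reporter state of detections
#'
#' A detection is Lgr5-positive when its mean GFP intensity exceeds the
#' threshold. With `gfpThreshold = "otsu"` the threshold is computed once per
#' movie from the pooled `mean_gfp` distribution of all detections, which
#' separates the bimodal reporter-on/reporter-off populations.
#'
#' @param detections a data.frame with a `mean_gfp` column.
#' @param gfpThreshold a fixed intensity, or `"otsu"`.
#' @return The detections with a logical `lgr5` column; the threshold used is
#'   attached as attribute `gfpThreshold`.
#' @export
classifyLgr5 <- function(detections, gfpThreshold = "otsu") {
  if (identical(gfpThreshold, "otsu")) {
    if (nrow(detections) < 2L) {
      stop("classifyLgr5: otsu mode needs at least 2 detections; supply a fixed threshold")
    }
    gfpThreshold <- .otsu1d(detections$mean_gfp)
  }
  detections$lgr5 <- detections$mean_gfp > gfpThreshold
  attr(detections, "gfpThreshold") <- gfpThreshold
  detections
}

#' Link detections into tracks by greedy nearest-neighbour assignment
#'
#' For each consecutive frame pair, candidate links between the previous
#' frame's detections and the current frame's detections are sorted by
#' increasing distance and accepted greedily, each detection used at most
#' once; links longer than `maxLinkUm` are rejected. Unmatched current-frame
#' detections start new tracks and unmatched previous-frame detections
#' terminate. The global distance ordering makes the assignment deterministic
#' and independent of input row order.
#'
#' @param detections a data.frame with `frame`, `x_um`, `y_um` columns (e.g.
#'   from [detectMovie()]).
#' @param maxLinkUm maximum link distance; default 1.5 x the mean detected
#'   diameter (requires a `diameter_um` column).
#' @return The detections with an integer `track_id` column; every detection
#'   belongs to exactly one track.
#' @export
linkTracks <- function(detections, maxLinkUm = NULL) {
  if (nrow(detections) == 0L) {
    detections$track_id <- integer(0)
    return(detections)
  }
  if (is.null(maxLinkUm)) {
    if (is.null(detections$diameter_um)) {
      stop("linkTracks: maxLinkUm not given and no diameter_um column to derive it")
    }
    maxLinkUm <- 1.5 * mean(detections$diameter_um)
  }
  det <- detections[order(detections$frame, detections$x_um, detections$y_um), ]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  nextId <- 1L
  first <- which(det$frame == frames[1])
  det$track_id[first] <- seq_len(length(first))
  nextId <- length(first) + 1L
  for (i in seq_along(frames)[-1]) {
    prev <- which(det$frame == frames[i - 1L])
    cur <- which(det$frame == frames[i])
    if (length(prev) && length(cur)) {
      dmat <- outer(det$x_um[prev], det$x_um[cur], "-")^2 +
        outer(det$y_um[prev], det$y_um[cur], "-")^2
      ord <- order(dmat)
      usedP <- logical(length(prev)); usedC <- logical(length(cur))
      for (o in ord) {
        if (dmat[o] > maxLinkUm^2) break
        pi <- (o - 1L) %% length(prev) + 1L
        ci <- (o - 1L) %/% length(prev) + 1L
        if (usedP[pi] || usedC[ci]) next
        det$track_id[cur[ci]] <- det$track_id[prev[pi]]
        usedP[pi] <- TRUE; usedC[ci] <- TRUE
      }
    }
    newcomers <- cur[is.na(det$track_id[cur])]
    if (length(newcomers)) {
      det$track_id[newcomers] <- seq(nextId, length.out = length(newcomers))
      nextId <- nextId + length(newcomers)
    }
  }
  det[order(det$track_id, det$frame), ]
}
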