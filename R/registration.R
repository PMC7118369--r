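#' Pearson correlation over the positive-overlap mask
#'
#' Computes the Pearson correlation coefficient between two equally sized
#' frames using only the pixels in which the gray value is strictly positive
#' in both images. Zero-filled pixels introduced by rigid shifting therefore
#' exclude themselves from the comparison.
#'
#' @param a,b numeric matrices of identical dimensions (non-negative counts).
#' @param minOverlap minimum number of pixels in the overlap mask; smaller
#'   masks raise a degenerate-overlap error (condition class
#'   `ivq_degenerate_overlap`), distinct from a dimension mismatch.
#' @return The correlation r in \code{[-1, 1]}.
#' @examples
#' a <- matrix(1:9, 3)
#' pearsonOverlap(a, 2 * a, minOverlap = 4)  # 1: scale invariance
#' @export
pearsonOverlap <- function(a, b, minOverlap = 64L) {
  if (!identical(dim(a), dim(b))) {
    stop("pearsonOverlap: images must have identical dimensions")
  }
  mask <- a > 0 & b > 0
  n <- sum(mask)
  if (n < minOverlap) {
    stop(errorCondition(
      sprintf("degenerate overlap: %d pixels < minimum %d", n, minOverlap),
      class = "ivq_degenerate_overlap"))
  }
  va <- as.numeric(a[mask])
  vb <- as.numeric(b[mask])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop(errorCondition(
      "degenerate overlap: zero variance on the positive-overlap mask",
      class = "ivq_degenerate_overlap"))
  }
  stats::cor(va, vb)
}

#' Rigid integer-pixel translation with zero fill
#'
#' Translates image content by \code{dx} columns (positive = rightward) and
#' \code{dy} rows (positive = downward). Vacated pixels are filled with 0 so
#' they drop out of the positive-overlap mask used by [pearsonOverlap()].
#'
#' @param m numeric matrix.
#' @param dx,dy integer shift in pixels; magnitudes must be smaller than the
#'   corresponding image dimension.
#' @return The shifted matrix; the input is not modified.
#' @export
shiftFrame <- function(m, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dx) >= nc || abs(dy) >= nr) {
    stop("shiftFrame: shift magnitude must be smaller than the image dimension")
  }
  if (dx == 0L && dy == 0L) return(m)
  out <- matrix(0, nr, nc)
  rows <- (1L + max(0L, dy)):(nr + min(0L, dy))
  cols <- (1L + max(0L, dx)):(nc + min(0L, dx))
  out[rows, cols] <- m[rows - dy, cols - dx]
  out
}

#' Greedy single-pixel alignment maximizing Pearson correlation
#'
#' Registers \code{moving} to \code{ref} by hill climbing on the correlation
#' surface: at each step the four unit moves (left, right, up, down) of the
#' current shift are evaluated with [pearsonOverlap()], and the single best
#' candidate is applied if and only if it strictly increases the correlation.
#' Iteration stops when no candidate improves the coefficient (converged) or
#' when \code{maxSteps} is reached. Ties among equally improving candidates
#' are broken in the fixed order left, right, up, down. A degenerate overlap
#' at the starting shift propagates as an error; a degenerate candidate is
#' treated as non-improving.
#'
#' @param ref,moving numeric matrices of identical dimensions, at least
#'   16 x 16.
#' @param initShift integer (dx, dy) warm-start shift (default c(0, 0)).
#' @param maxSteps maximum number of accepted moves (default 200).
#' @param minOverlap passed to [pearsonOverlap()].
#' @return A list with `shift` (cumulative integer (dx, dy)), `r` (final
#'   correlation), `converged` (TRUE when stopped by no-improvement),
#'   `steps` (accepted moves) and `rTrace` (the strictly increasing sequence
#'   of accepted correlations, starting at the initial one).
#' @export
greedyAlign <- function(ref, moving, initShift = c(0L, 0L), maxSteps = 200L,
                        minOverlap = 64L) {
  if (!identical(dim(ref), dim(moving))) {
    stop("greedyAlign: images must have identical dimensions")
  }
  if (nrow(ref) < 16L || ncol(ref) < 16L) {
    stop("greedyAlign: images smaller than 16 x 16 are rejected")
  }
  if (maxSteps < 1L) stop("greedyAlign: maxSteps must be >= 1")
  cur <- as.integer(round(initShift))
  rCur <- pearsonOverlap(ref, shiftFrame(moving, cur[1], cur[2]), minOverlap)
  rTrace <- rCur
  moves <- rbind(left = c(-1L, 0L), right = c(1L, 0L),
                 up = c(0L, -1L), down = c(0L, 1L))
  steps <- 0L
  converged <- FALSE
  while (steps < maxSteps) {
    cand <- vapply(seq_len(4L), function(i) {
      s <- cur + moves[i, ]
      tryCatch(
        pearsonOverlap(ref, shiftFrame(moving, s[1], s[2]), minOverlap),
        ivq_degenerate_overlap = function(e) -Inf,
        error = function(e) -Inf)
    }, numeric(1))
    best <- which.max(cand)      # first max: ties resolve left,right,up,down
    if (cand[best] > rCur) {
      cur <- cur + moves[best, ]
      rCur <- cand[best]
      rTrace <- c(rTrace, rCur)
      steps <- steps + 1L
    } else {
      converged <- TRUE
      break
    }
  }
  list(shift = cur, r = rCur, converged = converged, steps = steps,
       rTrace = rTrace)
}

#' Register a movie to its first time point
#'
#' Aligns every frame t >= 2 to frame 1 by [greedyAlign()] on the nominated
#' registration channel (default RFP, carried by all tumor cells), warm
#' starting each frame from the previous frame's accepted shift since tissue
#' drift accumulates. The identical shift is applied to both channels of a
#' frame; re-applying the returned [ShiftSeries-class] to the raw stack
#' reproduces the corrected stack exactly.
#'
#' A frame whose overlap is degenerate is flagged unconverged, inherits the
#' previous frame's shift, and triggers a warning; the run does not abort.
#'
#' @param movie a [MovieStack-class] with at least 2 frames.
#' @param channel registration channel, `"rfp"` (default) or `"gfp"`.
#' @param maxSteps,minOverlap passed to [greedyAlign()].
#' @return A list with `movie` (corrected [MovieStack-class]) and `shifts`
#'   (a [ShiftSeries-class]).
#' @export
registerMovie <- function(movie, channel = c("rfp", "gfp"), maxSteps = 200L,
                          minOverlap = 64L) {
  channel <- match.arg(channel)
  nT <- nFrames(movie)
  if (nT < 2L) stop("registerMovie: movie must have at least 2 frames")
  ref <- getChannel(movie, channel, 1L)
  shiftMat <- matrix(0L, nT, 2L)
  conv <- rep(TRUE, nT)
  rFin <- rep(NA_real_, nT)
  rFin[1L] <- 1
  for (t in 2:nT) {
    init <- shiftMat[t - 1L, ]
    res <- tryCatch(
      greedyAlign(ref, getChannel(movie, channel, t), initShift = init,
                  maxSteps = maxSteps, minOverlap = minOverlap),
      ivq_degenerate_overlap = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf(
        "registerMovie: degenerate overlap at frame %d; carrying over previous shift", t))
      shiftMat[t, ] <- init
      conv[t] <- FALSE
    } else {
      shiftMat[t, ] <- res$shift
      conv[t] <- res$converged
      rFin[t] <- res$r
    }
  }
  ss <- ShiftSeries(shiftMat, conv, rFin)
  list(movie = applyShifts(movie, ss), shifts = ss)
}

#' Apply a ShiftSeries to a raw movie
#'
#' @param movie a [MovieStack-class].
#' @param shiftSeries a [ShiftSeries-class] with one row per frame.
#' @return The corrected [MovieStack-class].
#' @export
applyShifts <- function(movie, shiftSeries) {
  s <- shifts(shiftSeries)
  nT <- nFrames(movie)
  if (nrow(s) != nT) stop("applyShifts: frame count mismatch")
  rfp <- getChannel(movie, "rfp")
  gfp <- getChannel(movie, "gfp")
  for (t in seq_len(nT)) {
    if (s[t, 1] != 0L || s[t, 2] != 0L) {
      rfp[, , t] <- shiftFrame(rfp[, , t], s[t, 1], s[t, 2])
      gfp[, , t] <- shiftFrame(gfp[, , t], s[t, 1], s[t, 2])
    }
  }
  MovieStack(rfp, gfp, pixelSize(movie), frameInterval(movie), bitDepth(movie))
}

#' Validate a drift correction by landmark residual motion
#'
#' Implements the success rule used for intravital corrections: positions of
#' picked (static) cells are tracked in the corrected movie, and the
#' correction is called successful when every landmark moves less than half a
#' cell diameter net over a 4-hour window.
#'
#' @param landmarks a data.frame of per-frame landmark centroids with columns
#'   `track_id`, `frame`, `x_um`, `y_um` (as produced by [linkTracks()]), or a
#'   list of (frames x 2) matrices of centroids in micrometres.
#' @param cellDiameterUm cell diameter in micrometres.
#' @param frameIntervalH hours between frames.
#' @param windowH validation window in hours (default 4); the landmark series
#'   must span at least this long.
#' @return A list with `success` (all residuals strictly below half a
#'   diameter), `maxResidualUm`, and `residualsUm` per landmark.
#' @export
validateCorrection <- function(landmarks, cellDiameterUm, frameIntervalH,
                               windowH = 4) {
  if (is.data.frame(landmarks)) {
    landmarks <- lapply(split(landmarks, landmarks$track_id), function(d) {
      d <- d[order(d$frame), ]
      cbind(d$x_um, d$y_um)
    })
  }
  if (length(landmarks) == 0L) stop("validateCorrection: no landmarks given")
  if (cellDiameterUm <= 0) stop("validateCorrection: cell diameter must be > 0")
  nWin <- as.integer(round(windowH / frameIntervalH))
  residuals <- vapply(landmarks, function(p) {
    if ((nrow(p) - 1L) * frameIntervalH < windowH) {
      stop("validateCorrection: landmark series shorter than the validation window")
    }
    sqrt(sum((p[1L + nWin, ] - p[1L, ])^2))
  }, numeric(1))
  list(success = all(residuals < 0.5 * cellDiameterUm),
       maxResidualUm = max(residuals),
       residualsUm = residuals)
}
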