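#' Configuration for the synthetic movie generator
#'
#' Builds and validates the parameter set for [simulateMovie()]. Defaults
#' emulate hourly intravital acquisition of a colorectal tumor field over a
#' 4-hour window (5 frames), 12-bit intensities, cells of ~15 um diameter
#' rendered as isotropic Gaussian blobs (sigma = diameter / 4), and a slow
#' integer-pixel random-walk tissue drift.
#'
#' Cells are split into static cells, single migratory cells, and cluster
#' events; each cluster event contributes two co-migrating cells in sustained
#' contact, so the movie carries
#' `nMigratoryCells + 2 * nClusterEvents` migratory cells in total.
#'
#' @param imageHeightPx,imageWidthPx frame size in pixels.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param nFrames number of time points (>= 2).
#' @param frameIntervalH hours between frames (> 0).
#' @param nStaticCells,nMigratoryCells,nClusterEvents non-negative counts.
#' @param pLgr5Pos probability that a static cell is Lgr5-positive.
#' @param pNegAmongMigratory probability that a migratory cell is
#'   Lgr5-negative.
#' @param cellDiameterMeanUm,cellDiameterSdUm cell diameter distribution (um).
#' @param migratoryStepUmPerFrame step length of migratory cells (um/frame).
#' @param drift either `list(model = "none")`,
#'   `list(model = "random_walk", maxStepPx = k)` (per-frame independent
#'   integer steps uniform on \[-k, k\] in x and y, accumulated), or
#'   `list(model = "fixed", shifts = <nFrames x 2 integer matrix>)` giving the
#'   cumulative (dx, dy) drift of each frame (row 1 must be 0, 0).
#' @param noiseSd additive zero-mean Gaussian noise sd (intensity counts).
#' @param staticJitterFrac per-frame positional jitter sd of static cells as a
#'   fraction of their diameter (default 0.01, keeping total wander well below
#'   a tenth of a diameter).
#' @param headingJitterRad per-frame angular jitter sd of migratory headings.
#' @param background,amplitude named vectors (rfp, gfp) of background level
#'   and blob peak amplitude in counts.
#' @param bitDepth acquisition bit depth (default 12).
#' @param seed RNG seed making the movie fully reproducible.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(imageHeightPx = 192L, imageWidthPx = 192L,
                      pixelSizeUm = 1, nFrames = 5L, frameIntervalH = 1,
                      nStaticCells = 6L, nMigratoryCells = 4L,
                      nClusterEvents = 1L, pLgr5Pos = 0.3,
                      pNegAmongMigratory = 0.9, cellDiameterMeanUm = 15,
                      cellDiameterSdUm = 1.5, migratoryStepUmPerFrame = 4,
                      drift = list(model = "random_walk", maxStepPx = 2L),
                      noiseSd = 20, staticJitterFrac = 0.01,
                      headingJitterRad = 0.1,
                      background = c(rfp = 100, gfp = 30),
                      amplitude = c(rfp = 2500, gfp = 2000),
                      bitDepth = 12L, seed = 1L) {
  cfg <- list(
    imageHeightPx = as.integer(imageHeightPx),
    imageWidthPx = as.integer(imageWidthPx),
    pixelSizeUm = pixelSizeUm, nFrames = as.integer(nFrames),
    frameIntervalH = frameIntervalH,
    nStaticCells = as.integer(nStaticCells),
    nMigratoryCells = as.integer(nMigratoryCells),
    nClusterEvents = as.integer(nClusterEvents),
    pLgr5Pos = pLgr5Pos, pNegAmongMigratory = pNegAmongMigratory,
    cellDiameterMeanUm = cellDiameterMeanUm,
    cellDiameterSdUm = cellDiameterSdUm,
    migratoryStepUmPerFrame = migratoryStepUmPerFrame,
    drift = drift, noiseSd = noiseSd,
    staticJitterFrac = staticJitterFrac,
    headingJitterRad = headingJitterRad,
    background = background, amplitude = amplitude,
    bitDepth = as.integer(bitDepth), seed = as.integer(seed))
  probs <- c(cfg$pLgr5Pos, cfg$pNegAmongMigratory)
  if (any(probs < 0 | probs > 1)) stop("simConfig: probabilities must lie in [0, 1]")
  if (cfg$imageHeightPx < 1L || cfg$imageWidthPx < 1L || cfg$pixelSizeUm <= 0) {
    stop("simConfig: image dimensions and pixel size must be positive")
  }
  if (cfg$nFrames < 2L) stop("simConfig: nFrames must be >= 2")
  if (cfg$frameIntervalH <= 0) stop("simConfig: frameIntervalH must be > 0")
  if (min(cfg$nStaticCells, cfg$nMigratoryCells, cfg$nClusterEvents) < 0L) {
    stop("simConfig: cell counts must be non-negative")
  }
  if (cfg$cellDiameterMeanUm <= 0 || cfg$cellDiameterSdUm < 0 ||
      cfg$migratoryStepUmPerFrame < 0 || cfg$noiseSd < 0) {
    stop("simConfig: sizes and noise must be non-negative")
  }
  if (!cfg$drift$model %in% c("none", "random_walk", "fixed")) {
    stop("simConfig: drift model must be none, random_walk or fixed")
  }
  if (cfg$drift$model == "fixed") {
    s <- cfg$drift$shifts
    if (!is.matrix(s) || nrow(s) != cfg$nFrames || ncol(s) != 2L ||
        any(s[1L, ] != 0)) {
      stop("simConfig: fixed drift needs an nFrames x 2 matrix with zero first row")
    }
  }
  nMig <- cfg$nMigratoryCells + 2L * cfg$nClusterEvents
  if (nMig > 0L && cfg$frameIntervalH * (cfg$nFrames - 1L) < 4) {
    warning("simConfig: movie spans less than 4 h; migratory classification cannot be exercised")
  }
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d x %d px @ %.3g um/px, %d frames every %.3g h\n",
              x$imageHeightPx, x$imageWidthPx, x$pixelSizeUm, x$nFrames,
              x$frameIntervalH))
  cat(sprintf("  cells: %d static, %d single migratory, %d cluster events; drift: %s; seed %d\n",
              x$nStaticCells, x$nMigratoryCells, x$nClusterEvents,
              x$drift$model, x$seed))
  invisible(x)
}

# cumulative per-frame drift (nFrames x 2 integer matrix, row 1 = 0,0)
.simDrift <- function(cfg) {
  nT <- cfg$nFrames
  switch(cfg$drift$model,
    none = matrix(0L, nT, 2L),
    fixed = matrix(as.integer(cfg$drift$shifts), nT, 2L),
    random_walk = {
      k <- as.integer(cfg$drift$maxStepPx)
      steps <- matrix(sample(seq(-k, k), 2L * (nT - 1L), replace = TRUE),
                      ncol = 2L)
      rbind(c(0L, 0L), apply(steps, 2L, cumsum))
    })
}

# trajectory of one migratory center: start, constant heading + angular jitter
.migratoryPath <- function(start, theta0, step, nT, jitterSd) {
  theta <- theta0 + cumsum(c(0, stats::rnorm(nT - 2L, 0, jitterSd)))
  pos <- matrix(NA_real_, nT, 2L)
  pos[1L, ] <- start
  for (f in 2:nT) {
    pos[f, ] <- pos[f - 1L, ] + step * c(cos(theta[f - 1L]), sin(theta[f - 1L]))
  }
  pos
}

.inBox <- function(pos, lo, hiX, hiY) {
  all(pos[, 1] >= lo & pos[, 1] <= hiX & pos[, 2] >= lo & pos[, 2] <= hiY)
}

# minimum over co-temporal frames of the distance between two trajectories
.minPairDist <- function(a, b) {
  min(sqrt(rowSums((a - b)^2)))
}

#' Generate a seeded synthetic two-channel movie with full ground truth
#'
#' Renders static, single-migratory and cluster-migratory cells as isotropic
#' Gaussian blobs (sigma = diameter / 4) in the RFP channel, with Lgr5-positive
#' cells additionally rendered with the same footprint in the GFP channel. The
#' whole content of frame t is rigidly translated by that frame's cumulative
#' drift, zero-mean Gaussian noise is added, and intensities are clipped to
#' the bit-depth range. The returned ground truth holds the true drift,
#' drift-free trajectories in micrometres, Lgr5 states, migratory labels and
#' migration modes.
#'
#' Placement guarantees the labels are self-consistent: cells not belonging to
#' the same cluster event keep a distance of at least 1.6 x the sum of their
#' radii in every frame (so singles never register sustained contact), while
#' the two cells of a cluster event co-move at 0.9 x the sum of their radii
#' (always in contact). Cells that cannot be placed inside the frame at those
#' margins raise a configuration error.
#'
#' @param config a [simConfig()] object.
#' @return A list with `movie` (a [MovieStack-class]) and `truth`, a list
#'   holding `shiftsPx` (nFrames x 2 cumulative drift), `trajectories`
#'   (data.frame cell_id, frame, x_um, y_um in drift-free coordinates),
#'   `lgr5`, `migratory`, `mode` (single/cluster/NA per cell), `clusterId`,
#'   `diametersUm` and the config. Warnings raised during generation (e.g.
#'   drift pushing over half the content out of frame) are collected in the
#'   `log` attribute of the result.
#' @export
simulateMovie <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  runLog <- character()
  psz <- config$pixelSizeUm
  Wum <- config$imageWidthPx * psz
  Hum <- config$imageHeightPx * psz
  nT <- config$nFrames
  margin <- config$cellDiameterMeanUm
  if (Wum - 2 * margin <= 0 || Hum - 2 * margin <= 0) {
    nCellsTotal <- config$nStaticCells + config$nMigratoryCells +
      2L * config$nClusterEvents
    if (nCellsTotal > 0L) {
      stop("simulateMovie: frame too small to initialize cells inside its margins")
    }
  }

  ns <- config$nStaticCells
  nmSingle <- config$nMigratoryCells
  nc <- config$nClusterEvents
  nCells <- ns + nmSingle + 2L * nc
  diam <- pmax(6, stats::rnorm(nCells, config$cellDiameterMeanUm,
                               config$cellDiameterSdUm))
  migratory <- c(rep(FALSE, ns), rep(TRUE, nmSingle + 2L * nc))
  clusterId <- c(rep(NA_integer_, ns + nmSingle), rep(seq_len(nc), each = 2L))
  mode <- ifelse(!migratory, NA_character_,
                 ifelse(is.na(clusterId), "single", "cluster"))
  lgr5 <- logical(nCells)
  if (ns > 0L) lgr5[1:ns] <- stats::runif(ns) < config$pLgr5Pos
  if (nCells > ns) {
    lgr5[(ns + 1L):nCells] <- stats::runif(nCells - ns) >=
      config$pNegAmongMigratory
  }

  # place entities sequentially under the pairwise separation constraint
  traj <- vector("list", nCells)       # each: nFrames x 2 (x_um, y_um)
  sepOk <- function(candList, cellIdx) {
    for (j in seq_along(traj)) {
      if (is.null(traj[[j]])) next
      for (k in seq_along(candList)) {
        i <- cellIdx[k]
        if (!is.na(clusterId[i]) && !is.na(clusterId[j]) &&
            clusterId[i] == clusterId[j]) next
        need <- 1.6 * (diam[i] / 2 + diam[j] / 2)
        if (.minPairDist(candList[[k]], traj[[j]]) < need) return(FALSE)
      }
    }
    TRUE
  }
  placeEntity <- function(cellIdx, makeTraj) {
    for (try in seq_len(500L)) {
      cand <- makeTraj()
      if (is.null(cand)) next
      if (sepOk(cand, cellIdx)) {
        for (k in seq_along(cand)) traj[[cellIdx[k]]] <<- cand[[k]]
        return(invisible(TRUE))
      }
    }
    stop("simulateMovie: frame too small to place the requested cells at the required separations")
  }
  randStart <- function() c(stats::runif(1, margin, Wum - margin),
                            stats::runif(1, margin, Hum - margin))
  for (i in seq_len(ns)) {
    placeEntity(i, function() {
      base <- randStart()
      jit <- matrix(stats::rnorm(2L * nT, 0,
                                 config$staticJitterFrac * diam[i]), nT, 2L)
      p <- sweep(jit, 2L, base, "+")
      if (.inBox(p, margin, Wum - margin, Hum - margin)) list(p) else NULL
    })
  }
  stepUm <- config$migratoryStepUmPerFrame
  for (i in seq_len(nmSingle)) {
    idx <- ns + i
    placeEntity(idx, function() {
      p <- .migratoryPath(randStart(), stats::runif(1, 0, 2 * pi), stepUm, nT,
                          config$headingJitterRad)
      if (.inBox(p, margin, Wum - margin, Hum - margin)) list(p) else NULL
    })
  }
  for (e in seq_len(nc)) {
    idx <- ns + nmSingle + 2L * (e - 1L) + 1:2
    placeEntity(idx, function() {
      theta0 <- stats::runif(1, 0, 2 * pi)
      ctr <- .migratoryPath(randStart(), theta0, stepUm, nT,
                            config$headingJitterRad)
      sep <- 0.9 * (diam[idx[1]] / 2 + diam[idx[2]] / 2)  # always in contact
      off <- sep * c(-sin(theta0), cos(theta0))
      p1 <- sweep(ctr, 2L, off / 2, "-")
      p2 <- sweep(ctr, 2L, off / 2, "+")
      if (.inBox(p1, margin, Wum - margin, Hum - margin) &&
          .inBox(p2, margin, Wum - margin, Hum - margin)) list(p1, p2) else NULL
    })
  }

  driftPx <- .simDrift(config)
  keepFrac <- (config$imageWidthPx - abs(driftPx[, 1])) *
    (config$imageHeightPx - abs(driftPx[, 2])) /
    (config$imageWidthPx * config$imageHeightPx)
  if (any(keepFrac < 0.5)) {
    msg <- sprintf("drift pushes more than 50%% of content out of frame at frame(s) %s",
                   paste(which(keepFrac < 0.5), collapse = ", "))
    warning(paste0("simulateMovie: ", msg))
    runLog <- c(runLog, msg)
  }

  maxVal <- 2^config$bitDepth - 1
  rfp <- array(config$background[["rfp"]],
               c(config$imageHeightPx, config$imageWidthPx, nT))
  gfp <- array(config$background[["gfp"]],
               c(config$imageHeightPx, config$imageWidthPx, nT))
  addBlob <- function(img, rowC, colC, sigmaPx, amp) {
    w <- ceiling(4 * sigmaPx)
    rLo <- max(1, floor(rowC - w)); rHi <- min(nrow(img), ceiling(rowC + w))
    cLo <- max(1, floor(colC - w)); cHi <- min(ncol(img), ceiling(colC + w))
    if (rLo > rHi || cLo > cHi) return(img)     # blob drifted out of frame
    rows <- rLo:rHi
    cols <- cLo:cHi
    g <- exp(-(outer((rows - rowC)^2, (cols - colC)^2, "+")) / (2 * sigmaPx^2))
    img[rows, cols] <- img[rows, cols] + amp * g
    img
  }
  for (t in seq_len(nT)) {
    for (i in seq_len(nCells)) {
      colC <- traj[[i]][t, 1] / psz + 1 + driftPx[t, 1]
      rowC <- traj[[i]][t, 2] / psz + 1 + driftPx[t, 2]
      sigmaPx <- diam[i] / 4 / psz
      rfp[, , t] <- addBlob(rfp[, , t], rowC, colC, sigmaPx,
                            config$amplitude[["rfp"]])
      if (lgr5[i]) {
        gfp[, , t] <- addBlob(gfp[, , t], rowC, colC, sigmaPx,
                              config$amplitude[["gfp"]])
      }
    }
  }
  if (config$noiseSd > 0) {
    rfp <- rfp + stats::rnorm(length(rfp), 0, config$noiseSd)
    gfp <- gfp + stats::rnorm(length(gfp), 0, config$noiseSd)
  }
  rfp <- pmin(pmax(round(rfp), 0), maxVal)
  gfp <- pmin(pmax(round(gfp), 0), maxVal)

  trajectories <- if (nCells > 0L) {
    do.call(rbind, lapply(seq_len(nCells), function(i) {
      data.frame(cell_id = i, frame = seq_len(nT),
                 x_um = traj[[i]][, 1], y_um = traj[[i]][, 2])
    }))
  } else {
    data.frame(cell_id = integer(), frame = integer(),
               x_um = numeric(), y_um = numeric())
  }
  truth <- list(shiftsPx = driftPx, trajectories = trajectories, lgr5 = lgr5,
                migratory = migratory, mode = mode, clusterId = clusterId,
                diametersUm = diam, config = config)
  structure(list(movie = MovieStack(rfp, gfp, psz, config$frameIntervalH,
                                    config$bitDepth),
                 truth = truth),
            log = runLog)
}

#' Generate a synthetic metastatic-lesion table with a step composition rule
#'
#' Lesion diameters are drawn uniformly on `diameterRangeUm`. A lesion
#' contains Lgr5-positive cells with probability 1 when its diameter exceeds
#' the plasticity threshold `thresholdUm`, and with probability `p0Below`
#' otherwise — except lesions at single-cell scale (diameter at or below
#' `cellDiameterMeanUm`), which are always Lgr5-negative, matching the
#' observation that single-cell metastases are uniformly Lgr5-negative.
#' The packaged defaults (threshold 80 um, below-threshold probability 0.4)
#' reproduce the qualitative size-composition structure of scored liver
#' metastases.
#'
#' @param nLesions number of lesions (>= 0).
#' @param diameterRangeUm positive interval for the uniform diameter draw.
#' @param thresholdUm plasticity threshold L* in micrometres.
#' @param p0Below probability a below-threshold (non-single-cell) lesion
#'   contains Lgr5-positive cells.
#' @param cellDiameterMeanUm single-cell scale in micrometres.
#' @param seed RNG seed.
#' @return A list with `lesions` (data.frame lesion_id, diameter_um,
#'   contains_lgr5) and `truth` (the rule parameters).
#' @export
simulateLesionTable <- function(nLesions, diameterRangeUm = c(10, 300),
                                thresholdUm = 80, p0Below = 0.4,
                                cellDiameterMeanUm = 15, seed = 1L) {
  if (nLesions < 0) stop("simulateLesionTable: nLesions must be >= 0")
  if (any(diameterRangeUm <= 0) || diff(diameterRangeUm) < 0) {
    stop("simulateLesionTable: diameter range must be positive and ordered")
  }
  if (p0Below < 0 || p0Below > 1) {
    stop("simulateLesionTable: p0Below must lie in [0, 1]")
  }
  set.seed(seed)
  d <- stats::runif(nLesions, diameterRangeUm[1], diameterRangeUm[2])
  contains <- ifelse(d > thresholdUm, TRUE, stats::runif(nLesions) < p0Below)
  contains[d <= cellDiameterMeanUm] <- FALSE
  lesions <- data.frame(lesion_id = seq_len(nLesions), diameter_um = d,
                        contains_lgr5 = as.logical(contains))
  list(lesions = lesions,
       truth = list(thresholdUm = thresholdUm, p0Below = p0Below,
                    cellDiameterMeanUm = cellDiameterMeanUm,
                    diameterRangeUm = diameterRangeUm))
}
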