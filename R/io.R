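#' Write a movie as a multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-interleaved (frame 1 RFP, frame 1 GFP, frame 2 RFP, ...)
#' and stored as 16-bit samples, so 12-bit counts round-trip bit-exactly.
#' The sidecar records pixel size, frame interval, channel roles, bit depth
#' and frame count.
#'
#' @param movie a [MovieStack-class].
#' @param path output TIFF path.
#' @param metaPath sidecar JSON path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path, metaPath = paste0(path, ".json")) {
  nT <- nFrames(movie)
  pages <- vector("list", 2L * nT)
  for (t in seq_len(nT)) {
    pages[[2L * t - 1L]] <- getChannel(movie, "rfp", t) / 65535
    pages[[2L * t]] <- getChannel(movie, "gfp", t) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = pixelSize(movie),
               frame_interval_h = frameInterval(movie),
               bit_depth = bitDepth(movie),
               channels = c("rfp", "gfp"), n_frames = nT)
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [writeMovie()]
#'
#' @param path TIFF path.
#' @param metaPath sidecar JSON path; default `<path>.json`.
#' @return A [MovieStack-class].
#' @export
readMovie <- function(path, metaPath = paste0(path, ".json")) {
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nT <- as.integer(meta$n_frames)
  stopifnot(length(pages) == 2L * nT)
  d <- dim(pages[[1]])
  rfp <- array(0, c(d[1], d[2], nT))
  gfp <- array(0, c(d[1], d[2], nT))
  for (t in seq_len(nT)) {
    rfp[, , t] <- round(pages[[2L * t - 1L]] * 65535)
    gfp[, , t] <- round(pages[[2L * t]] * 65535)
  }
  MovieStack(rfp, gfp, meta$pixel_size_um, meta$frame_interval_h,
             as.integer(meta$bit_depth))
}

#' Write / read a ShiftSeries as CSV
#'
#' Columns: `frame`, `dx_px`, `dy_px`, `r_final`, `converged`.
#'
#' @param shiftSeries a [ShiftSeries-class].
#' @param path CSV path.
#' @return `path` invisibly; `readShifts` returns a [ShiftSeries-class].
#' @export
writeShifts <- function(shiftSeries, path) {
  s <- shifts(shiftSeries)
  utils::write.csv(data.frame(frame = seq_len(nrow(s)),
                              dx_px = s[, 1], dy_px = s[, 2],
                              r_final = finalCorrelation(shiftSeries),
                              converged = converged(shiftSeries)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeShifts
#' @export
readShifts <- function(path) {
  d <- utils::read.csv(path)
  ShiftSeries(cbind(d$dx_px, d$dy_px), d$converged, d$r_final)
}

#' Write generator ground truth as CSV files
#'
#' Produces `cells.csv` (one row per cell per frame: cell_id, frame, x_um,
#' y_um, lgr5, migratory, mode) and `shifts.csv` (frame, dx_px, dy_px holding
#' the true cumulative drift) under `dir`.
#'
#' @param truth the `truth` element returned by [simulateMovie()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- truth$trajectories
  tr$lgr5 <- truth$lgr5[tr$cell_id]
  tr$migratory <- truth$migratory[tr$cell_id]
  tr$mode <- truth$mode[tr$cell_id]
  utils::write.csv(tr, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_len(nrow(truth$shiftsPx)),
                              dx_px = truth$shiftsPx[, 1],
                              dy_px = truth$shiftsPx[, 2]),
                   file.path(dir, "shifts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names match the arguments of [simConfig()]; a `drift` entry is
#' passed through as the drift model list.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `SimConfig`.
#' @export
readSimConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$drift) && !is.null(cfg$drift$shifts)) {
    cfg$drift$shifts <- matrix(as.integer(unlist(cfg$drift$shifts)),
                               ncol = 2L, byrow = TRUE)
  }
  if (!is.null(cfg$background)) cfg$background <- unlist(cfg$background)
  if (!is.null(cfg$amplitude)) cfg$amplitude <- unlist(cfg$amplitude)
  do.call(simConfig, cfg)
}
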