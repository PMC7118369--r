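#' Per-track migration metrics over the analysis window
#'
#' Computes, for each track, the metrics the migratory classification is based
#' on: net start-to-end displacement over the first `windowH`-long sub-track,
#' cumulative path length over the same window, and velocity (net
#' displacement divided by the window, the default, or path length divided by
#' the window when `velocityMode = "path"`). Tracks that do not span the
#' window, or have a gap inside it, are excluded (with the reason recorded in
#' the `excluded` attribute), not errored.
#'
#' @param tracks a data.frame with `track_id`, `frame`, `x_um`, `y_um` and
#'   optionally `diameter_um`, `lgr5`, `animal_id`, `movie_id` columns.
#' @param frameIntervalH hours between frames.
#' @param windowH analysis window in hours (default 4, the window over which
#'   the half-diameter migratory rule is defined).
#' @param cellDiameterUm global diameter override for the migratory rule;
#'   when `NULL` (default) each track uses its mean detected diameter.
#' @param velocityMode `"net"` (default) or `"path"`; the choice is recorded
#'   in the output.
#' @return A data.frame with one row per retained track: `track_id`,
#'   `n_frames`, `duration_h`, `net_displacement_um`, `path_length_um`,
#'   `velocity_um_per_h`, `diameter_um`, `lgr5` (majority vote over member
#'   detections, ties resolved toward Lgr5-positive), `migratory`, `mode`
#'   (filled by [classifyMode()]; `not_migratory` or `NA` here), plus
#'   `animal_id` / `movie_id` when present.
#' @export
computeTrackMetrics <- function(tracks, frameIntervalH, windowH = 4,
                                cellDiameterUm = NULL,
                                velocityMode = c("net", "path")) {
  velocityMode <- match.arg(velocityMode)
  stopifnot(frameIntervalH > 0, windowH > 0)
  nWin <- as.integer(round(windowH / frameIntervalH))
  excluded <- data.frame(track_id = integer(), reason = character())
  rows <- lapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$frame), ]
    id <- d$track_id[1]
    if ((nrow(d) - 1L) * frameIntervalH < windowH) {
      excluded <<- rbind(excluded, data.frame(
        track_id = id, reason = "track shorter than analysis window"))
      return(NULL)
    }
    win <- d[seq_len(nWin + 1L), ]
    if (any(diff(win$frame) != 1L)) {
      excluded <<- rbind(excluded, data.frame(
        track_id = id, reason = "gap inside analysis window"))
      return(NULL)
    }
    stepsUm <- sqrt(diff(win$x_um)^2 + diff(win$y_um)^2)
    net <- sqrt((win$x_um[nWin + 1L] - win$x_um[1L])^2 +
                (win$y_um[nWin + 1L] - win$y_um[1L])^2)
    path <- sum(stepsUm)
    diam <- if (!is.null(cellDiameterUm)) cellDiameterUm
            else if (!is.null(d$diameter_um)) mean(d$diameter_um)
            else stop("computeTrackMetrics: no diameter_um column and no override")
    lgr5 <- if (!is.null(d$lgr5)) mean(d$lgr5) >= 0.5 else NA
    data.frame(track_id = id, n_frames = nrow(d),
               duration_h = (nrow(d) - 1L) * frameIntervalH,
               net_displacement_um = net, path_length_um = path,
               velocity_um_per_h = (if (velocityMode == "net") net else path) / windowH,
               diameter_um = diam, lgr5 = lgr5,
               migratory = classifyMigratory(net, diam),
               mode = NA_character_,
               animal_id = if (!is.null(d$animal_id)) d$animal_id[1] else NA,
               movie_id = if (!is.null(d$movie_id)) d$movie_id[1] else NA)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), n_frames = integer(),
                      duration_h = numeric(), net_displacement_um = numeric(),
                      path_length_um = numeric(), velocity_um_per_h = numeric(),
                      diameter_um = numeric(), lgr5 = logical(),
                      migratory = logical(), mode = character(),
                      animal_id = character(), movie_id = character())
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "velocityMode") <- velocityMode
  out
}

#' The half-cell-diameter migratory rule
#'
#' A cell is migratory when its net displacement over the 4-hour analysis
#' window is strictly more than half a cell diameter; a displacement of
#' exactly half a diameter is not migratory.
#'
#' @param netDisplacementUm net displacement(s) in micrometres.
#' @param cellDiameterUm cell diameter(s) in micrometres (> 0).
#' @return Logical vector.
#' @examples
#' classifyMigratory(c(10, 10.1), 20)  # FALSE at the boundary, TRUE above
#' @export
classifyMigratory <- function(netDisplacementUm, cellDiameterUm) {
  if (any(cellDiameterUm <= 0)) {
    stop("classifyMigratory: cell diameter must be positive")
  }
  netDisplacementUm > 0.5 * cellDiameterUm
}

#' Classify migratory tracks as single cells or cell clusters
#'
#' Two migratory cells are in contact in a frame when their center distance is
#' at most `contactFactor` x the sum of their radii. A migratory track is a
#' cluster when it is in contact with at least one other migratory track in at
#' least a `persistence` fraction of its analysis-window frames (sustained
#' cell-cell contact); otherwise it escapes as a single cell. Contact is
#' symmetric. Non-migratory tracks receive mode `not_migratory`.
#'
#' @param tracks the detection-level track table (columns `track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param metrics output of [computeTrackMetrics()] for the same tracks.
#' @param contactFactor contact distance in units of summed radii
#'   (default 1.2).
#' @param persistence minimum fraction of window frames in contact
#'   (default 0.75).
#' @param windowH,frameIntervalH the analysis window definition.
#' @return `metrics` with the `mode` column filled
#'   (single / cluster / not_migratory).
#' @export
classifyMode <- function(tracks, metrics, contactFactor = 1.2,
                         persistence = 0.75, windowH = 4, frameIntervalH = 1) {
  nWin <- as.integer(round(windowH / frameIntervalH))
  metrics$mode <- ifelse(metrics$migratory, "single", "not_migratory")
  migIds <- metrics$track_id[metrics$migratory]
  if (length(migIds) < 2L) return(metrics)
  pos <- lapply(migIds, function(id) {
    d <- tracks[tracks$track_id == id, ]
    d <- d[order(d$frame), ][seq_len(min(nrow(d), nWin + 1L)), ]
    d
  })
  names(pos) <- as.character(migIds)
  radii <- metrics$diameter_um[match(migIds, metrics$track_id)] / 2
  isCluster <- setNames(rep(FALSE, length(migIds)), as.character(migIds))
  for (i in seq_along(migIds)) {
    for (j in seq_along(migIds)) {
      if (j <= i) next
      a <- pos[[i]]; b <- pos[[j]]
      common <- intersect(a$frame, b$frame)
      if (length(common) == 0L) next
      pa <- a[match(common, a$frame), ]
      pb <- b[match(common, b$frame), ]
      dd <- sqrt((pa$x_um - pb$x_um)^2 + (pa$y_um - pb$y_um)^2)
      inContact <- dd <= contactFactor * (radii[i] + radii[j])
      if (sum(inContact) / (nWin + 1L) >= persistence) {
        isCluster[i] <- TRUE; isCluster[j] <- TRUE
      }
    }
  }
  clusterIds <- migIds[isCluster]
  metrics$mode[metrics$track_id %in% clusterIds] <- "cluster"
  metrics
}

#' Aggregate migration metrics per animal and across animals
#'
#' The unit of analysis is the animal: per-animal fractions (of migratory
#' cells that are Lgr5-negative, and single versus cluster mode) are computed
#' over that animal's migratory tracks, and the group summary is the mean and
#' SEM of the animal-level fractions — not a pool over cells. Animals without
#' migratory tracks are excluded from the fractions and recorded in the
#' `excluded` attribute.
#'
#' @param metrics a metrics data.frame (from [computeTrackMetrics()] /
#'   [classifyMode()]) with an `animal_id` column.
#' @return A list with `perAnimal` (animal_id, n_migratory, fraction_lgr5neg,
#'   fraction_single, fraction_cluster) and `group` (mean and SEM across
#'   animals for each fraction, plus animal count).
#' @export
aggregateByAnimal <- function(metrics) {
  if (is.null(metrics$animal_id) || all(is.na(metrics$animal_id))) {
    stop("aggregateByAnimal: metrics must carry animal_id labels")
  }
  mig <- metrics[metrics$migratory, ]
  allAnimals <- unique(metrics$animal_id)
  perAnimal <- do.call(rbind, lapply(split(mig, mig$animal_id), function(d) {
    data.frame(animal_id = d$animal_id[1], n_migratory = nrow(d),
               fraction_lgr5neg = mean(!d$lgr5),
               fraction_single = mean(d$mode == "single"),
               fraction_cluster = mean(d$mode == "cluster"))
  }))
  rownames(perAnimal) <- NULL
  excluded <- setdiff(allAnimals, perAnimal$animal_id)
  groupRow <- function(name, v) {
    data.frame(metric = name, mean = mean(v),
               sem = if (length(v) >= 2L) sem(v) else NA_real_,
               n_animals = length(v))
  }
  group <- rbind(groupRow("fraction_lgr5neg", perAnimal$fraction_lgr5neg),
                 groupRow("fraction_single", perAnimal$fraction_single),
                 groupRow("fraction_cluster", perAnimal$fraction_cluster))
  structure(list(perAnimal = perAnimal, group = group), excluded = excluded)
}
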