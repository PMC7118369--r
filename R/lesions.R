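#' Score metastatic lesions from a two-channel section image
#'
#' Lesions are connected components of the RFP channel above threshold with
#' an area of at least one cell of mean diameter (configurable). Each lesion
#' is summarized by its equivalent-circle diameter, 2 x sqrt(area / pi), and
#' is called Lgr5-containing when at least `minGfpPixels` GFP-positive pixels
#' fall inside the component (a small minimum rejects shot noise).
#'
#' @param rfp,gfp numeric matrices (registered/overlaid section channels).
#' @param pixelSizeUm micrometres per pixel; required.
#' @param rfpThreshold,gfpThreshold fixed intensity thresholds or `"otsu"`
#'   (computed from the pixel intensity distribution of the channel).
#' @param minAreaUm2 minimum lesion area; default the area of one cell of
#'   `cellDiameterMeanUm`.
#' @param cellDiameterMeanUm mean cell diameter used for the default minimum
#'   area (default 15 um).
#' @param minGfpPixels minimum count of GFP-positive pixels for
#'   `contains_lgr5` (default 5).
#' @return A data.frame with one row per lesion: `lesion_id`, `diameter_um`,
#'   `contains_lgr5`, `area_um2`, `n_gfp_pixels`.
#' @export
scoreLesionImage <- function(rfp, gfp, pixelSizeUm, rfpThreshold = "otsu",
                             gfpThreshold = "otsu", minAreaUm2 = NULL,
                             cellDiameterMeanUm = 15, minGfpPixels = 5L) {
  if (missing(pixelSizeUm) || is.null(pixelSizeUm) || !is.finite(pixelSizeUm) ||
      pixelSizeUm <= 0) {
    stop("scoreLesionImage: pixel size is required and must be positive")
  }
  stopifnot(identical(dim(rfp), dim(gfp)))
  if (is.null(minAreaUm2)) minAreaUm2 <- pi * (cellDiameterMeanUm / 2)^2
  empty <- data.frame(lesion_id = integer(), diameter_um = numeric(),
                      contains_lgr5 = logical(), area_um2 = numeric(),
                      n_gfp_pixels = integer())
  if (identical(rfpThreshold, "otsu")) {
    if (length(unique(as.numeric(rfp))) < 2L) return(empty)
    rfpThreshold <- .otsu1d(as.numeric(rfp))
  }
  if (identical(gfpThreshold, "otsu")) {
    gfpThreshold <- if (length(unique(as.numeric(gfp))) < 2L) Inf
                    else .otsu1d(as.numeric(gfp))
  }
  bw <- matrix(as.numeric(rfp > rfpThreshold), nrow(rfp))
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bw)))
  nLab <- max(lab)
  if (nLab == 0L) return(empty)
  areasPx <- tabulate(lab[lab > 0], nbins = nLab)
  gfpPos <- gfp > gfpThreshold
  nGfp <- vapply(seq_len(nLab),
                 function(l) sum(gfpPos[lab == l]), numeric(1))
  areaUm2 <- areasPx * pixelSizeUm^2
  keep <- which(areaUm2 >= minAreaUm2)
  if (length(keep) == 0L) return(empty)
  data.frame(lesion_id = seq_along(keep),
             diameter_um = 2 * sqrt(areaUm2[keep] / pi),
             contains_lgr5 = nGfp[keep] >= minGfpPixels,
             area_um2 = areaUm2[keep],
             n_gfp_pixels = as.integer(nGfp[keep]))
}

#' Bin lesions by diameter and summarize Lgr5 composition per bin
#'
#' Bins are half-open intervals \[lo, hi) over strictly increasing edges.
#' Every lesion lands in exactly one bin; lesions outside all bins are
#' counted in an `overflow` row and flagged with a message. Within each
#' non-empty bin the fractions of Lgr5-negative-only lesions and of lesions
#' containing Lgr5-positive cells sum to 1.
#'
#' @param lesions a data.frame with `diameter_um` and `contains_lgr5`.
#' @param binEdgesUm strictly increasing edges; default
#'   `c(0, 20, 40, 80, 160, 320, Inf)`, chosen to straddle the 80-um
#'   plasticity threshold.
#' @return A data.frame with `bin_lo_um`, `bin_hi_um`, `n`,
#'   `n_lgr5neg_only`, `n_contains_lgr5`, `frac_lgr5neg_only`,
#'   `frac_contains_lgr5` (fractions NA for empty bins), plus an overflow
#'   row when needed.
#' @export
binComposition <- function(lesions, binEdgesUm = c(0, 20, 40, 80, 160, 320, Inf)) {
  if (any(diff(binEdgesUm) <= 0)) {
    stop("binComposition: bin edges must be strictly increasing")
  }
  d <- lesions$diameter_um
  idx <- findInterval(d, binEdgesUm)                    # [lo, hi)
  idx[idx == length(binEdgesUm) & d > binEdgesUm[length(binEdgesUm)]] <- 0L
  inBin <- idx >= 1L & idx < length(binEdgesUm)
  nBins <- length(binEdgesUm) - 1L
  rows <- lapply(seq_len(nBins), function(b) {
    sel <- inBin & idx == b
    n <- sum(sel)
    nPos <- sum(lesions$contains_lgr5[sel])
    data.frame(bin_lo_um = binEdgesUm[b], bin_hi_um = binEdgesUm[b + 1L],
               n = n, n_lgr5neg_only = n - nPos, n_contains_lgr5 = nPos,
               frac_lgr5neg_only = if (n) (n - nPos) / n else NA_real_,
               frac_contains_lgr5 = if (n) nPos / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  nOver <- sum(!inBin)
  if (nOver > 0L) {
    message(sprintf("binComposition: %d lesion(s) outside all bins counted as overflow", nOver))
    nPos <- sum(lesions$contains_lgr5[!inBin])
    out <- rbind(out, data.frame(
      bin_lo_um = NA_real_, bin_hi_um = NA_real_, n = nOver,
      n_lgr5neg_only = nOver - nPos, n_contains_lgr5 = nPos,
      frac_lgr5neg_only = (nOver - nPos) / nOver,
      frac_contains_lgr5 = nPos / nOver))
  }
  out
}

#' Recover the plasticity threshold from a lesion table
#'
#' Finds the smallest diameter D in the observed set such that every lesion
#' strictly larger than D contains Lgr5-positive cells — the empirical
#' counterpart of the observation that all lesions above a critical size
#' harbor Lgr5-positive stem cells. Returns no threshold (`NA`) when the
#' largest lesion is itself Lgr5-negative-only.
#'
#' @param lesions a data.frame with `diameter_um` and `contains_lgr5`; must
#'   have at least one row.
#' @return A list with `dStarUm` (the threshold, or `NA`), `nAbove` (lesions
#'   strictly above it) and `nViolationsAbove` (Lgr5-negative-only lesions
#'   above it; 0 by construction when a threshold exists).
#' @export
plasticityThreshold <- function(lesions) {
  if (nrow(lesions) == 0L) stop("plasticityThreshold: empty lesion table")
  d <- lesions$diameter_um
  neg <- !lesions$contains_lgr5
  if (!any(neg)) {
    dStar <- min(d)
  } else if (max(d[neg]) >= max(d)) {
    return(list(dStarUm = NA_real_, nAbove = 0L, nViolationsAbove = 0L))
  } else {
    dStar <- max(d[neg])
  }
  above <- d > dStar
  list(dStarUm = dStar, nAbove = sum(above),
       nViolationsAbove = sum(neg & above))
}
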