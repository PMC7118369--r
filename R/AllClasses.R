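#' MovieStack: a two-channel intravital time-lapse movie
#'
#' Container for a T-frame, two-channel 2D intensity movie. The RFP channel
#' carries the constitutive lineage label present in all tumor cells (used for
#' registration and detection); the GFP channel carries the Lgr5 reporter
#' present only in the stem-cell subset (used for classification). Intensities
#' are integer counts in the acquisition bit-depth range (12 bit by default).
#'
#' Arrays are indexed \code{[row, col, frame]}; x is the column index
#' increasing rightward, y the row index increasing downward, with the origin
#' at the center of the top-left pixel, so \code{x_um = (col - 1) * pixelSize}.
#'
#' @slot rfp numeric array (rows x cols x frames), RFP channel counts.
#' @slot gfp numeric array with identical dimensions, GFP channel counts.
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot frameIntervalH hours between consecutive frames (> 0).
#' @slot bitDepth acquisition bit depth; intensities lie in
#'   \code{[0, 2^bitDepth - 1]}.
#'
#' @seealso [MovieStack()] constructor, [registerMovie()], [detectMovie()]
#' @export
setClass("MovieStack",
  slots = c(
    rfp = "array",
    gfp = "array",
    pixelSizeUm = "numeric",
    frameIntervalH = "numeric",
    bitDepth = "integer"
  )
)

setValidity("MovieStack", function(object) {
  msg <- character()
  if (length(dim(object@rfp)) != 3L) {
    msg <- c(msg, "rfp must be a 3D array (rows x cols x frames)")
  }
  if (!identical(dim(object@rfp), dim(object@gfp))) {
    msg <- c(msg, "rfp and gfp dimensions differ")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) {
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  }
  if (length(object@frameIntervalH) != 1L || !is.finite(object@frameIntervalH) ||
      object@frameIntervalH <= 0) {
    msg <- c(msg, "frameIntervalH must be a single positive number")
  }
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L) {
    msg <- c(msg, "bitDepth must be a single positive integer")
  }
  maxVal <- 2^object@bitDepth - 1
  if (length(msg) == 0L) {
    rng <- range(object@rfp, object@gfp)
    if (rng[1] < 0 || rng[2] > maxVal) {
      msg <- c(msg, sprintf("intensities must lie in [0, %d]", maxVal))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MovieStack
#'
#' @param rfp,gfp numeric arrays (rows x cols x frames) of channel counts.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalH hours between frames.
#' @param bitDepth acquisition bit depth (default 12).
#' @return A [MovieStack-class] object.
#' @examples
#' m <- MovieStack(array(0, c(32, 32, 2)), array(0, c(32, 32, 2)),
#'                 pixelSizeUm = 1, frameIntervalH = 1)
#' nFrames(m)
#' @export
MovieStack <- function(rfp, gfp, pixelSizeUm, frameIntervalH, bitDepth = 12L) {
  methods::new("MovieStack",
    rfp = rfp, gfp = gfp,
    pixelSizeUm = as.numeric(pixelSizeUm),
    frameIntervalH = as.numeric(frameIntervalH),
    bitDepth = as.integer(bitDepth)
  )
}

#' ShiftSeries: per-frame rigid XY corrections for a movie
#'
#' The translation \code{(dx, dy)} recorded for frame t is the shift applied
#' to the raw frame to produce the corrected frame (x = columns rightward,
#' y = rows downward). Frame 1 is the reference and always carries (0, 0).
#'
#' @slot shifts integer matrix (frames x 2), columns dx_px and dy_px.
#' @slot converged logical per frame; FALSE when the greedy search hit its
#'   step budget or the overlap was degenerate.
#' @slot rFinal Pearson correlation with frame 1 at the accepted shift
#'   (1 for the reference frame itself).
#' @export
setClass("ShiftSeries",
  slots = c(
    shifts = "matrix",
    converged = "logical",
    rFinal = "numeric"
  )
)

setValidity("ShiftSeries", function(object) {
  msg <- character()
  s <- object@shifts
  if (ncol(s) != 2L) msg <- c(msg, "shifts must have two columns (dx, dy)")
  if (nrow(s) >= 1L && any(s[1L, ] != 0)) {
    msg <- c(msg, "reference frame shift must be (0, 0)")
  }
  if (any(s != round(s))) msg <- c(msg, "shifts must be integer pixels")
  if (length(object@converged) != nrow(s) || length(object@rFinal) != nrow(s)) {
    msg <- c(msg, "converged and rFinal must have one entry per frame")
  }
  ok <- is.na(object@rFinal) | (object@rFinal >= -1 & object@rFinal <= 1)
  if (!all(ok)) msg <- c(msg, "rFinal must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ShiftSeries
#'
#' @param shifts integer matrix (frames x 2) of (dx, dy) pixel shifts.
#' @param converged logical vector, one entry per frame.
#' @param rFinal numeric vector of final correlations, one per frame.
#' @return A [ShiftSeries-class] object.
#' @export
ShiftSeries <- function(shifts, converged, rFinal) {
  shifts <- matrix(as.integer(round(shifts)), ncol = 2L,
                   dimnames = list(NULL, c("dx_px", "dy_px")))
  methods::new("ShiftSeries", shifts = shifts,
               converged = as.logical(converged), rFinal = as.numeric(rFinal))
}

#' TestResult: outcome of a two-sample or paired test
#'
#' @slot method test name.
#' @slot statistic test statistic (t or U).
#' @slot df degrees of freedom where defined, otherwise NA.
#' @slot pValue two-sided p value in [0, 1] (NA when undefined).
#' @slot n1,n2 sample sizes.
#' @slot degenerate TRUE when a zero-variance guard fired and the reported
#'   statistic/p are boundary values rather than formula outputs.
#' @export
setClass("TestResult",
  slots = c(
    method = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    n1 = "integer",
    n2 = "integer",
    degenerate = "logical"
  )
)

setValidity("TestResult", function(object) {
  msg <- character()
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@n1 < 1L || object@n2 < 1L) msg <- c(msg, "n1, n2 must be >= 1")
  if (length(msg)) msg else TRUE
})

TestResult <- function(method, statistic, df = NA_real_, pValue, n1, n2,
                       degenerate = FALSE) {
  methods::new("TestResult", method = method, statistic = as.numeric(statistic),
               df = as.numeric(df), pValue = as.numeric(pValue),
               n1 = as.integer(n1), n2 = as.integer(n2),
               degenerate = isTRUE(degenerate))
}
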