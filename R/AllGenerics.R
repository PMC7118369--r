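#' @name MovieStack-accessors
#' @title Accessors for MovieStack and ShiftSeries objects
#' @description Slot access for the movie and shift containers goes through
#'   these accessors; user code should not reach into slots directly.
#' @param object a [MovieStack-class] or [ShiftSeries-class] object.
#' @param channel `"rfp"` or `"gfp"`.
#' @param frame 1-based frame index; `NULL` returns the full channel array.
NULL

#' @rdname MovieStack-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("getChannel", function(object, channel = c("rfp", "gfp"),
                                  frame = NULL) standardGeneric("getChannel"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("shifts", function(object) standardGeneric("shifts"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname MovieStack-accessors
#' @export
setGeneric("finalCorrelation",
           function(object) standardGeneric("finalCorrelation"))

#' @rdname MovieStack-accessors
#' @export
setMethod("nFrames", "MovieStack", function(object) dim(object@rfp)[3L])

#' @rdname MovieStack-accessors
#' @export
setMethod("pixelSize", "MovieStack", function(object) object@pixelSizeUm)

#' @rdname MovieStack-accessors
#' @export
setMethod("frameInterval", "MovieStack", function(object) object@frameIntervalH)

#' @rdname MovieStack-accessors
#' @export
setMethod("bitDepth", "MovieStack", function(object) object@bitDepth)

#' @rdname MovieStack-accessors
#' @export
setMethod("getChannel", "MovieStack", function(object,
                                               channel = c("rfp", "gfp"),
                                               frame = NULL) {
  channel <- match.arg(channel)
  arr <- if (channel == "rfp") object@rfp else object@gfp
  if (is.null(frame)) arr else arr[, , frame]
})

#' @rdname MovieStack-accessors
#' @export
setMethod("shifts", "ShiftSeries", function(object) object@shifts)

#' @rdname MovieStack-accessors
#' @export
setMethod("converged", "ShiftSeries", function(object) object@converged)

#' @rdname MovieStack-accessors
#' @export
setMethod("finalCorrelation", "ShiftSeries", function(object) object@rFinal)

#' @rdname MovieStack-accessors
#' @export
setMethod("nFrames", "ShiftSeries", function(object) nrow(object@shifts))

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@rfp)
  cat(sprintf(
    "MovieStack: %d x %d px, %d frames, 2 channels (rfp, gfp)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.3g um, frame interval %.3g h, %d-bit\n",
              object@pixelSizeUm, object@frameIntervalH, object@bitDepth))
  invisible(object)
})

setMethod("show", "ShiftSeries", function(object) {
  n <- nrow(object@shifts)
  cat(sprintf("ShiftSeries: %d frames, %d converged\n",
              n, sum(object@converged)))
  rng <- apply(abs(object@shifts), 2, max)
  cat(sprintf("  max |dx| = %d px, max |dy| = %d px, min r = %.4f\n",
              rng[1], rng[2], suppressWarnings(min(object@rFinal, na.rm = TRUE))))
  invisible(object)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n", object@method))
  cat(sprintf("  statistic = %.6g", object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %.4g", object@df))
  cat(sprintf(", p (two-sided) = %.6g, n = %d/%d\n",
              object@pValue, object@n1, object@n2))
  if (object@degenerate) cat("  [degenerate: zero-variance guard applied]\n")
  invisible(object)
})

#' @rdname MovieStack-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname MovieStack-accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname MovieStack-accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))

#' @rdname MovieStack-accessors
#' @export
setMethod("statistic", "TestResult", function(object) object@statistic)
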