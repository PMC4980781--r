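#' @import methods
#' @importFrom stats dnorm quantile rnorm runif rpois sd
NULL

## Frames are stored as plain numeric matrices in (row, col) order, 0-based
## time indexing at the sequence level. All intensities are promoted to
## double on read; PDE stages require fractional values.

#' FrameSequence: a time-ordered stack of 2D grayscale frames
#'
#' Container for a fluorescence time-lapse sequence. All frames share one
#' shape; intensities are stored as doubles regardless of the source bit
#' depth. The global intensity extrema over the whole sequence are cached
#' because the standardization stage anchors its affine rescaling to them.
#'
#' @slot frames list of numeric matrices, one per time point, identical dims
#' @slot bitDepth integer, 8 or 16, bit depth of the source data
#' @slot globalMin,globalMax numeric, intensity extrema over all frames
#'
#' @seealso [readFrameSequence()], [frameSequence()]
#' @export
setClass("FrameSequence",
  representation(
    frames    = "list",
    bitDepth  = "integer",
    globalMin = "numeric",
    globalMax = "numeric"
  )
)

setValidity("FrameSequence", function(object) {
  if (length(object@frames) == 0L)
    return("sequence must contain at least one frame")
  dims <- vapply(object@frames, dim, integer(2))
  if (!all(dims == dims[, 1L]))
    return("inconsistent frame shapes")
  if (any(dims < 3L))
    return("frames must be at least 3x3 (diffusion stencil needs interior pixels)")
  px <- unlist(object@frames, use.names = FALSE)
  if (!all(is.finite(px)))
    return("all intensities must be finite")
  if (any(px < 0))
    return("all intensities must be nonnegative")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (object@globalMax <= object@globalMin)
    return("globalMax must exceed globalMin (constant sequence)")
  if (abs(object@globalMin - min(px)) > 1e-9 ||
      abs(object@globalMax - max(px)) > 1e-9)
    return("globalMin/globalMax do not match frame contents")
  TRUE
})

#' FrameTriplet: three consecutive frames around a time point
#'
#' Sliding window \{t-1, t, t+1\} consumed by the coupled spatio-temporal
#' diffusion solver. At the ends of a sequence the missing neighbour is
#' replicated from the centre frame and flagged, the temporal analogue of
#' zero-gradient spatial padding.
#'
#' @slot prev,center,nxt numeric matrices of identical dims
#' @slot paddedPrev,paddedNext logical, TRUE when the neighbour was
#'   replicated at a sequence boundary
#' @slot frameIndex integer, 0-based time index of the centre frame
#' @export
setClass("FrameTriplet",
  representation(
    prev       = "matrix",
    center     = "matrix",
    nxt        = "matrix",
    paddedPrev = "logical",
    paddedNext = "logical",
    frameIndex = "integer"
  )
)

setValidity("FrameTriplet", function(object) {
  d <- dim(object@center)
  if (!identical(dim(object@prev), d) || !identical(dim(object@nxt), d))
    return("prev/center/nxt must share the same shape")
  if (object@paddedPrev && object@paddedNext && object@frameIndex != 0L &&
      FALSE) return("unreachable")
  TRUE
})

#' StandardizationModel: global background-intensity reference
#'
#' Learned in a training pass over all frames: the pooled empirical CDF,
#' the reference background threshold intensity and its cumulative
#' probability, plus the global extrema used by the affine rescaling.
#'
#' @slot iRef reference background-threshold intensity (raw scale)
#' @slot fRef cumulative probability of the pooled CDF at `iRef`
#' @slot gMin,gMax global sequence extrema
#' @slot nBins number of histogram bins (256 by default)
#' @slot cdf list with `binEdges`, `binMids`, `cdf` of the pooled histogram
#' @seealso [learnStandardization()], [standardizeTriplet()]
#' @export
setClass("StandardizationModel",
  representation(
    iRef  = "numeric",
    fRef  = "numeric",
    gMin  = "numeric",
    gMax  = "numeric",
    nBins = "integer",
    cdf   = "list"
  )
)

setValidity("StandardizationModel", function(object) {
  if (object@iRef < object@gMin || object@iRef > object@gMax)
    return("iRef must lie within [gMin, gMax]")
  if (object@fRef < 0 || object@fRef > 1)
    return("fRef must lie in [0, 1]")
  if (object@nBins < 2L)
    return("nBins must be >= 2")
  TRUE
})

#' EdgeMap: per-pixel edge-occurrence index
#'
#' Stochastic map in \[0, 1\] derived from Parzen density estimation of
#' local intensity windows; 1 marks the strongest edge evidence (most
#' bimodal local distribution). Serves as the topographic surface whose
#' inversion is flooded by the watershed transform.
#'
#' @slot values numeric matrix in \[0,1\], same shape as the source frame
#' @slot h Parzen kernel bandwidth used
#' @slot window odd window side length used
#' @seealso [edgeIndexMap()], [watershedRegions()]
#' @export
setClass("EdgeMap",
  representation(
    values = "matrix",
    h      = "numeric",
    window = "integer"
  )
)

setValidity("EdgeMap", function(object) {
  v <- object@values
  if (!all(is.finite(v))) return("edge indices must be finite")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
    return("edge indices must lie in [0, 1]")
  if (object@h <= 0) return("bandwidth h must be positive")
  if (object@window < 3L || object@window %% 2L == 0L)
    return("window must be odd and >= 3")
  TRUE
})

#' LevelSetField: signed level-set function over a frame
#'
#' The zero level set of `phi` is the cell boundary; the foreground is
#' \{phi >= 0\}. Carries the iteration count at convergence (used by the
#' temporal-linking warm start) and the per-iteration energy trace.
#'
#' @slot phi numeric matrix, finite signed field
#' @slot iFinal integer, iterations run until convergence
#' @slot energyTrace numeric vector of per-iteration energies
#' @seealso [cvEvolve()], [tcvSequence()]
#' @export
setClass("LevelSetField",
  representation(
    phi         = "matrix",
    iFinal      = "integer",
    energyTrace = "numeric"
  )
)

setValidity("LevelSetField", function(object) {
  if (!all(is.finite(object@phi))) return("phi must be finite everywhere")
  if (object@iFinal < 0L) return("iFinal must be nonnegative")
  TRUE
})
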