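#' @describeIn FrameSequence-class list of frame matrices
#' @export
setMethod("frames", "FrameSequence", function(object) object@frames)

#' @describeIn FrameSequence-class number of frames
#' @export
setMethod("nFrames", "FrameSequence", function(object) length(object@frames))

#' @describeIn FrameSequence-class c(rows, cols) of every frame
#' @export
setMethod("frameDims", "FrameSequence", function(object) dim(object@frames[[1L]]))

#' @describeIn FrameSequence-class c(globalMin, globalMax) over all frames
#' @export
setMethod("globalRange", "FrameSequence",
          function(object) c(object@globalMin, object@globalMax))

#' @describeIn FrameSequence-class extract one frame matrix (1-based index)
#' @export
setMethod("frameAt", "FrameSequence", function(x, i) {
  if (i < 1L || i > length(x@frames))
    stop("frame index out of range")
  x@frames[[i]]
})

setMethod("show", "FrameSequence", function(object) {
  d <- frameDims(object)
  cat(sprintf("FrameSequence: %d frame(s) of %dx%d (%d-bit)\n",
              nFrames(object), d[1L], d[2L], object@bitDepth))
  cat(sprintf("  global intensity range: [%g, %g]\n",
              object@globalMin, object@globalMax))
})

#' @describeIn EdgeMap-class matrix of edge indices in [0,1]
#' @export
setMethod("values2d", "EdgeMap", function(object) object@values)

setMethod("show", "EdgeMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("EdgeMap: %dx%d, h = %g, window = %d, max index = %.3f\n",
              d[1L], d[2L], object@h, object@window, max(object@values)))
})

#' @describeIn LevelSetField-class the signed field matrix
#' @export
setMethod("phi", "LevelSetField", function(object) object@phi)

#' @describeIn LevelSetField-class iterations run until convergence
#' @export
setMethod("iFinal", "LevelSetField", function(object) object@iFinal)

#' @describeIn LevelSetField-class per-iteration energy values
#' @export
setMethod("energyTrace", "LevelSetField", function(object) object@energyTrace)

#' @describeIn LevelSetField-class logical foreground mask \{phi >= 0\}
#' @export
setMethod("levelSetMask", "LevelSetField", function(object) object@phi >= 0)

setMethod("show", "LevelSetField", function(object) {
  d <- dim(object@phi)
  cat(sprintf("LevelSetField: %dx%d, iFinal = %d, foreground = %d px\n",
              d[1L], d[2L], object@iFinal, sum(object@phi >= 0)))
})

setMethod("show", "StandardizationModel", function(object) {
  cat(sprintf(paste0("StandardizationModel: iRef = %g (F = %.4f), ",
                     "global range [%g, %g], %d bins\n"),
              object@iRef, object@fRef, object@gMin, object@gMax,
              object@nBins))
})

setMethod("show", "FrameTriplet", function(object) {
  d <- dim(object@center)
  pad <- c(if (object@paddedPrev) "prev replicated",
           if (object@paddedNext) "next replicated")
  cat(sprintf("FrameTriplet: centre index %d, %dx%d%s\n",
              object@frameIndex, d[1L], d[2L],
              if (length(pad)) paste0(" (", paste(pad, collapse = ", "), ")")
              else ""))
})
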