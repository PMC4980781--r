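#' @rdname FrameSequence-class
#' @param object a `FrameSequence` (or other object)
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frameDims", function(object) standardGeneric("frameDims"))

#' @rdname FrameSequence-class
#' @export
setGeneric("globalRange", function(object) standardGeneric("globalRange"))

#' @rdname FrameSequence-class
#' @param x a `FrameSequence`
#' @param i frame position (1-based)
#' @export
setGeneric("frameAt", function(x, i) standardGeneric("frameAt"))

#' @rdname EdgeMap-class
#' @param object object with a pixel-value payload
#' @export
setGeneric("values2d", function(object) standardGeneric("values2d"))

#' @rdname LevelSetField-class
#' @param object a `LevelSetField`
#' @export
setGeneric("phi", function(object) standardGeneric("phi"))

#' @rdname LevelSetField-class
#' @export
setGeneric("iFinal", function(object) standardGeneric("iFinal"))

#' @rdname LevelSetField-class
#' @export
setGeneric("energyTrace", function(object) standardGeneric("energyTrace"))

#' @rdname LevelSetField-class
#' @export
setGeneric("levelSetMask", function(object) standardGeneric("levelSetMask"))
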