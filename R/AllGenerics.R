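#' @rdname VoltageMovie-class
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname VoltageMovie-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname VoltageMovie-class
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname VoltageMovie-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname VoltageMovie-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname VoltageMovie-class
#' @export
setGeneric("frameDims", function(x) standardGeneric("frameDims"))

#' @rdname PhaseMovie-class
#' @export
setGeneric("phaseData", function(x) standardGeneric("phaseData"))

#' @rdname PhaseMovie-class
#' @export
setGeneric("amplitudeData", function(x) standardGeneric("amplitudeData"))

#' @rdname PhaseMovie-class
#' @export
setGeneric("reliability", function(x) standardGeneric("reliability"))

#' @rdname PhaseVelocityField-class
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' @rdname PhaseVelocityField-class
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname SVDModeSet-class
#' @export
setGeneric("modeFields", function(x) standardGeneric("modeFields"))

#' @rdname SVDModeSet-class
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname SVDModeSet-class
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' @rdname SVDModeSet-class
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
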