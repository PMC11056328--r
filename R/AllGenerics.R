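#' @rdname VelocityField4D-class
#' @param x,object a \linkS4class{VelocityField4D} (or other container where
#'   noted).
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("velocityArray", function(x) standardGeneric("velocityArray"))

#' @rdname VelocityField4D-class
#' @export
setGeneric("phaseDuration", function(x) standardGeneric("phaseDuration"))

#' Average a velocity field over cardiac phases
#'
#' Returns a single-phase \linkS4class{VelocityField4D} whose velocities are
#' the mean over phases (each phase has equal duration). Fontan caval flow is
#' quasi-steady, so the time-averaged field is the default substrate for
#' streamline tracing.
#'
#' @param x a \linkS4class{VelocityField4D}.
#' @return a single-phase \linkS4class{VelocityField4D}.
#' @export
setGeneric("timeAverage", function(x) standardGeneric("timeAverage"))

#' @rdname LumenMask-class
#' @param x a \linkS4class{LumenMask}.
#' @export
setGeneric("segmentNames", function(x) standardGeneric("segmentNames"))

#' @rdname LumenMask-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname StreamlineSet-class
#' @param x a \linkS4class{StreamlineSet}.
#' @export
setGeneric("distribution", function(x) standardGeneric("distribution"))

#' @rdname EnergeticsResult-class
#' @param x result object.
#' @export
setGeneric("keNorm", function(x) standardGeneric("keNorm"))

#' @rdname EnergeticsResult-class
#' @export
setGeneric("elNorm", function(x) standardGeneric("elNorm"))

#' @rdname EnergeticsResult-class
#' @export
setGeneric("elKeIndex", function(x) standardGeneric("elKeIndex"))

#' @rdname FlowResult-class
#' @param x a \linkS4class{FlowResult}.
#' @export
setGeneric("qNet", function(x) standardGeneric("qNet"))

#' @rdname FlowResult-class
#' @export
setGeneric("meanVelocity", function(x) standardGeneric("meanVelocity"))

#' @rdname FlowPhantom-class
#' @param x a \linkS4class{FlowPhantom}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
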