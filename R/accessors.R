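#' @rdname VelocityField4D-class
#' @aliases gridDim,VelocityField4D-method
setMethod("gridDim", "VelocityField4D",
          function(x) dim(x@velocities)[1:3])

#' @rdname VelocityField4D-class
setMethod("gridDim", "LumenMask", function(x) dim(x@labels))

#' @rdname VelocityField4D-class
setMethod("nPhases", "VelocityField4D",
          function(x) dim(x@velocities)[5])

#' @rdname VelocityField4D-class
setMethod("spacing", "VelocityField4D", function(x) x@spacing)

#' @rdname VelocityField4D-class
setMethod("spacing", "LumenMask", function(x) x@spacing)

#' @rdname VelocityField4D-class
setMethod("gridOrigin", "VelocityField4D", function(x) x@origin)

#' @rdname VelocityField4D-class
setMethod("gridOrigin", "LumenMask", function(x) x@origin)

#' @rdname VelocityField4D-class
setMethod("voxelVolumeMl", "VelocityField4D",
          function(x) prod(x@spacing) / 1000)

#' @rdname VelocityField4D-class
setMethod("voxelVolumeMl", "LumenMask",
          function(x) prod(x@spacing) / 1000)

#' @rdname VelocityField4D-class
setMethod("velocityArray", "VelocityField4D", function(x) x@velocities)

#' @rdname VelocityField4D-class
setMethod("phaseDuration", "VelocityField4D", function(x) x@phaseDuration)

#' @rdname timeAverage
setMethod("timeAverage", "VelocityField4D", function(x) {
  np <- nPhases(x)
  if (np == 1L) return(x)
  d <- dim(x@velocities)
  avg <- array(rowMeans(matrix(x@velocities, ncol = np)), dim = c(d[1:4], 1L))
  new("VelocityField4D", velocities = avg, spacing = x@spacing,
      origin = x@origin, phaseDuration = x@phaseDuration * np)
})

#' @rdname LumenMask-class
setMethod("segmentNames", "LumenMask", function(x) names(x@segments))

#' @rdname LumenMask-class
setMethod("maskArray", "LumenMask", function(x) x@labels)

#' @rdname StreamlineSet-class
setMethod("distribution", "StreamlineSet", function(x) x@distribution)

#' @rdname EnergeticsResult-class
setMethod("keNorm", "EnergeticsResult", function(x) x@keNorm)

#' @rdname EnergeticsResult-class
setMethod("elNorm", "EnergeticsResult", function(x) x@elNorm)

#' @rdname EnergeticsResult-class
setMethod("elKeIndex", "EnergeticsResult", function(x) x@elKeIndex)

#' @rdname FlowResult-class
setMethod("qNet", "FlowResult", function(x) x@qNet)

#' @rdname FlowResult-class
setMethod("meanVelocity", "FlowResult", function(x) x@meanVelocity)

#' @rdname FlowPhantom-class
setMethod("groundTruth", "FlowPhantom", function(x) x@truth)

setMethod("show", "VelocityField4D", function(object) {
  d <- gridDim(object)
  cat("VelocityField4D:", paste(d, collapse = " x "), "voxels,",
      nPhases(object), "phase(s)\n")
  cat("  spacing (mm): ", paste(format(spacing(object)), collapse = ", "),
      "; origin (mm): ", paste(format(gridOrigin(object)), collapse = ", "),
      "\n", sep = "")
  sp <- sqrt(apply(object@velocities^2, 5, function(a)
    max(rowSums(matrix(a, ncol = 3)^2))))
  cat("  peak speed (cm/s):", format(sqrt(max(sp)), digits = 4),
      "; phase duration (s):", format(object@phaseDuration), "\n")
})

setMethod("show", "LumenMask", function(object) {
  cat("LumenMask:", paste(gridDim(object), collapse = " x "), "voxels,",
      sum(object@labels > 0L), "lumen voxels\n")
  if (length(object@segments)) {
    cnt <- vapply(object@segments, function(id) sum(object@labels == id),
                  integer(1))
    cat("  segments:",
        paste(sprintf("%s(%d)", names(object@segments), cnt),
              collapse = ", "), "\n")
  }
})

setMethod("show", "AnalysisPlane", function(object) {
  cat(sprintf("AnalysisPlane '%s': origin (%s) mm, normal (%s), radius %g mm\n",
              object@vessel,
              paste(format(object@origin, digits = 4), collapse = ", "),
              paste(format(object@normal, digits = 3), collapse = ", "),
              object@radius))
})

setMethod("show", "FlowResult", function(object) {
  cat(sprintf("FlowResult '%s': qNet %.3f l/min", object@vessel, object@qNet))
  if (is.finite(object@qIndexed))
    cat(sprintf(" (%.3f l/min/m2)", object@qIndexed))
  cat(sprintf(", mean velocity %.1f cm/s, %d phase(s)\n",
              object@meanVelocity, length(object@perPhaseFlux)))
})

setMethod("show", "StreamlineSet", function(object) {
  cat(sprintf("StreamlineSet from '%s': %d lines (%s)\n", object@seedVessel,
              length(object@lines),
              paste(sprintf("%s %d", names(table(object@status)),
                            as.integer(table(object@status))),
                    collapse = ", ")))
  if (length(object@distribution)) {
    cat("  distribution (% of resolved):",
        paste(sprintf("%s %.1f", names(object@distribution),
                      object@distribution), collapse = ", "),
        sprintf("; unresolved %.1f%%\n", object@unresolvedPct))
  }
})

setMethod("show", "EnergeticsResult", function(object) {
  cat(sprintf(
    "EnergeticsResult: KE %.3g uJ/ml, EL %.3g uW/ml, EL/KE %.3g 1/s (VOI %.1f ml)\n",
    object@keNorm, object@elNorm, object@elKeIndex, object@voiVolume))
  if (object@nExcluded > 0L)
    cat("  ", object@nExcluded,
        "voxel(s) excluded from the EL integral (isolated on some axis)\n")
})

setMethod("show", "SectionShape", function(object) {
  cat(sprintf(
    "SectionShape '%s': WSS %.3g Pa, jet angle %.1f deg, eccentricity %.3f\n",
    object@vessel, object@wssMean, object@jetAngle, object@eccentricity))
})

setMethod("show", "DerivedCirculation", function(object) {
  cat(sprintf(
    "DerivedCirculation: QSPC %.3g l/min (%.3g l/min/m2), effective CI %.3g l/min/m2\n",
    object@qspc, object@qspcIndexed, object@effectiveCi))
  if (is.finite(object@rpaLpaRatio))
    cat(sprintf("  RPA/LPA ratio %.2f -> %s\n", object@rpaLpaRatio,
                object@asymmetryClass))
})

setMethod("show", "FlowPhantom", function(object) {
  cat(sprintf("FlowPhantom '%s': grid %s, %d plane(s), truth: %s\n",
              object@kind, paste(gridDim(object@field), collapse = " x "),
              length(object@planes),
              paste(names(object@truth), collapse = ", ")))
})

#' @rdname VolumeOfInterest-class
#' @param x a \linkS4class{VolumeOfInterest}.
#' @export
voiVolumeMl <- function(x) {
  stopifnot(is(x, "VolumeOfInterest"))
  x@volumeMl
}

setMethod("show", "VolumeOfInterest", function(object) {
  cat(sprintf("VolumeOfInterest: %d voxels, %.2f ml\n",
              length(object@indices), object@volumeMl))
})
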