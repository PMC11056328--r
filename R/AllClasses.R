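#' @import methods
NULL

#' Gridded 4D velocity field
#'
#' Container for a three-component velocity field sampled on a regular voxel
#' grid over one or more cardiac phases. Velocities are stored in cm/s (the
#' VENC convention of phase-contrast MRI); grid geometry is physical, in mm,
#' with voxel centers at \code{origin + (index - 1) * spacing} in a
#' right-handed frame.
#'
#' @slot velocities five-dimensional numeric array
#'   \code{[nx, ny, nz, component, phase]} with components ordered (x, y, z),
#'   in cm/s.
#' @slot spacing numeric(3), voxel size per axis in mm (strictly positive).
#' @slot origin numeric(3), physical coordinate of voxel (1,1,1) in mm.
#' @slot phaseDuration seconds per cardiac phase.
#'
#' @seealso [readVelocityField()], [poiseuillePhantom()], [planeFlux()]
#' @export
setClass("VelocityField4D",
  representation(
    velocities    = "array",
    spacing       = "numeric",
    origin        = "numeric",
    phaseDuration = "numeric"
  ),
  prototype(
    spacing       = c(1, 1, 1),
    origin        = c(0, 0, 0),
    phaseDuration = 1
  )
)

setValidity("VelocityField4D", function(object) {
  d <- dim(object@velocities)
  if (length(d) != 5L)
    return("'velocities' must be a 5-D array [nx, ny, nz, 3, nPhases]")
  if (d[4] != 3L)
    return("fourth dimension of 'velocities' must hold 3 components")
  if (d[5] < 1L)
    return("at least one cardiac phase is required")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be 3 finite values (mm)")
  if (length(object@phaseDuration) != 1L || !is.finite(object@phaseDuration) ||
      object@phaseDuration <= 0)
    return("'phaseDuration' must be a single positive value (s)")
  if (any(!is.finite(object@velocities)))
    return("velocity magnitudes must be finite")
  TRUE
})

#' Segmented lumen mask
#'
#' Integer label volume on the same grid as its [VelocityField4D]: 0 is
#' background, values >= 1 identify named vessel segments (e.g. SVC,
#' IVC_conduit, RPA, LPA, confluence).
#'
#' @slot labels 3-D integer array of segment labels.
#' @slot segments named integer vector mapping segment name -> label id.
#' @slot spacing,origin grid geometry in mm, as in [VelocityField4D].
#' @export
setClass("LumenMask",
  representation(
    labels   = "array",
    segments = "integer",
    spacing  = "numeric",
    origin   = "numeric"
  ),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("LumenMask", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("'labels' must be a 3-D array")
  if (length(object@segments) &&
      (is.null(names(object@segments)) || any(!nzchar(names(object@segments)))))
    return("'segments' must be a named integer vector (name -> id)")
  present <- unique(as.integer(object@labels))
  for (nm in names(object@segments)) {
    if (!(object@segments[[nm]] %in% present))
      return(sprintf("named segment '%s' has no voxels", nm))
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("'spacing' must be 3 strictly positive values (mm)")
  TRUE
})

#' Oriented analysis plane
#'
#' A cross-sectional disc through a vessel: measurement site for flux, jet
#' angle, eccentricity and wall shear stress. The normal is oriented in the
#' physiologic flow direction so that net flow is positive.
#'
#' @slot origin numeric(3), center of the disc (mm).
#' @slot normal numeric(3), unit normal.
#' @slot radius disc radius (mm), > 0.
#' @slot vessel vessel name.
#' @export
setClass("AnalysisPlane",
  representation(
    origin = "numeric",
    normal = "numeric",
    radius = "numeric",
    vessel = "character"
  ),
  prototype(vessel = "")
)

setValidity("AnalysisPlane", function(object) {
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be 3 finite values (mm)")
  if (length(object@normal) != 3L ||
      abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("'normal' must be a unit vector (||n|| = 1 within 1e-9)")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("'radius' must be a single positive value (mm)")
  TRUE
})

#' Volume of interest
#'
#' A subset of lumen voxels (stored as linear indices into the 3-D grid) over
#' which energetic quantities are integrated and volume-normalized.
#'
#' @slot indices integer vector of linear voxel indices.
#' @slot gridDim integer(3), dimensions of the parent grid.
#' @slot volumeMl total volume in ml (voxel count x voxel volume).
#' @export
setClass("VolumeOfInterest",
  representation(
    indices  = "integer",
    gridDim  = "integer",
    volumeMl = "numeric"
  )
)

setValidity("VolumeOfInterest", function(object) {
  n <- prod(object@gridDim)
  if (length(object@indices) &&
      (min(object@indices) < 1L || max(object@indices) > n))
    return("voxel indices out of grid range")
  if (anyDuplicated(object@indices))
    return("duplicated voxel indices")
  TRUE
})

#' Plane-based flow measurement
#'
#' @slot vessel vessel name.
#' @slot qNet net flow in l/min (phase-duration-weighted mean of the
#'   per-phase flux), signed along the plane normal.
#' @slot qIndexed qNet / BSA in l/min/m^2 (NA when no BSA was supplied).
#' @slot meanVelocity area-averaged |v . n| on the section, cm/s.
#' @slot perPhaseFlux numeric vector of per-phase flux in ml/s.
#' @slot areaCm2 sampled lumen section area, cm^2.
#' @export
setClass("FlowResult",
  representation(
    vessel       = "character",
    qNet         = "numeric",
    qIndexed     = "numeric",
    meanVelocity = "numeric",
    perPhaseFlux = "numeric",
    areaCm2      = "numeric"
  ),
  prototype(qIndexed = NA_real_)
)

setValidity("FlowResult", function(object) {
  if (length(object@perPhaseFlux) >= 1L && is.finite(object@qNet)) {
    lmin <- mean(object@perPhaseFlux) * 60 / 1000
    if (abs(lmin - object@qNet) > 1e-9 * max(1, abs(object@qNet)))
      return("qNet inconsistent with per-phase flux")
  }
  if (is.finite(object@meanVelocity) && object@meanVelocity < 0)
    return("meanVelocity must be >= 0")
  TRUE
})

#' Traced streamline set
#'
#' Pathlines integrated forward from a caval seed plane, with per-line
#' termination status, outlet labels (after [classifyOutlets()]) and the
#' percent distribution over resolved lines.
#'
#' @slot lines list of n x 3 matrices of points (mm); each line starts on the
#'   seed plane.
#' @slot seedVessel name of the seeding vessel.
#' @slot status character per line: "exited", "stalled" or "length_out".
#' @slot outletLabels character per line: an outlet segment name or
#'   "unresolved".
#' @slot distribution named numeric, percent of resolved lines per outlet
#'   (sums to 100 when any line resolved).
#' @slot unresolvedPct percent of all lines that did not resolve to an outlet.
#' @export
setClass("StreamlineSet",
  representation(
    lines         = "list",
    seedVessel    = "character",
    status        = "character",
    outletLabels  = "character",
    distribution  = "numeric",
    unresolvedPct = "numeric"
  ),
  prototype(distribution = numeric(0), unresolvedPct = NA_real_)
)

setValidity("StreamlineSet", function(object) {
  n <- length(object@lines)
  if (length(object@status) != n)
    return("'status' must have one entry per line")
  if (length(object@outletLabels) && length(object@outletLabels) != n)
    return("'outletLabels' must have one entry per line")
  if (length(object@distribution) &&
      abs(sum(object@distribution) - 100) > 1e-6)
    return("distribution percentages must sum to 100")
  TRUE
})

#' Volume-normalized flow energetics
#'
#' Kinetic energy and viscous energy loss integrated over a volume of
#' interest and normalized by its volume, with the EL/KE efficiency index.
#'
#' @slot keNorm volume-normalized kinetic energy, uJ/ml (cycle average).
#' @slot elNorm volume-normalized viscous energy loss, uW/ml (cycle average).
#' @slot elKeIndex elNorm / keNorm, 1/s (NA with flag when keNorm = 0).
#' @slot voiVolume volume of interest, ml.
#' @slot phaseProfile matrix with one row per phase, columns keNorm, elNorm.
#' @slot nExcluded number of voxels excluded from the energy-loss integral
#'   because a velocity gradient was undefined along some axis.
#' @export
setClass("EnergeticsResult",
  representation(
    keNorm       = "numeric",
    elNorm       = "numeric",
    elKeIndex    = "numeric",
    voiVolume    = "numeric",
    phaseProfile = "matrix",
    nExcluded    = "integer"
  ),
  prototype(keNorm = NA_real_, elNorm = NA_real_, elKeIndex = NA_real_,
            nExcluded = 0L)
)

setValidity("EnergeticsResult", function(object) {
  if (is.finite(object@keNorm) && object@keNorm < 0)
    return("keNorm must be >= 0")
  if (is.finite(object@elNorm) && object@elNorm < 0)
    return("elNorm must be >= 0")
  if (is.finite(object@keNorm) && object@keNorm > 0 &&
      is.finite(object@elNorm) && is.finite(object@elKeIndex)) {
    if (abs(object@elKeIndex - object@elNorm / object@keNorm) >
        1e-9 * max(1, abs(object@elKeIndex)))
      return("elKeIndex inconsistent with elNorm/keNorm")
  }
  TRUE
})

#' Sectional jet-shape metrics
#'
#' @slot wssMean sectional mean wall shear stress, Pa.
#' @slot jetAngle angle between the flux-weighted mean velocity and the plane
#'   normal, degrees in [0, 90].
#' @slot eccentricity displacement of the velocity-weighted flow centroid
#'   from the geometric lumen centroid, normalized by the equivalent lumen
#'   diameter; dimensionless in [0, 1].
#' @slot vessel vessel name.
#' @export
setClass("SectionShape",
  representation(
    wssMean      = "numeric",
    jetAngle     = "numeric",
    eccentricity = "numeric",
    vessel       = "character"
  ),
  prototype(vessel = "")
)

setValidity("SectionShape", function(object) {
  if (is.finite(object@jetAngle) &&
      (object@jetAngle < 0 || object@jetAngle > 90))
    return("jetAngle must lie in [0, 90] degrees")
  if (is.finite(object@eccentricity) &&
      (object@eccentricity < 0 || object@eccentricity > 1))
    return("eccentricity must lie in [0, 1]")
  TRUE
})

#' Derived circulation parameters
#'
#' Systemic-to-pulmonary collateral flow (QSPC), effective cardiac index and
#' pulmonary branch flow asymmetry.
#'
#' @slot qspc QSPC = (Q_LPV + Q_RPV) - (Q_RPA + Q_LPA), l/min.
#' @slot qspcIndexed QSPC / BSA, l/min/m^2.
#' @slot effectiveCi (Q_Ao - QSPC) / BSA, l/min/m^2.
#' @slot rpaLpaRatio Q_RPA / Q_LPA, dimensionless.
#' @slot asymmetryClass "rpa_dominant" (ratio > 1.56), "lpa_dominant"
#'   (ratio < 0.75) or "symmetric".
#' @export
setClass("DerivedCirculation",
  representation(
    qspc           = "numeric",
    qspcIndexed    = "numeric",
    effectiveCi    = "numeric",
    rpaLpaRatio    = "numeric",
    asymmetryClass = "character"
  ),
  prototype(qspc = NA_real_, qspcIndexed = NA_real_, effectiveCi = NA_real_,
            rpaLpaRatio = NA_real_, asymmetryClass = NA_character_)
)

setValidity("DerivedCirculation", function(object) {
  r <- object@rpaLpaRatio
  cl <- object@asymmetryClass
  if (is.finite(r) && !is.na(cl)) {
    expect <- if (r > 1.56) "rpa_dominant" else if (r < 0.75) "lpa_dominant"
              else "symmetric"
    if (cl != expect)
      return("asymmetryClass inconsistent with rpaLpaRatio thresholds")
  }
  TRUE
})

#' Analytic flow phantom
#'
#' A synthetic velocity field with its lumen mask, analysis planes and a
#' machine-readable ground-truth record for every quantity the downstream
#' estimators compute. The generator and the estimators share no code paths
#' for those quantities.
#'
#' @slot field a [VelocityField4D].
#' @slot mask a [LumenMask].
#' @slot planes named list of [AnalysisPlane] objects.
#' @slot truth named list of ground-truth values.
#' @slot kind phantom kind ("poiseuille_tube", "tilted_jet_tube",
#'   "tcpc_junction").
#' @export
setClass("FlowPhantom",
  representation(
    field  = "VelocityField4D",
    mask   = "LumenMask",
    planes = "list",
    truth  = "list",
    kind   = "character"
  )
)

setValidity("FlowPhantom", function(object) {
  if (!all(vapply(object@planes, is, logical(1), class2 = "AnalysisPlane")))
    return("'planes' must be a list of AnalysisPlane objects")
  if (!identical(dim(object@mask@labels),
                 dim(object@field@velocities)[1:3]))
    return("mask grid does not match field grid")
  TRUE
})
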