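## Grid geometry, constructors and trilinear sampling shared by the
## quantification stages. Physical frame: right-handed, mm, voxel centers at
## origin + (index - 1) * spacing.

#' Construct a VelocityField4D
#'
#' @param velocities numeric array; either \code{[nx, ny, nz, 3]} (single
#'   phase) or \code{[nx, ny, nz, 3, nPhases]}, in cm/s.
#' @param spacing voxel size per axis, mm.
#' @param origin physical coordinate of voxel (1,1,1), mm.
#' @param phaseDuration seconds per cardiac phase.
#' @return a \linkS4class{VelocityField4D}.
#' @export
velocityField4D <- function(velocities, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), phaseDuration = 1) {
  if (length(dim(velocities)) == 4L)
    dim(velocities) <- c(dim(velocities), 1L)
  new("VelocityField4D", velocities = velocities,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      phaseDuration = phaseDuration)
}

#' Construct a LumenMask
#'
#' @param labels 3-D integer array (0 = background).
#' @param segments named integer vector, segment name -> label id. Defaults
#'   to a single segment "lumen" = 1 when labels are binary.
#' @param spacing,origin grid geometry, mm.
#' @return a \linkS4class{LumenMask}.
#' @export
lumenMask <- function(labels, segments = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  if (is.null(segments)) {
    ids <- setdiff(sort(unique(as.integer(labels))), 0L)
    segments <- if (identical(ids, 1L)) c(lumen = 1L)
                else stats::setNames(ids, paste0("segment", ids))
  }
  new("LumenMask", labels = labels,
      segments = stats::setNames(as.integer(segments), names(segments)),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct an AnalysisPlane
#'
#' @param origin center of the disc, mm.
#' @param normal plane normal (normalized internally unless already unit
#'   within 1e-9; a zero vector is an error).
#' @param radius disc radius, mm.
#' @param vessel vessel name.
#' @return an \linkS4class{AnalysisPlane}.
#' @export
analysisPlane <- function(origin, normal, radius, vessel = "") {
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("argument error: plane normal must be non-zero")
  new("AnalysisPlane", origin = as.numeric(origin),
      normal = as.numeric(normal) / nrm, radius = radius, vessel = vessel)
}

#' Assemble a volume of interest from named mask segments
#'
#' Collects the voxels of the named segments, optionally clipped by
#' half-spaces (used to restrict the Fontan confluence to within a given
#' distance of the bifurcation, e.g. at planes 15 mm out on each limb).
#'
#' @param mask a \linkS4class{LumenMask}.
#' @param segments character vector of segment names; default all segments.
#' @param clipPlanes optional list of \linkS4class{AnalysisPlane}; voxels on
#'   the positive side of any clip normal (beyond the plane) are dropped.
#' @return a \linkS4class{VolumeOfInterest}.
#' @export
voiFromSegments <- function(mask, segments = segmentNames(mask),
                            clipPlanes = NULL) {
  missing <- setdiff(segments, segmentNames(mask))
  if (length(missing))
    stop("configuration error: segment(s) not in mask: ",
         paste(missing, collapse = ", "))
  ids <- mask@segments[segments]
  idx <- which(mask@labels %in% ids)
  if (length(clipPlanes)) {
    pts <- voxelCenters(mask, idx)
    keep <- rep(TRUE, length(idx))
    for (pl in clipPlanes) {
      d <- (pts - matrix(pl@origin, nrow(pts), 3, byrow = TRUE)) %*% pl@normal
      keep <- keep & (d <= 0)
    }
    idx <- idx[keep]
  }
  if (!length(idx)) stop("empty volume of interest")
  new("VolumeOfInterest", indices = as.integer(idx),
      gridDim = as.integer(gridDim(mask)),
      volumeMl = length(idx) * prod(mask@spacing) / 1000)
}

## physical coordinates (mm) of voxel centers for linear indices
voxelCenters <- function(grid, idx) {
  d <- gridDim(grid)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(grid@origin[1] + i * grid@spacing[1],
        grid@origin[2] + j * grid@spacing[2],
        grid@origin[3] + k * grid@spacing[3])
}

## nearest-voxel 1-based index matrix for physical points; NA outside grid
nearestVoxel <- function(grid, pts) {
  d <- gridDim(grid)
  ijk <- sweep(sweep(pts, 2, grid@origin, "-"), 2, grid@spacing, "/")
  ijk <- round(ijk) + 1
  bad <- ijk[, 1] < 1 | ijk[, 1] > d[1] | ijk[, 2] < 1 | ijk[, 2] > d[2] |
         ijk[, 3] < 1 | ijk[, 3] > d[3]
  ijk[bad, ] <- NA_real_
  ijk
}

## mask labels at physical points (nearest neighbor); 0 outside the grid
maskLabelAt <- function(mask, pts) {
  d <- gridDim(mask)
  ijk <- nearestVoxel(mask, pts)
  lab <- integer(nrow(pts))
  ok <- !is.na(ijk[, 1])
  if (any(ok)) {
    lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] + ijk[ok, 1]
    lab[ok] <- mask@labels[lin]
  }
  lab
}

## Vectorized trilinear interpolation of a 3-component volume at physical
## points. `comp` is [nx, ny, nz, 3]. Outside the voxel-center hull the
## field samples as zero ("zero") or as the nearest-edge value ("clamp";
## used by the streamline tracer so open limb ends do not read as an
## artificial zero-velocity layer).
trilinearVelocity <- function(comp, spacing, origin, pts,
                              extrapolate = c("zero", "clamp")) {
  extrapolate <- match.arg(extrapolate)
  d <- dim(comp)[1:3]
  out <- matrix(0, nrow(pts), 3)
  g <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
  inside <- if (extrapolate == "zero") {
    g[, 1] >= 1 & g[, 1] <= d[1] &
      g[, 2] >= 1 & g[, 2] <= d[2] &
      g[, 3] >= 1 & g[, 3] <= d[3]
  } else rep(TRUE, nrow(pts))
  if (!any(inside)) return(out)
  g <- g[inside, , drop = FALSE]
  if (extrapolate == "clamp")
    g <- pmin(pmax(g, 1), matrix(d, nrow(g), 3, byrow = TRUE))
  i0 <- pmin(pmax(floor(g), 1), matrix(d - 1L, nrow(g), 3, byrow = TRUE))
  f <- g - i0
  n12 <- d[1] * d[2]
  base <- (i0[, 3] - 1) * n12 + (i0[, 2] - 1) * d[1] + i0[, 1]
  nvol <- prod(d)
  acc <- matrix(0, nrow(g), 3)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- base + dx + dy * d[1] + dz * n12
    acc[, 1] <- acc[, 1] + w * comp[lin]
    acc[, 2] <- acc[, 2] + w * comp[lin + nvol]
    acc[, 3] <- acc[, 3] + w * comp[lin + 2 * nvol]
  }
  out[inside, ] <- acc
  out
}

## Orthonormal in-plane basis (e1, e2) for a unit normal
planeBasis <- function(normal) {
  a <- if (abs(normal[1]) <= abs(normal[2]) && abs(normal[1]) <= abs(normal[3]))
         c(1, 0, 0)
       else if (abs(normal[2]) <= abs(normal[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

## Uniform raster over the plane disc: physical points plus in-plane (s, t)
## coordinates at pitch `h` mm.
planeRaster <- function(plane, h) {
  r <- plane@radius
  s <- seq(-r + h / 2, r - h / 2, by = h)
  st <- expand.grid(s = s, t = s)
  keep <- st$s^2 + st$t^2 <= r^2
  st <- st[keep, ]
  b <- planeBasis(plane@normal)
  pts <- matrix(plane@origin, nrow(st), 3, byrow = TRUE) +
    outer(st$s, b$e1) + outer(st$t, b$e2)
  list(pts = pts, s = st$s, t = st$t, h = h, basis = b)
}

#' Blood fluid constants
#'
#' Density and dynamic viscosity used by the energetic definitions. Defaults
#' are the standard blood values used in 4D-flow energetics practice.
#'
#' @param rho blood density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @return a list with elements \code{rho} and \code{mu}.
#' @export
fluidConstants <- function(rho = 1060, mu = 3.5e-3) {
  if (!is.finite(rho) || rho <= 0 || !is.finite(mu) || mu <= 0)
    stop("argument error: rho and mu must be strictly positive")
  list(rho = rho, mu = mu)
}

## run an expression with a local RNG state (deterministic per seed, does not
## disturb the caller's stream)
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
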