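## Voxel-level kinetic energy and viscous energy-loss fields, volume-of-
## interest integration, EL/KE index, and sectional jet-shape metrics.
##
## Units: velocities enter in cm/s and are converted to SI here; results are
## volume-normalized, so J/m^3 prints as uJ/ml and W/m^3 as uW/ml directly.

## neighbor-shifted copy of a 3-D array along `axis` (+1 or -1); NA outside
shiftArray <- function(A, axis, by) {
  d <- dim(A)
  out <- array(NA_real_, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1)
  } else {
    src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

## mask-aware partial derivative of A (3-D) along axis: central differences
## in the lumen interior, one-sided at the lumen boundary. Returns the
## gradient and a validity flag (FALSE where no lumen neighbor exists).
maskedGradient <- function(A, lumen, axis, delta) {
  up <- shiftArray(A, axis, +1)
  dn <- shiftArray(A, axis, -1)
  upOk <- shiftArray(lumen * 1, axis, +1) == 1
  dnOk <- shiftArray(lumen * 1, axis, -1) == 1
  upOk[is.na(upOk)] <- FALSE
  dnOk[is.na(dnOk)] <- FALSE
  g <- array(NA_real_, dim(A))
  both <- upOk & dnOk
  g[both] <- (up[both] - dn[both]) / (2 * delta)
  uo <- upOk & !dnOk
  g[uo] <- (up[uo] - A[uo]) / delta
  do <- dnOk & !upOk
  g[do] <- (A[do] - dn[do]) / delta
  list(g = g, valid = upOk | dnOk)
}

#' Volume-normalized kinetic energy
#'
#' Per-voxel kinetic energy density \eqn{\frac{1}{2} \rho |v|^2} integrated
#' over the volume of interest and normalized by its volume, per cardiac
#' phase and as the cycle average.
#'
#' @param field a \linkS4class{VelocityField4D}.
#' @param voi a \linkS4class{VolumeOfInterest}.
#' @param consts [fluidConstants()].
#' @return an \linkS4class{EnergeticsResult} with \code{keNorm} (uJ/ml) and
#'   the per-phase profile (\code{elNorm} slots unset).
#' @export
kineticEnergy <- function(field, voi, consts = fluidConstants()) {
  if (!length(voi@indices)) stop("empty volume of interest")
  d <- dim(field@velocities)
  nvol <- prod(d[1:3])
  np <- d[5]
  kep <- numeric(np)
  for (p in seq_len(np)) {
    off <- (p - 1L) * 3L * nvol
    vx <- field@velocities[off + voi@indices]
    vy <- field@velocities[off + nvol + voi@indices]
    vz <- field@velocities[off + 2L * nvol + voi@indices]
    v2 <- (vx^2 + vy^2 + vz^2) / 1e4            # (m/s)^2
    kep[p] <- 0.5 * consts$rho * mean(v2)       # J/m^3 == uJ/ml
  }
  new("EnergeticsResult", keNorm = mean(kep), voiVolume = voi@volumeMl,
      phaseProfile = cbind(keNorm = kep, elNorm = NA_real_))
}

#' Volume-normalized viscous energy loss
#'
#' The strain-rate tensor \eqn{e_{ij} = \frac{1}{2}(\partial_j v_i +
#' \partial_i v_j)} is estimated by mask-aware finite differences (central in
#' the lumen interior, one-sided at the lumen boundary); the viscous
#' dissipation density \eqn{\phi = 2 \mu \, e_{ij} e_{ij}} (incompressible
#' Newtonian form) is integrated over the volume of interest and normalized
#' by volume. Voxels with no lumen neighbor along some axis are excluded
#' (counted in \code{nExcluded}).
#'
#' @inheritParams kineticEnergy
#' @param mask the \linkS4class{LumenMask} (gradient support).
#' @return an \linkS4class{EnergeticsResult} with \code{elNorm} (uW/ml) and
#'   the per-phase profile (\code{keNorm} slots unset).
#' @export
energyLoss <- function(field, mask, voi, consts = fluidConstants()) {
  if (!length(voi@indices)) stop("empty volume of interest")
  d <- dim(field@velocities)
  nvol <- prod(d[1:3])
  np <- d[5]
  lumen <- mask@labels > 0L
  deltas <- field@spacing / 1000                 # m
  elp <- numeric(np)
  nExcluded <- 0L
  for (p in seq_len(np)) {
    off <- (p - 1L) * 3L * nvol
    v <- lapply(1:3, function(comp) {
      a <- field@velocities[off + (comp - 1L) * nvol + seq_len(nvol)] / 100
      array(a, dim = d[1:3])                     # m/s
    })
    grads <- vector("list", 9)                   # dv_i/dx_j
    validAxis <- vector("list", 3)
    for (j in 1:3) {
      for (i in 1:3) {
        gr <- maskedGradient(v[[i]], lumen, j, deltas[j])
        grads[[(j - 1) * 3 + i]] <- gr$g
        if (i == 1) validAxis[[j]] <- gr$valid
      }
    }
    gij <- function(i, j) grads[[(j - 1) * 3 + i]][voi@indices]
    phi <- 2 * consts$mu * (
      gij(1, 1)^2 + gij(2, 2)^2 + gij(3, 3)^2 +
        0.5 * ((gij(1, 2) + gij(2, 1))^2 +
               (gij(1, 3) + gij(3, 1))^2 +
               (gij(2, 3) + gij(3, 2))^2))
    ok <- validAxis[[1]][voi@indices] & validAxis[[2]][voi@indices] &
      validAxis[[3]][voi@indices]
    if (p == 1L) {
      nExcluded <- sum(!ok)
      if (nExcluded > 0L)
        warning(nExcluded,
                " voxel(s) excluded from the energy-loss integral",
                call. = FALSE)
    }
    elp[p] <- mean(phi[ok])                      # W/m^3 == uW/ml
  }
  new("EnergeticsResult", elNorm = mean(elp), voiVolume = voi@volumeMl,
      phaseProfile = cbind(keNorm = NA_real_, elNorm = elp),
      nExcluded = nExcluded)
}

#' Combine KE and EL into the EL/KE efficiency index
#'
#' \code{elKeIndex = elNorm / keNorm} (1/s): the fraction of the kinetic
#' energy present that is dissipated per second — a flow-efficiency marker
#' that, unlike EL alone, does not grow with the flow itself. For Poiseuille
#' flow the index is \eqn{12 \mu / (\rho R^2)}, independent of velocity.
#'
#' @param ke result of [kineticEnergy()].
#' @param el result of [energyLoss()].
#' @return a complete \linkS4class{EnergeticsResult}. When \code{keNorm} is
#'   zero the index is NA (undefined, with a warning).
#' @export
combineEnergetics <- function(ke, el) {
  stopifnot(is(ke, "EnergeticsResult"), is(el, "EnergeticsResult"))
  idx <- if (is.finite(ke@keNorm) && ke@keNorm > 0) el@elNorm / ke@keNorm
         else {
           warning("undefined index: keNorm is zero", call. = FALSE)
           NA_real_
         }
  new("EnergeticsResult", keNorm = ke@keNorm, elNorm = el@elNorm,
      elKeIndex = idx, voiVolume = ke@voiVolume,
      phaseProfile = cbind(keNorm = ke@phaseProfile[, "keNorm"],
                           elNorm = el@phaseProfile[, "elNorm"]),
      nExcluded = el@nExcluded)
}

#' Full energetics of a volume of interest
#'
#' Convenience wrapper: [kineticEnergy()], [energyLoss()] and
#' [combineEnergetics()] in one call.
#'
#' @inheritParams energyLoss
#' @return a complete \linkS4class{EnergeticsResult}.
#' @export
energetics <- function(field, mask, voi, consts = fluidConstants()) {
  combineEnergetics(kineticEnergy(field, voi, consts),
                    energyLoss(field, mask, voi, consts))
}

#' Sectional jet-shape metrics
#'
#' On one analysis plane (time-averaged field by default):
#' \itemize{
#'   \item \strong{jet angle}: angle in degrees between the flux-weighted
#'     mean velocity vector on the lumen section and the plane normal;
#'   \item \strong{eccentricity}: in-plane displacement of the
#'     velocity-weighted flow centroid from the geometric lumen centroid,
#'     normalized by the equivalent lumen diameter \eqn{2\sqrt{A/\pi}};
#'   \item \strong{mean WSS}: \eqn{\mu \langle |\partial v_t / \partial n|
#'     \rangle} over the lumen boundary contour, with the wall-normal
#'     gradient taken as a linear one-sided difference over \code{wallOffset}
#'     with zero velocity imposed at the wall (the wall is placed midway
#'     between the last lumen and first background raster cell).
#' }
#'
#' @inheritParams planeFlux
#' @param consts [fluidConstants()] (viscosity for WSS).
#' @param phaseMode "time_averaged" (default) or "single_phase".
#' @param phaseIndex phase used in single-phase mode.
#' @param wallOffset sampling depth for the wall gradient, mm; defaults to
#'   one voxel spacing.
#' @return a \linkS4class{SectionShape}.
#' @export
sectionShape <- function(field, mask, plane, consts = fluidConstants(),
                         raster = 0.5,
                         phaseMode = c("time_averaged", "single_phase"),
                         phaseIndex = 1L, wallOffset = NULL) {
  phaseMode <- match.arg(phaseMode)
  comp <- if (phaseMode == "time_averaged") {
    timeAverage(field)@velocities[, , , , 1]
  } else field@velocities[, , , , phaseIndex]
  dim(comp) <- dim(field@velocities)[1:4]
  if (is.null(wallOffset)) wallOffset <- min(field@spacing)

  rs <- planeRaster(plane, raster)
  lum <- maskLabelAt(mask, rs$pts) > 0L
  if (!any(lum)) stop("empty section: plane does not intersect the lumen")
  pts <- rs$pts[lum, , drop = FALSE]
  v <- trilinearVelocity(comp, field@spacing, field@origin, pts)
  vdotn <- as.numeric(v %*% plane@normal)
  wgt <- abs(vdotn)

  ## jet angle from the flux-weighted mean velocity
  if (sum(wgt) == 0) {
    jet <- NA_real_
    ecc <- NA_real_
  } else {
    vbar <- colSums(v * wgt) / sum(wgt)
    cosang <- abs(sum(vbar * plane@normal)) / sqrt(sum(vbar^2))
    jet <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ## centroids in plane coordinates
    st <- cbind(rs$s[lum], rs$t[lum])
    cGeo <- colMeans(st)
    cVel <- colSums(st * wgt) / sum(wgt)
    area <- sum(lum) * raster^2                  # mm^2
    dEq <- 2 * sqrt(area / pi)                   # mm
    ecc <- min(1, sqrt(sum((cVel - cGeo)^2)) / dEq)
  }

  ## wall shear stress over the section boundary contour. Wall points sit
  ## midway between boundary lumen cells and their background neighbors;
  ## the inward wall normal is taken radially towards the section centroid
  ## (vessel sections are near-convex), which is robust to the staircase of
  ## the rasterized contour.
  h <- raster
  r <- plane@radius
  sAxis <- seq(-r + h / 2, r - h / 2, by = h)
  ns <- length(sAxis)
  occ <- matrix(-1L, ns, ns)                     # -1 outside disc
  si <- round((rs$s + r - h / 2) / h) + 1L
  ti <- round((rs$t + r - h / 2) / h) + 1L
  occ[cbind(si, ti)] <- ifelse(lum, 1L, 0L)
  cSec <- c(mean(rs$s[lum]), mean(rs$t[lum]))
  wallS <- wallT <- numeric(0)
  for (dir in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- matrix(-1L, ns, ns)
    srcS <- seq_len(ns) + dir[1]
    srcT <- seq_len(ns) + dir[2]
    okS <- srcS >= 1 & srcS <= ns
    okT <- srcT >= 1 & srcT <= ns
    nb[okS, okT] <- occ[srcS[okS], srcT[okT]]
    edge <- which(occ == 1L & nb == 0L, arr.ind = TRUE)
    if (!nrow(edge)) next
    wallS <- c(wallS, sAxis[edge[, 1]] + dir[1] * h / 2)
    wallT <- c(wallT, sAxis[edge[, 2]] + dir[2] * h / 2)
  }
  wss <- NA_real_
  if (length(wallS)) {
    dS <- cSec[1] - wallS; dT <- cSec[2] - wallT
    len <- sqrt(dS^2 + dT^2)
    keep <- len > h                              # degenerate wall points
    if (any(keep)) {
      nS <- dS[keep] / len[keep]; nT <- dT[keep] / len[keep]
      wall3 <- matrix(plane@origin, sum(keep), 3, byrow = TRUE) +
        outer(wallS[keep], rs$basis$e1) + outer(wallT[keep], rs$basis$e2)
      in3 <- outer(nS, rs$basis$e1) + outer(nT, rs$basis$e2)
      vi <- trilinearVelocity(comp, field@spacing, field@origin,
                              wall3 + in3 * wallOffset)
      vt <- vi - in3 * rowSums(vi * in3)
      speedT <- sqrt(rowSums(vt^2)) / 100        # m/s
      wss <- mean(consts$mu * speedT / (wallOffset / 1000))
    }
  }
  new("SectionShape", wssMean = wss, jetAngle = jet, eccentricity = ecc,
      vessel = plane@vessel)
}
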