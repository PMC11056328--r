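## Analytic flow phantoms. Each generator attaches machine-readable ground
## truth for every quantity the estimation stages compute; the truth values
## come from closed forms (or prescribed stream-function fluxes), never from
## the estimators themselves.

## shared pulsatile modulation: field scaled by 1 + a*sin(2*pi*t/T) at phase
## midtimes t_p = (p-1)*T/nPhases
phaseScales <- function(nPhases, pulsatility) {
  1 + pulsatility * sin(2 * pi * (seq_len(nPhases) - 1) / nPhases)
}

## time-average factor of the squared modulation (enters KE and EL truth)
pulsatileEnergyFactor <- function(nPhases, pulsatility) {
  mean(phaseScales(nPhases, pulsatility)^2)
}

#' Straight-tube Poiseuille phantom
#'
#' Fully developed laminar pipe flow along +z: axial velocity
#' \eqn{v(r) = v_{max} (1 - r^2/R^2)} inside radius R, zero outside, on an
#' isotropic voxel grid. Closed-form ground truth is attached for flow rate
#' (\eqn{Q = v_{max} \pi R^2 / 2}), volume-normalized kinetic energy
#' (\eqn{\rho v_{max}^2 / 6}), viscous energy loss
#' (\eqn{2 \mu v_{max}^2 / R^2}), the EL/KE index
#' (\eqn{12 \mu / (\rho R^2)}, independent of \eqn{v_{max}}) and wall shear
#' stress (\eqn{2 \mu v_{max} / R}).
#'
#' @param radius tube radius R, mm.
#' @param length tube length, mm.
#' @param vmax centerline velocity, cm/s.
#' @param spacing isotropic voxel size, mm.
#' @param nPhases number of cardiac phases (1 = steady).
#' @param pulsatility amplitude fraction a of the sinusoidal modulation
#'   \eqn{1 + a \sin(2\pi t/T)}.
#' @param cycleDuration cardiac cycle length T, s.
#' @param margin background margin around the lumen, mm.
#' @param consts [fluidConstants()] used for the energetic ground truth.
#' @return a \linkS4class{FlowPhantom} with one mid-tube analysis plane.
#' @export
poiseuillePhantom <- function(radius = 10, length = 40, vmax = 60,
                              spacing = 1, nPhases = 1L, pulsatility = 0,
                              cycleDuration = 1, margin = 3,
                              consts = fluidConstants()) {
  if (radius <= 0 || length <= 0) stop("argument error: radius and length > 0")
  half <- radius + margin
  x <- seq(-half, half, by = spacing)
  z <- seq(0, length, by = spacing)
  if (max(abs(x)) < radius) stop("geometry exceeds grid")
  nx <- length(x); nz <- length(z)
  r2 <- outer(x^2, x^2, "+")                     # nx x ny
  inside <- r2 <= radius^2
  prof <- ifelse(inside, vmax * (1 - r2 / radius^2), 0)

  vel <- array(0, dim = c(nx, nx, nz, 3, nPhases))
  sc <- phaseScales(nPhases, pulsatility)
  for (p in seq_len(nPhases))
    vel[, , , 3, p] <- array(rep(prof * sc[p], nz), dim = c(nx, nx, nz))

  org <- c(-half, -half, 0)
  field <- new("VelocityField4D", velocities = vel,
               spacing = rep(spacing, 3), origin = org,
               phaseDuration = cycleDuration / nPhases)
  labels <- array(0L, dim = c(nx, nx, nz))
  labels[rep(inside, nz)] <- 1L
  mask <- new("LumenMask", labels = labels, segments = c(tube = 1L),
              spacing = rep(spacing, 3), origin = org)
  plane <- analysisPlane(origin = c(0, 0, length / 2), normal = c(0, 0, 1),
                         radius = radius + 2 * spacing, vessel = "tube")

  vm <- vmax / 100                                # m/s
  Rm <- radius / 1000                             # m
  efac <- pulsatileEnergyFactor(nPhases, pulsatility)
  truth <- list(
    qLmin        = vm * pi * Rm^2 / 2 * 6e4,      # l/min
    meanVelocity = vmax / 2,                      # cm/s (area average)
    keNorm       = consts$rho * vm^2 / 6 * efac,  # uJ/ml
    elNorm       = 2 * consts$mu * vm^2 / Rm^2 * efac,  # uW/ml
    elKeIndex    = 12 * consts$mu / (consts$rho * Rm^2), # 1/s
    wssMean      = 2 * consts$mu * vm / Rm,       # Pa
    jetAngle     = 0,
    eccentricity = 0,
    consts       = consts
  )
  new("FlowPhantom", field = field, mask = mask,
      planes = list(tube = plane), truth = truth, kind = "poiseuille_tube")
}

#' Tilted / offset jet phantom
#'
#' A straight tube (lumen radius R along +z) carrying a parabolic jet whose
#' direction is tilted by \code{tiltDeg} towards +x and whose center is
#' displaced along +x by \code{offsetFraction} times the equivalent lumen
#' diameter 2R. The jet radius shrinks to \code{R - offset} so the displaced
#' profile stays inside the lumen. Ground truth: jet angle = tiltDeg,
#' eccentricity = offsetFraction (displacement / equivalent diameter).
#'
#' @inheritParams poiseuillePhantom
#' @param tiltDeg jet tilt angle from the tube axis, degrees.
#' @param offsetFraction jet-center displacement as a fraction of the
#'   equivalent lumen diameter (2R); must satisfy offsetFraction < 0.5.
#' @return a \linkS4class{FlowPhantom} with one mid-tube analysis plane.
#' @export
tiltedJetPhantom <- function(radius = 10, length = 40, vmax = 60,
                             tiltDeg = 0, offsetFraction = 0, spacing = 1,
                             margin = 3, consts = fluidConstants()) {
  if (offsetFraction < 0 || offsetFraction >= 0.5)
    stop("argument error: offsetFraction must lie in [0, 0.5)")
  half <- radius + margin
  x <- seq(-half, half, by = spacing)
  z <- seq(0, length, by = spacing)
  nx <- length(x); nz <- length(z)

  d <- offsetFraction * 2 * radius               # displacement, mm
  rj <- radius - d                               # jet radius, mm
  r2c <- outer((x - d)^2, x^2, "+")              # about jet center (d, 0)
  prof <- pmax(0, vmax * (1 - r2c / rj^2))
  th <- tiltDeg * pi / 180
  dirv <- c(sin(th), 0, cos(th))

  vel <- array(0, dim = c(nx, nx, nz, 3, 1))
  for (comp in 1:3)
    vel[, , , comp, 1] <- array(rep(prof * dirv[comp], nz),
                                dim = c(nx, nx, nz))
  org <- c(-half, -half, 0)
  field <- new("VelocityField4D", velocities = vel,
               spacing = rep(spacing, 3), origin = org, phaseDuration = 1)
  inside <- outer(x^2, x^2, "+") <= radius^2
  labels <- array(0L, dim = c(nx, nx, nz))
  labels[rep(inside, nz)] <- 1L
  mask <- new("LumenMask", labels = labels, segments = c(tube = 1L),
              spacing = rep(spacing, 3), origin = org)
  plane <- analysisPlane(origin = c(0, 0, length / 2), normal = c(0, 0, 1),
                         radius = radius + 2 * spacing, vessel = "tube")
  truth <- list(jetAngle = tiltDeg, eccentricity = offsetFraction,
                jetCenter = c(d, 0), consts = consts)
  new("FlowPhantom", field = field, mask = mask,
      planes = list(tube = plane), truth = truth, kind = "tilted_jet_tube")
}

#' Total cavopulmonary connection (TCPC) junction phantom
#'
#' Four rectangular limbs (SVC from above, IVC conduit from below, RPA to +x,
#' LPA to -x) meeting in a cuboid confluence, extruded in y with a parabolic
#' depth profile. The in-plane field derives from a piecewise stream function
#' built from four quarter-elliptic corner-turn flows, so it is exactly
#' divergence-free within each depth slab and the prescribed caval-to-
#' pulmonary split fractions are exact ground truth: seeds released uniformly
#' over a caval section reach each pulmonary artery in exactly the prescribed
#' proportion (plug profile across the routing axis). Analysis planes are
#' placed on all four limbs at \code{planeDistance} from the junction.
#'
#' @param halfWidth caval channel half-width in x, mm.
#' @param halfHeight pulmonary channel half-height in z, mm.
#' @param halfDepth half-depth of all channels in y, mm.
#' @param limbLength limb length beyond the confluence, mm.
#' @param qIvc,qSvc caval inflows, l/min.
#' @param splitIvcLpa fraction of IVC flow routed to the LPA, in [0, 1].
#' @param splitSvcRpa fraction of SVC flow routed to the RPA, in [0, 1].
#' @param planeDistance distance of the limb analysis planes from the
#'   junction (default 15 mm).
#' @inheritParams poiseuillePhantom
#' @return a \linkS4class{FlowPhantom} with planes IVC, SVC, RPA, LPA.
#' @export
tcpcPhantom <- function(halfWidth = 8, halfHeight = 8, halfDepth = 8,
                        limbLength = 40, qIvc = 2.5, qSvc = 1.5,
                        splitIvcLpa = 0.5, splitSvcRpa = 0.5,
                        spacing = 1, planeDistance = 15,
                        nPhases = 1L, pulsatility = 0, cycleDuration = 1) {
  if (splitIvcLpa < 0 || splitIvcLpa > 1 || splitSvcRpa < 0 || splitSvcRpa > 1)
    stop("infeasible split: fractions must lie in [0, 1]")
  if (qIvc < 0 || qSvc < 0) stop("infeasible split: negative inflow")
  a <- halfWidth; b <- halfHeight; cc <- halfDepth
  ext <- max(a, b) + limbLength
  if (planeDistance + spacing > limbLength)
    stop("geometry exceeds grid: planeDistance beyond limb")

  x <- seq(-(a + limbLength), a + limbLength, by = spacing)
  z <- seq(-(b + limbLength), b + limbLength, by = spacing)
  y <- seq(-cc, cc, by = spacing)
  nx <- length(x); ny <- length(y); nz <- length(z)

  toMm3s <- 1e6 / 60                             # l/min -> mm^3/s
  qI <- qIvc * toMm3s / (2 * cc)                 # per-depth fluxes, mm^2/s
  qS <- qSvc * toMm3s / (2 * cc)
  q1 <- splitIvcLpa * qI; q2 <- qI - q1          # IVC->LPA, IVC->RPA
  q3 <- splitSvcRpa * qS; q4 <- qS - q3          # SVC->RPA, SVC->LPA
  qL <- q1 + q4; qR <- q2 + q3

  ## per-depth in-plane velocity (u along x, w along z) on the x-z grid
  X <- matrix(x, nx, nz); Z <- matrix(z, nx, nz, byrow = TRUE)
  u <- matrix(0, nx, nz); w <- matrix(0, nx, nz)
  inIvc <- abs(X) <= a & Z < -b
  inSvc <- abs(X) <= a & Z > b
  inLpa <- X < -a & abs(Z) <= b
  inRpa <- X > a & abs(Z) <= b
  inBox <- abs(X) <= a & abs(Z) <= b
  w[inIvc] <- qI / (2 * a)
  w[inSvc] <- -qS / (2 * a)
  u[inLpa] <- -qL / (2 * b)
  u[inRpa] <- qR / (2 * b)

  ## Each (inlet, outlet) stream occupies a triangular turning region hugging
  ## its corner: stream function psi = q (1 - xi/beta - zeta/gamma) on
  ## xi/beta + zeta/gamma <= 1, i.e. a constant oblique velocity whose
  ## normal components match the adjoining plug limbs exactly. The four
  ## triangles tile the confluence without overlap for any feasible splits
  ## (the band constraints of a diagonal pair sum to >= 2), so the
  ## prescribed split fractions are exact routing ground truth. Voxel
  ## centers on a shared boundary line average the adjacent streams.
  xi1 <- (X + a) / (2 * a); xi2 <- 1 - xi1       # from left / right wall
  ze1 <- (Z + b) / (2 * b); ze2 <- 1 - ze1       # from bottom / top wall
  cnt <- matrix(0L, nx, nz)
  uAcc <- matrix(0, nx, nz); wAcc <- matrix(0, nx, nz)
  corner <- function(q, beta, gamma, xi, ze, su, sw) {
    if (q <= 0 || beta <= 0 || gamma <= 0) return(invisible())
    sel <- inBox & (xi / beta + ze / gamma <= 1 + 1e-12)
    uAcc[sel] <<- uAcc[sel] + su * q / (2 * b * gamma)
    wAcc[sel] <<- wAcc[sel] + sw * q / (2 * a * beta)
    cnt[sel] <<- cnt[sel] + 1L
  }
  corner(q1, splitIvcLpa,     q1 / qL, xi1, ze1, -1, +1)  # IVC -> LPA
  corner(q2, 1 - splitIvcLpa, q2 / qR, xi2, ze1, +1, +1)  # IVC -> RPA
  corner(q3, splitSvcRpa,     q3 / qR, xi2, ze2, +1, -1)  # SVC -> RPA
  corner(q4, 1 - splitSvcRpa, q4 / qL, xi1, ze2, -1, -1)  # SVC -> LPA
  div <- pmax(cnt, 1L)
  u[inBox] <- (uAcc / div)[inBox]
  w[inBox] <- (wAcc / div)[inBox]

  inLumen2d <- inIvc | inSvc | inLpa | inRpa | inBox
  u[!inLumen2d] <- 0; w[!inLumen2d] <- 0

  g <- 1.5 * (1 - (y / cc)^2)                    # parabolic depth profile
  ## assemble [nx, ny, nz, 3, nPhases]; arrays are (x, y, z)
  expand <- function(m2d) aperm(outer(m2d, g), c(1, 3, 2))  # -> (x, y, z)
  u3 <- expand(u) / 10                           # mm/s -> cm/s
  w3 <- expand(w) / 10
  sc <- phaseScales(nPhases, pulsatility)
  vel <- array(0, dim = c(nx, ny, nz, 3, nPhases))
  for (p in seq_len(nPhases)) {
    vel[, , , 1, p] <- u3 * sc[p]
    vel[, , , 3, p] <- w3 * sc[p]
  }
  org <- c(min(x), min(y), min(z))
  field <- new("VelocityField4D", velocities = vel,
               spacing = rep(spacing, 3), origin = org,
               phaseDuration = cycleDuration / nPhases)

  lab2d <- matrix(0L, nx, nz)
  lab2d[inIvc] <- 1L; lab2d[inSvc] <- 2L; lab2d[inRpa] <- 3L
  lab2d[inLpa] <- 4L; lab2d[inBox] <- 5L
  labels <- aperm(array(rep(lab2d, ny), dim = c(nx, nz, ny)), c(1, 3, 2))
  storage.mode(labels) <- "integer"
  mask <- new("LumenMask", labels = labels,
              segments = c(IVC = 1L, SVC = 2L, RPA = 3L, LPA = 4L,
                           confluence = 5L),
              spacing = rep(spacing, 3), origin = org)

  pr <- sqrt(max(a, b)^2 + cc^2) + spacing       # covers the rectangle
  planes <- list(
    IVC = analysisPlane(c(0, 0, -(b + planeDistance)), c(0, 0, 1),  pr, "IVC"),
    SVC = analysisPlane(c(0, 0,  b + planeDistance),  c(0, 0, -1), pr, "SVC"),
    RPA = analysisPlane(c(a + planeDistance, 0, 0),   c(1, 0, 0),  pr, "RPA"),
    LPA = analysisPlane(c(-(a + planeDistance), 0, 0), c(-1, 0, 0), pr, "LPA"))

  truth <- list(
    qIvc = qIvc, qSvc = qSvc,
    qRpa = (1 - splitIvcLpa) * qIvc + splitSvcRpa * qSvc,
    qLpa = splitIvcLpa * qIvc + (1 - splitSvcRpa) * qSvc,
    splitIvcLpa = splitIvcLpa, splitSvcRpa = splitSvcRpa,
    ## uniform seeding over a caval section recovers the split as a line
    ## count fraction (plug profile across x)
    countSplitIvcLpa = splitIvcLpa, countSplitSvcRpa = splitSvcRpa)
  new("FlowPhantom", field = field, mask = mask, planes = planes,
      truth = truth, kind = "tcpc_junction")
}

#' Add VENC-like Gaussian velocity noise
#'
#' Adds i.i.d. zero-mean Gaussian noise per component per voxel, emulating
#' the velocity noise of phase-contrast MRI. When a mask is supplied, noise
#' is confined to the lumen enlarged by \code{dilate} voxels (velocity noise
#' outside the vessel carries no signal and is excluded by segmentation).
#' Deterministic for a given seed.
#'
#' @param field a \linkS4class{VelocityField4D}.
#' @param sigma noise standard deviation, cm/s (>= 0).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param mask optional \linkS4class{LumenMask}.
#' @param dilate mask enlargement in voxels.
#' @return a new \linkS4class{VelocityField4D}.
#' @export
addVelocityNoise <- function(field, sigma, seed = NULL, mask = NULL,
                             dilate = 2L) {
  if (!is.finite(sigma) || sigma < 0)
    stop("argument error: sigma must be >= 0")
  if (sigma == 0) return(field)
  vel <- field@velocities
  withLocalSeed(seed, {
    if (is.null(mask)) {
      vel <- vel + array(stats::rnorm(length(vel), 0, sigma), dim = dim(vel))
    } else {
      region <- dilateMask(mask@labels > 0L, dilate)
      idx <- which(region)
      d <- dim(vel)
      nvol <- prod(d[1:3])
      for (p in seq_len(d[5])) for (comp in 1:3) {
        off <- (p - 1L) * 3L * nvol + (comp - 1L) * nvol
        vel[off + idx] <- vel[off + idx] +
          stats::rnorm(length(idx), 0, sigma)
      }
    }
  })
  new("VelocityField4D", velocities = vel, spacing = field@spacing,
      origin = field@origin, phaseDuration = field@phaseDuration)
}

## binary dilation of a logical 3-D array by r voxels (Chebyshev ball)
dilateMask <- function(m, r) {
  if (r <= 0) return(m)
  d <- dim(m)
  out <- m
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      m[xs - dx, ys - dy, zs - dz]
  }
  out
}

#' Synthetic Fontan cohort with a planted EL/KE association
#'
#' Generates a clinical covariate table shaped like a Fontan CPET subgroup:
#' age (years), gender, BSA, peak VO2 (ml/kg/min) and EL/KE index (1/s),
#' with a planted age-adjusted partial correlation between EL/KE and peak
#' VO2. Marginal scales follow typical Fontan cohort values (age 22 +- 10,
#' peak VO2 20 +- 4.9, EL/KE centered at 0.24 with SD ~0.08).
#'
#' @param n cohort size.
#' @param rPartial target age-adjusted partial correlation between EL/KE and
#'   peak VO2 (negative: higher EL/KE, lower exercise capacity).
#' @param seed integer seed or NULL.
#' @return a data.frame with columns id, age, gender, bsa, vo2Peak,
#'   elKeIndex.
#' @export
syntheticCohort <- function(n = 34, rPartial = -0.453, seed = NULL) {
  if (abs(rPartial) >= 1) stop("argument error: |rPartial| must be < 1")
  withLocalSeed(seed, {
    age <- stats::rnorm(n, 22, 10)
    zAge <- as.numeric(scale(age))
    vo2 <- 20 + 4.9 * (-0.3 * zAge + sqrt(1 - 0.09) * stats::rnorm(n))
    ## standardized VO2 residual after age: the adjusted channel
    xres <- stats::lm.fit(cbind(1, age), vo2)$residuals
    xres <- xres / stats::sd(xres)
    eps <- stats::rnorm(n)
    elke <- 0.24 + 0.015 * zAge +
      0.08 * (rPartial * xres + sqrt(1 - rPartial^2) * eps)
    data.frame(
      id = sprintf("S%03d", seq_len(n)),
      age = age,
      gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.65, 0.35)),
      bsa = pmax(0.8, stats::rnorm(n, 1.5, 0.3)),
      vo2Peak = vo2,
      elKeIndex = elke)
  })
}

#' Power to recover a planted EL/KE-VO2 association
#'
#' Monte-Carlo power of the age-adjusted partial correlation to detect the
#' planted EL/KE vs peak-VO2 association in synthetic cohorts: the fraction
#' of replicates with two-sided p < alpha and the correct sign.
#'
#' @param nRep number of replicate cohorts.
#' @param n cohort size per replicate.
#' @param rPartial planted partial correlation.
#' @param alpha significance level.
#' @param seed integer seed or NULL.
#' @return proportion of successful replicates.
#' @export
associationPower <- function(nRep = 500, n = 34, rPartial = -0.453,
                             alpha = 0.05, seed = NULL) {
  withLocalSeed(seed, {
    hits <- vapply(seq_len(nRep), function(i) {
      d <- syntheticCohort(n = n, rPartial = rPartial, seed = NULL)
      pc <- partialCorrelation(d$elKeIndex, d$vo2Peak, d["age"])
      pc$p.value < alpha && sign(pc$estimate) == sign(rPartial)
    }, logical(1))
    mean(hits)
  })
}
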