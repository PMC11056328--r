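## Streamline tracing through the interpolated voxel velocity field with an
## adaptive Dormand-Prince Runge-Kutta 4(5) integrator, and caval flow
## distribution to the pulmonary arteries.

## Dormand-Prince 4(5) tableau
.dp45 <- list(
  A = matrix(c(
    0,          0,           0,          0,        0,             0,     0,
    1/5,        0,           0,          0,        0,             0,     0,
    3/40,       9/40,        0,          0,        0,             0,     0,
    44/45,     -56/15,       32/9,       0,        0,             0,     0,
    19372/6561, -25360/2187, 64448/6561, -212/729, 0,             0,     0,
    9017/3168,  -355/33,     46732/5247, 49/176,   -5103/18656,   0,     0,
    35/384,     0,           500/1113,   125/192,  -2187/6784,    11/84, 0),
    nrow = 7, byrow = TRUE),
  b5 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0),
  b4 = c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
)

#' Trace streamlines from a seed plane
#'
#' Seeds are placed uniformly at random over the lumen-intersected seed disc
#' (deterministic per seed) and integrated forward through the interpolated
#' velocity field — time-averaged by default, as Fontan caval flow is
#' quasi-steady — with an adaptive Runge-Kutta 4(5) (Dormand-Prince)
#' integrator. A line terminates when it exits the lumen (the crossing is
#' refined by bisection so the terminal point lies at the boundary), exceeds
#' \code{maxLength}, or stalls (speed below \code{stallSpeed}).
#'
#' @param field a \linkS4class{VelocityField4D}.
#' @param mask a \linkS4class{LumenMask}.
#' @param seedPlane an \linkS4class{AnalysisPlane} (e.g. the SVC or IVC
#'   section).
#' @param nSeeds number of seed points (>= 1).
#' @param seedWeighting "uniform" (default; matches the line-count semantics
#'   of streamline visualization) or "flux_weighted" (seed density
#'   proportional to the local through-plane speed, so line counts
#'   approximate flow fractions on non-plug profiles).
#' @param phaseMode "time_averaged" (default) or "single_phase".
#' @param phaseIndex phase used when \code{phaseMode = "single_phase"}.
#' @param seed integer seed for reproducible seeding, or NULL.
#' @param maxLength maximum arc length, mm.
#' @param stallSpeed stall threshold, cm/s.
#' @param relTol,absTol integrator tolerances (relative; absolute in mm).
#' @param maxStepMm cap on the spatial advance per step, mm.
#' @param maxSteps per-line accepted-step budget.
#' @return a \linkS4class{StreamlineSet} (outlet labels unset; see
#'   [classifyOutlets()]).
#' @export
traceStreamlines <- function(field, mask, seedPlane, nSeeds = 500L,
                             seedWeighting = c("uniform", "flux_weighted"),
                             phaseMode = c("time_averaged", "single_phase"),
                             phaseIndex = 1L, seed = NULL,
                             maxLength = 500, stallSpeed = 0.1,
                             relTol = 1e-4, absTol = 1e-6,
                             maxStepMm = 5, maxSteps = 5000L) {
  seedWeighting <- match.arg(seedWeighting)
  phaseMode <- match.arg(phaseMode)
  if (nSeeds < 1L) stop("argument error: nSeeds must be >= 1")
  comp <- if (phaseMode == "time_averaged") {
    timeAverage(field)@velocities[, , , , 1]
  } else {
    field@velocities[, , , , phaseIndex]
  }
  dim(comp) <- dim(field@velocities)[1:4]

  ## mm/s velocity at physical points (clamp: open limb ends stay open)
  vfun <- function(pts)
    10 * trilinearVelocity(comp, field@spacing, field@origin, pts,
                           extrapolate = "clamp")

  seeds <- withLocalSeed(seed, {
    got <- matrix(numeric(0), 0, 3)
    b <- planeBasis(seedPlane@normal)
    guard <- 0L
    while (nrow(got) < nSeeds && guard < 200L) {
      m <- max(4L * (nSeeds - nrow(got)), 64L)
      rr <- seedPlane@radius * sqrt(stats::runif(m))
      th <- 2 * pi * stats::runif(m)
      cand <- matrix(seedPlane@origin, m, 3, byrow = TRUE) +
        outer(rr * cos(th), b$e1) + outer(rr * sin(th), b$e2)
      keep <- maskLabelAt(mask, cand) > 0L
      if (seedWeighting == "flux_weighted" && any(keep)) {
        vn <- abs(trilinearVelocity(comp, field@spacing, field@origin,
                                    cand[keep, , drop = FALSE]) %*%
                    seedPlane@normal)
        vmaxn <- max(vn)
        if (vmaxn > 0)
          keep[keep] <- stats::runif(sum(keep)) < vn / vmaxn
      }
      got <- rbind(got, cand[keep, , drop = FALSE])
      guard <- guard + 1L
    }
    if (nrow(got) < nSeeds)
      stop("empty seed section: seed plane does not intersect the lumen")
    got[seq_len(nSeeds), , drop = FALSE]
  })

  n <- nSeeds
  pos <- seeds
  v0 <- vfun(pos)
  sp0 <- sqrt(rowSums(v0^2))                     # mm/s
  status <- rep(NA_character_, n)
  status[sp0 < stallSpeed * 10] <- "stalled"
  active <- is.na(status)
  h <- ifelse(sp0 > 0, 0.5 * min(field@spacing) / pmax(sp0, 1e-9), 1e-3)
  arclen <- numeric(n)
  nsteps <- integer(n)

  K <- 64L
  rec <- array(NA_real_, dim = c(n, 3, K))
  rec[, , 1] <- pos
  nrec <- rep(1L, n)

  A <- .dp45$A; b5 <- .dp45$b5; b4 <- .dp45$b4
  iter <- 0L
  while (any(active) && iter < 20L * maxSteps) {
    iter <- iter + 1L
    idx <- which(active)
    p <- pos[idx, , drop = FALSE]
    hh <- h[idx]
    ## cap spatial advance
    v1 <- vfun(p)
    sp <- sqrt(rowSums(v1^2))
    hh <- pmin(hh, maxStepMm / pmax(sp, 1e-9))
    k <- vector("list", 7)
    k[[1]] <- v1
    for (s in 2:7) {
      dp <- matrix(0, length(idx), 3)
      for (j in seq_len(s - 1)) if (A[s, j] != 0)
        dp <- dp + A[s, j] * k[[j]]
      k[[s]] <- vfun(p + hh * dp)
    }
    y5 <- p; y4 <- p
    for (s in 1:7) {
      if (b5[s] != 0) y5 <- y5 + hh * b5[s] * k[[s]]
      if (b4[s] != 0) y4 <- y4 + hh * b4[s] * k[[s]]
    }
    sc <- absTol + relTol * pmax(abs(y5), abs(p))
    err <- sqrt(rowMeans(((y5 - y4) / sc)^2))
    ok <- err <= 1 | hh <= 1e-10
    fac <- pmin(5, pmax(0.2, 0.9 * err^(-0.2), na.rm = TRUE))
    fac[!is.finite(fac)] <- 5
    h[idx] <- hh * fac

    if (any(ok)) {
      ai <- idx[ok]
      newp <- y5[ok, , drop = FALSE]
      oldp <- p[ok, , drop = FALSE]
      step <- sqrt(rowSums((newp - oldp)^2))
      outside <- maskLabelAt(mask, newp) == 0L
      ## bisect exit crossings onto the lumen boundary
      if (any(outside)) {
        lo <- oldp[outside, , drop = FALSE]
        hi <- newp[outside, , drop = FALSE]
        for (it in 1:12) {
          mid <- (lo + hi) / 2
          ins <- maskLabelAt(mask, mid) > 0L
          lo[ins, ] <- mid[ins, , drop = FALSE]
          hi[!ins, ] <- mid[!ins, , drop = FALSE]
        }
        newp[outside, ] <- hi                     # just outside the wall
      }
      pos[ai, ] <- newp
      arclen[ai] <- arclen[ai] + step
      nsteps[ai] <- nsteps[ai] + 1L
      if (max(nrec[ai]) + 1L > K) {
        K2 <- 2L * K
        rec2 <- array(NA_real_, dim = c(n, 3, K2))
        rec2[, , seq_len(K)] <- rec
        rec <- rec2; K <- K2
      }
      nrec[ai] <- nrec[ai] + 1L
      for (cmp in 1:3)
        rec[cbind(ai, cmp, nrec[ai])] <- newp[, cmp]

      spd <- sqrt(rowSums(vfun(newp)^2))          # mm/s
      st <- rep(NA_character_, length(ai))
      st[arclen[ai] > maxLength] <- "length_out"
      st[spd < stallSpeed * 10 & is.na(st)] <- "stalled"
      st[outside] <- "exited"
      st[nsteps[ai] >= maxSteps & is.na(st)] <- "length_out"
      done <- !is.na(st)
      status[ai[done]] <- st[done]
      active[ai[done]] <- FALSE
    }
    stuck <- idx[hh <= 1e-10 & !ok]
    if (length(stuck)) {
      status[stuck] <- "stalled"
      active[stuck] <- FALSE
    }
  }
  status[is.na(status)] <- "length_out"

  lines <- lapply(seq_len(n), function(i)
    t(rec[i, , seq_len(nrec[i]), drop = TRUE]))
  lines <- lapply(lines, function(m) if (ncol(m) == 3) m else t(m))
  new("StreamlineSet", lines = lines, seedVessel = seedPlane@vessel,
      status = status, outletLabels = character(0),
      distribution = numeric(0), unresolvedPct = NA_real_)
}

#' Classify streamline outlets and compute the caval flow distribution
#'
#' Labels each traced line by the outlet segment containing its terminal
#' point (within a dilation tolerance of \code{dilate} voxels) and computes
#' the percent distribution of resolved lines per outlet. Lines that
#' stalled, ran out of length, or ended away from any named outlet are
#' reported as "unresolved" and excluded from the denominator, so the
#' resolved percentages sum to 100.
#'
#' @param sl a \linkS4class{StreamlineSet} from [traceStreamlines()].
#' @param mask the \linkS4class{LumenMask}.
#' @param outletSegments names of the outlet segments (default RPA, LPA).
#' @param dilate tolerance, in voxels, around each outlet segment.
#' @return the \linkS4class{StreamlineSet} with outlet labels and
#'   distribution filled in.
#' @export
classifyOutlets <- function(sl, mask, outletSegments = c("RPA", "LPA"),
                            dilate = 2L) {
  absent <- setdiff(outletSegments, segmentNames(mask))
  if (length(absent))
    stop("configuration error: outlet segment(s) not in mask: ",
         paste(absent, collapse = ", "))
  ids <- mask@segments[outletSegments]
  d <- gridDim(mask)
  labels <- rep("unresolved", length(sl@lines))
  for (i in seq_along(sl@lines)) {
    if (sl@status[i] != "exited") next
    tp <- sl@lines[[i]][nrow(sl@lines[[i]]), ]
    ijk <- round((tp - mask@origin) / mask@spacing) + 1
    ijk <- pmin(pmax(ijk, 1), d)
    xs <- max(1, ijk[1] - dilate):min(d[1], ijk[1] + dilate)
    ys <- max(1, ijk[2] - dilate):min(d[2], ijk[2] + dilate)
    zs <- max(1, ijk[3] - dilate):min(d[3], ijk[3] + dilate)
    nb <- array(mask@labels[xs, ys, zs],
                dim = c(length(xs), length(ys), length(zs)))
    hit <- which(array(nb %in% ids, dim = dim(nb)), arr.ind = TRUE)
    if (nrow(hit)) {
      cx <- cbind(xs[hit[, 1]], ys[hit[, 2]], zs[hit[, 3]])
      d2 <- rowSums(sweep(cx, 2, ijk, "-")^2)
      lab <- mask@labels[cx[which.min(d2), , drop = FALSE]]
      labels[i] <- outletSegments[match(lab, ids)]
    }
  }
  resolved <- labels %in% outletSegments
  dist <- if (any(resolved)) {
    tab <- vapply(outletSegments, function(s) sum(labels == s), numeric(1))
    pct <- 100 * tab / sum(tab)
    ## exact normalization: the last outlet is the complement, so the
    ## percentages over resolved lines sum to 100
    k <- length(pct)
    if (k > 1L) pct[k] <- 100 - sum(pct[-k])
    stats::setNames(pct, outletSegments)
  } else numeric(0)
  new("StreamlineSet", lines = sl@lines, seedVessel = sl@seedVessel,
      status = sl@status, outletLabels = labels, distribution = dist,
      unresolvedPct = 100 * mean(!resolved))
}

#' Caval flow distribution in one call
#'
#' Traces streamlines from a seed plane and classifies their pulmonary
#' outlet: the quantity reported per caval vessel (percent of resolved
#' streamlines reaching RPA vs LPA).
#'
#' @inheritParams traceStreamlines
#' @inheritParams classifyOutlets
#' @return a classified \linkS4class{StreamlineSet}.
#' @export
cavalDistribution <- function(field, mask, seedPlane, nSeeds = 500L,
                              outletSegments = c("RPA", "LPA"),
                              seed = NULL, ...) {
  sl <- traceStreamlines(field, mask, seedPlane, nSeeds = nSeeds,
                         seed = seed, ...)
  classifyOutlets(sl, mask, outletSegments = outletSegments)
}

#' Export streamlines as a legacy VTK polyline file
#'
#' Writes an ASCII VTK polydata file for external viewers.
#'
#' @param sl a \linkS4class{StreamlineSet}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStreamlinesVTK <- function(sl, path) {
  npts <- vapply(sl@lines, nrow, integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "streamlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", sum(npts))), con)
  pts <- do.call(rbind, sl@lines)
  utils::write.table(format(pts, trim = TRUE), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("LINES %d %d", length(npts), sum(npts) + length(npts)),
             con)
  off <- cumsum(c(0, npts[-length(npts)]))
  for (i in seq_along(npts))
    writeLines(paste(c(npts[i], seq(off[i], length.out = npts[i])),
                     collapse = " "), con)
  invisible(path)
}
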