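test_that("Poiseuille energetics match their closed forms", {
  ph <- refPoiseuille()
  tr <- groundTruth(ph)
  voi <- voiFromSegments(ph@mask, "tube")
  en <- suppressWarnings(energetics(ph@field, ph@mask, voi))
  expect_equal(keNorm(en), tr$keNorm, tolerance = 0.03)      # rho vmax^2/6
  expect_equal(elNorm(en), tr$elNorm, tolerance = 0.05)      # 2 mu vmax^2/R^2
  expect_equal(elKeIndex(en), tr$elKeIndex, tolerance = 0.05)
  expect_equal(elKeIndex(en), elNorm(en) / keNorm(en), tolerance = 1e-12)
  expect_error(kineticEnergy(ph@field,
                             new("VolumeOfInterest", indices = integer(0),
                                 gridDim = gridDim(ph@mask),
                                 volumeMl = 0)),
               "empty volume of interest")
})

test_that("KE scales quadratically and EL/KE is invariant to velocity scale", {
  ph <- refPoiseuille()
  voi <- voiFromSegments(ph@mask, "tube")
  en1 <- suppressWarnings(energetics(ph@field, ph@mask, voi))
  doubled <- velocityField4D(ph@field@velocities * 2,
                             spacing = spacing(ph@field),
                             origin = gridOrigin(ph@field))
  en2 <- suppressWarnings(energetics(doubled, ph@mask, voi))
  expect_equal(keNorm(en2), 4 * keNorm(en1), tolerance = 1e-6)
  expect_equal(elNorm(en2), 4 * elNorm(en1), tolerance = 1e-6)
  expect_equal(elKeIndex(en2), elKeIndex(en1), tolerance = 0.01)
})

test_that("EL/KE scales as 1/R^2 (halving the radius quadruples the index)", {
  en10 <- suppressWarnings({
    ph <- refPoiseuille()
    energetics(ph@field, ph@mask, voiFromSegments(ph@mask, "tube"))
  })
  en5 <- suppressWarnings({
    ph <- fixture("poiseuilleR5",
                  poiseuillePhantom(radius = 5, length = 40, vmax = 60,
                                    spacing = 0.5))
    energetics(ph@field, ph@mask, voiFromSegments(ph@mask, "tube"))
  })
  expect_equal(elKeIndex(en5) / elKeIndex(en10), 4, tolerance = 0.06)
})

test_that("zero-strain fields dissipate nothing", {
  ph <- refPoiseuille()
  voi <- voiFromSegments(ph@mask, "tube")
  uni <- uniformTubeField(speed = 30)
  expect_identical(elNorm(suppressWarnings(energyLoss(uni, ph@mask, voi))), 0)
  rot <- rotationField(n = 41, omega = 2)
  voiR <- voiFromSegments(rot$mask)
  elRot <- elNorm(energyLoss(rot$field, rot$mask, voiR))
  expect_lt(elRot, 1e-3 * groundTruth(ph)$elNorm)
})

test_that("strain-rate dissipation matches a brute-force voxel loop", {
  set.seed(8)
  d <- c(5, 5, 5)
  vel <- array(rnorm(prod(d) * 3), dim = c(d, 3, 1))
  lab <- array(0L, d)
  lab[sample(prod(d), 80)] <- 1L
  field <- velocityField4D(vel, spacing = c(1, 2, 1.5))
  mask <- lumenMask(lab, c(lumen = 1L), spacing = c(1, 2, 1.5))
  idx <- which(lab > 0L)
  voi <- new("VolumeOfInterest", indices = as.integer(idx),
             gridDim = as.integer(d), volumeMl = length(idx) * 3 / 1000)
  got <- suppressWarnings(energyLoss(field, mask, voi))

  ## independent oracle: explicit loops over voxels, axes and components
  mu <- 3.5e-3
  deltas <- c(1, 2, 1.5) / 1000
  lum <- lab > 0L
  g <- function(i, j, k, comp, axis) {       # dv_comp/dx_axis or NA
    at <- function(ii, jj, kk) {
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        return(NULL)
      if (!lum[ii, jj, kk]) return(NULL)
      vel[ii, jj, kk, comp, 1] / 100
    }
    step <- c(0, 0, 0); step[axis] <- 1
    up <- at(i + step[1], j + step[2], k + step[3])
    dn <- at(i - step[1], j - step[2], k - step[3])
    self <- vel[i, j, k, comp, 1] / 100
    if (!is.null(up) && !is.null(dn)) (up - dn) / (2 * deltas[axis])
    else if (!is.null(up)) (up - self) / deltas[axis]
    else if (!is.null(dn)) (self - dn) / deltas[axis]
    else NA_real_
  }
  phis <- c()
  for (lin in idx) {
    ijk <- arrayInd(lin, d)
    i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
    G <- matrix(NA_real_, 3, 3)
    for (comp in 1:3) for (axis in 1:3)
      G[comp, axis] <- g(i, j, k, comp, axis)
    if (any(is.na(G))) next                  # isolated along some axis
    e <- (G + t(G)) / 2
    phis <- c(phis, 2 * mu * sum(e * e))
  }
  expect_equal(elNorm(got), mean(phis), tolerance = 1e-12)
})

test_that("EL discretization error shrinks with the grid", {
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    ph <- poiseuillePhantom(radius = 10, length = 20, vmax = 60,
                            spacing = sp)
    voi <- voiFromSegments(ph@mask, "tube")
    el <- elNorm(suppressWarnings(energyLoss(ph@field, ph@mask, voi)))
    abs(el - groundTruth(ph)$elNorm) / groundTruth(ph)$elNorm
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("jet angle, eccentricity and WSS recover phantom ground truth", {
  ph <- refPoiseuille()
  sh <- sectionShape(ph@field, ph@mask, ph@planes$tube)
  expect_lt(sh@jetAngle, 0.5)
  expect_lt(sh@eccentricity, 0.01)
  expect_equal(sh@wssMean, groundTruth(ph)$wssMean, tolerance = 0.15)

  tilt <- fixture("jet30", tiltedJetPhantom(tiltDeg = 30))
  shT <- sectionShape(tilt@field, tilt@mask, tilt@planes$tube)
  expect_equal(shT@jetAngle, 30, tolerance = 2 / 30)

  for (off in c(0.1, 0.2, 0.3)) {
    phO <- tiltedJetPhantom(offsetFraction = off)
    shO <- sectionShape(phO@field, phO@mask, phO@planes$tube)
    expect_lt(abs(shO@eccentricity - off), 0.02)
  }
  expect_error(
    sectionShape(ph@field, ph@mask,
                 analysisPlane(c(0, 0, 300), c(0, 0, 1), 5)),
    "empty section")
})

test_that("combineEnergetics flags an undefined index on a still field", {
  ph <- refPoiseuille()
  voi <- voiFromSegments(ph@mask, "tube")
  still <- velocityField4D(array(0, dim(ph@field@velocities)),
                           spacing = spacing(ph@field),
                           origin = gridOrigin(ph@field))
  ke <- kineticEnergy(still, voi)
  el <- suppressWarnings(energyLoss(still, ph@mask, voi))
  expect_identical(keNorm(ke), 0)
  expect_warning(res <- combineEnergetics(ke, el), "undefined index")
  expect_true(is.na(elKeIndex(res)))
})
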