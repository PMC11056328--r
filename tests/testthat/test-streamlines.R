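test_that("uniform advection carries all lines straight down the tube", {
  ph <- refPoiseuille()
  f <- uniformTubeField(speed = 30)
  sl <- traceStreamlines(f, ph@mask, ph@planes$tube, nSeeds = 60, seed = 2)
  expect_true(all(sl@status == "exited"))
  for (m in sl@lines) {
    ## paths parallel to the axis: lateral drift below 1e-3 rad
    lat <- max(abs(m[, 1] - m[1, 1]), abs(m[, 2] - m[1, 2]))
    run <- abs(m[nrow(m), 3] - m[1, 3])
    expect_lt(lat / run, 1e-3)
    expect_gt(m[nrow(m), 3], 39)          # downstream end of the tube
  }
  ## every line starts on the seed plane
  starts <- t(vapply(sl@lines, function(m) m[1, ], numeric(3)))
  expect_lt(max(abs(starts[, 3] - 20)), 1e-9)
})

test_that("a zero field stalls every line and flags the distribution", {
  ph <- refPoiseuille()
  f <- velocityField4D(array(0, dim(ph@field@velocities)),
                       spacing = spacing(ph@field),
                       origin = gridOrigin(ph@field))
  sl <- traceStreamlines(f, ph@mask, ph@planes$tube, nSeeds = 20, seed = 5)
  expect_true(all(sl@status == "stalled"))
  cls <- classifyOutlets(sl, ph@mask, outletSegments = "tube")
  expect_length(distribution(cls), 0)
  expect_equal(cls@unresolvedPct, 100)
})

test_that("rigid rotation orbits stay on their radius (integrator accuracy)", {
  rot <- rotationField(n = 41, omega = 2)
  pl <- analysisPlane(c(0, 0, 0), c(0, 0, 1), 15, "seed")
  sl <- traceStreamlines(rot$field, rot$mask, pl, nSeeds = 25, seed = 3,
                         maxLength = 130)
  for (m in sl@lines) {
    r <- sqrt(rowSums(m[, 1:2, drop = FALSE]^2))
    if (r[1] < 2) next                     # arc length cap, not one turn
    len <- sum(sqrt(rowSums(diff(m)^2)))
    expect_gt(len, 2 * pi * r[1] * 0.99)   # at least one revolution
    expect_lt(max(abs(r - r[1])) / r[1], 0.005)
  }
})

test_that("streamline tracing is bit-for-bit deterministic per seed", {
  ph <- refTcpc()
  s1 <- traceStreamlines(ph@field, ph@mask, ph@planes$IVC, nSeeds = 50,
                         seed = 17)
  s2 <- traceStreamlines(ph@field, ph@mask, ph@planes$IVC, nSeeds = 50,
                         seed = 17)
  expect_identical(s1@lines, s2@lines)
  expect_identical(s1@status, s2@status)
})

test_that("caval splits are recovered and percentages normalize exactly", {
  ph <- refTcpc()                          # IVC->LPA 0.75, SVC->RPA 0.9
  ivc <- cavalDistribution(ph@field, ph@mask, ph@planes$IVC,
                           nSeeds = 800, seed = 21)
  expect_equal(unname(distribution(ivc)["LPA"]), 75, tolerance = 6 / 75)
  expect_equal(sum(distribution(ivc)), 100, tolerance = 1e-12)
  svc <- cavalDistribution(ph@field, ph@mask, ph@planes$SVC,
                           nSeeds = 800, seed = 22)
  expect_equal(unname(distribution(svc)["RPA"]), 90, tolerance = 6 / 90)
  sym <- refTcpcSymmetric()
  d <- distribution(cavalDistribution(sym@field, sym@mask, sym@planes$IVC,
                                      nSeeds = 800, seed = 23))
  expect_equal(unname(d["LPA"]), 50, tolerance = 5 / 50)
  expect_error(
    classifyOutlets(ivc, ph@mask, outletSegments = c("RPA", "nonesuch")),
    "configuration error")
})

test_that("complete separation routes each cava to its own artery", {
  ph <- fixture("tcpcFull", tcpcPhantom(splitIvcLpa = 1, splitSvcRpa = 1))
  ivc <- cavalDistribution(ph@field, ph@mask, ph@planes$IVC,
                           nSeeds = 400, seed = 31)
  svc <- cavalDistribution(ph@field, ph@mask, ph@planes$SVC,
                           nSeeds = 400, seed = 32)
  expect_gte(unname(distribution(ivc)["LPA"]), 95)
  expect_gte(unname(distribution(svc)["RPA"]), 95)
})

test_that("distribution converges with seed count and lines respect the lumen", {
  ph <- refTcpcSymmetric()
  d1 <- distribution(cavalDistribution(ph@field, ph@mask, ph@planes$IVC,
                                       nSeeds = 300, seed = 41))
  d2 <- distribution(cavalDistribution(ph@field, ph@mask, ph@planes$IVC,
                                       nSeeds = 1500, seed = 42))
  expect_lt(abs(d1["LPA"] - d2["LPA"]), 3)
  ## no traced point occupies a background voxel beyond the tolerance
  sl <- traceStreamlines(ph@field, ph@mask, ph@planes$IVC, nSeeds = 100,
                         seed = 43)
  dil <- fontanflow:::dilateMask(ph@mask@labels > 0L, 2L)
  pts <- do.call(rbind, sl@lines)
  ijk <- fontanflow:::nearestVoxel(ph@mask, pts)
  ok <- !is.na(ijk[, 1])
  lin <- (ijk[ok, 3] - 1) * prod(gridDim(ph@mask)[1:2]) +
    (ijk[ok, 2] - 1) * gridDim(ph@mask)[1] + ijk[ok, 1]
  expect_true(all(dil[lin]))
})

test_that("flux-weighted seeding concentrates seeds in the fast core", {
  ph <- refPoiseuille()
  su <- traceStreamlines(ph@field, ph@mask, ph@planes$tube, nSeeds = 300,
                         seed = 6)
  sf <- traceStreamlines(ph@field, ph@mask, ph@planes$tube, nSeeds = 300,
                         seedWeighting = "flux_weighted", seed = 6)
  radius0 <- function(sl) mean(vapply(sl@lines, function(m)
    sqrt(sum(m[1, 1:2]^2)), numeric(1)))
  ## parabolic weighting pulls the mean seed radius well inside uniform
  expect_lt(radius0(sf), 0.9 * radius0(su))
})

test_that("an off-lumen seed plane is rejected", {
  ph <- refPoiseuille()
  pl <- analysisPlane(c(0, 0, -50), c(0, 0, 1), 5, "outside")
  expect_error(traceStreamlines(ph@field, ph@mask, pl, nSeeds = 10, seed = 1),
               "empty seed section")
})
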