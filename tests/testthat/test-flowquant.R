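test_that("plane flux recovers the Poiseuille flow rate", {
  ph <- refPoiseuille()
  fl <- planeFlux(ph@field, ph@mask, ph@planes$tube)
  expect_equal(qNet(fl), groundTruth(ph)$qLmin, tolerance = 0.02)
  expect_equal(meanVelocity(fl), 30, tolerance = 0.05)
})

test_that("flux is antisymmetric under normal flip and linear in the field", {
  ph <- refPoiseuille()
  pl <- ph@planes$tube
  flipped <- analysisPlane(pl@origin, -pl@normal, pl@radius, pl@vessel)
  q1 <- qNet(planeFlux(ph@field, ph@mask, pl))
  q2 <- qNet(planeFlux(ph@field, ph@mask, flipped))
  expect_identical(q1, -q2)
  scaled <- velocityField4D(ph@field@velocities * 2.5,
                            spacing = spacing(ph@field),
                            origin = gridOrigin(ph@field))
  q3 <- qNet(planeFlux(scaled, ph@mask, pl))
  expect_equal(q3, 2.5 * q1, tolerance = 1e-9)
})

test_that("uniform axial flow reproduces the imposed speed and area flux", {
  ph <- refPoiseuille()
  f <- uniformTubeField(speed = 30)
  fl <- planeFlux(f, ph@mask, ph@planes$tube)
  expect_equal(meanVelocity(fl), 30, tolerance = 0.01 * 30)
  ## flux = speed * pi R^2 (30 cm/s through R = 10 mm)
  expect_equal(qNet(fl), 0.3 * pi * 0.01^2 * 6e4, tolerance = 0.02)
})

test_that("flux is stable along the tube and under raster refinement", {
  ph <- refPoiseuille()
  pl <- ph@planes$tube
  qMid <- qNet(planeFlux(ph@field, ph@mask, pl))
  shifted <- analysisPlane(pl@origin + c(0, 0, 8), pl@normal, pl@radius)
  qShift <- qNet(planeFlux(ph@field, ph@mask, shifted))
  expect_lt(abs(qShift - qMid) / qMid, 0.01)
  qFine <- qNet(planeFlux(ph@field, ph@mask, pl, raster = 0.25))
  expect_lt(abs(qFine - qMid) / qMid, 0.005)
})

test_that("planes outside the lumen are rejected", {
  ph <- refPoiseuille()
  outPlane <- analysisPlane(c(0, 0, 200), c(0, 0, 1), 5)
  expect_error(planeFlux(ph@field, ph@mask, outPlane), "empty section")
})

test_that("QSPC and effective CI reproduce the stated arithmetic", {
  dc <- qspc(1.4, 1.6, 1.2, 1.0, bsa = 1.6)
  expect_equal(dc@qspc, 0.8)
  expect_equal(dc@qspcIndexed, 0.5)
  expect_equal(qspc(1.2, 1.3, 1.2, 1.3)@qspc, 0)      # PV flows equal PA flows
  expect_error(qspc(NULL, 1, 1, 1), "missing vessel")
  expect_equal(effectiveCi(5.0, 0.8, 1.5), 2.8)
  expect_equal(effectiveCi(4.2, 0, 1.5), 4.2 / 1.5)
  expect_equal(effectiveCi(3.1, 3.1, 1.4), 0)
  expect_error(effectiveCi(5, 0.8, 0), "bsa")
})

test_that("branch asymmetry classification follows the printed thresholds", {
  expect_equal(classifyAsymmetry(1.26, 1)@asymmetryClass, "symmetric")
  expect_equal(classifyAsymmetry(1.56, 1)@asymmetryClass, "symmetric")
  expect_equal(classifyAsymmetry(1.561, 1)@asymmetryClass, "rpa_dominant")
  expect_equal(classifyAsymmetry(0.70, 1)@asymmetryClass, "lpa_dominant")
  expect_equal(classifyAsymmetry(0.75, 1)@asymmetryClass, "symmetric")
  expect_error(classifyAsymmetry(1, 0), "degenerate ratio")
})

test_that("QSPC recovers an injected collateral flow from measured planes", {
  ## pulmonary venous return carries the arterial flow plus half the
  ## aortopulmonary collateral inflow per side; all four vessels are
  ## measured with the same plane-flux instrument (Poiseuille tube sections
  ## carrying the prescribed flows), as in a single CMR modality
  tr <- groundTruth(refTcpc())
  collateral <- 0.6                                     # l/min
  measureTube <- function(qTrue) {
    vmax <- qTrue / 6e4 / (pi * 0.008^2 / 2) * 100      # cm/s for R = 8 mm
    tube <- poiseuillePhantom(radius = 8, length = 24, vmax = vmax)
    planeFlux(tube@field, tube@mask, tube@planes$tube)
  }
  est <- qspc(measureTube(tr$qLpa + collateral / 2),
              measureTube(tr$qRpa + collateral / 2),
              measureTube(tr$qRpa), measureTube(tr$qLpa))@qspc
  expect_equal(est, collateral, tolerance = 0.03)
})
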