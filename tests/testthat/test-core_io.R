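test_that("velocity field containers enforce their invariants", {
  vel <- array(0, c(4, 4, 4, 3, 2))
  f <- velocityField4D(vel, spacing = c(1, 2, 1), phaseDuration = 0.05)
  expect_identical(gridDim(f), c(4L, 4L, 4L))
  expect_identical(nPhases(f), 2L)
  expect_error(velocityField4D(array(0, c(4, 4, 4, 2, 2))), "3 components")
  expect_error(velocityField4D(vel, spacing = c(0, 1, 1)), "positive")
  bad <- vel; bad[1] <- NaN
  expect_error(velocityField4D(bad), "finite")
  expect_error(analysisPlane(c(0, 0, 0), c(0, 0, 0), 5), "non-zero")
  pl <- analysisPlane(c(0, 0, 0), c(0, 0, 2), 5)   # normalized internally
  expect_equal(sqrt(sum(pl@normal^2)), 1, tolerance = 1e-12)
  expect_error(new("AnalysisPlane", origin = c(0, 0, 0),
                   normal = c(0, 0, 1), radius = -1), "radius")
  expect_error(lumenMask(array(0L, c(3, 3, 3)), c(SVC = 2L)), "no voxels")
})

test_that("HDF5 round trip is exact and NIfTI round trip is lossless for doubles", {
  ph <- poiseuillePhantom(radius = 6, length = 16, vmax = 45,
                          nPhases = 3, pulsatility = 0.25)
  tmp <- withr::local_tempdir()
  h5 <- file.path(tmp, "f.h5")
  writeVelocityField(ph@field, h5, "hdf5")
  back <- readVelocityField(h5, "hdf5")
  expect_identical(back@velocities, ph@field@velocities)
  expect_identical(back@spacing, ph@field@spacing)
  expect_equal(back@phaseDuration, ph@field@phaseDuration)

  nb <- file.path(tmp, "f")
  writeVelocityField(ph@field, nb, "nifti")
  back2 <- readVelocityField(nb, "nifti")
  expect_equal(max(abs(back2@velocities - ph@field@velocities)), 0)
  expect_equal(back2@origin, ph@field@origin)
  expect_equal(back2@spacing, ph@field@spacing)
})

test_that("mask and plane configs survive a round trip in both formats", {
  ph <- refTcpc()
  tmp <- withr::local_tempdir()
  for (fmt in c("hdf5", "nifti")) {
    p <- file.path(tmp, paste0("m.", if (fmt == "hdf5") "h5" else "nii.gz"))
    writeLumenMask(ph@mask, p, fmt)
    back <- readLumenMask(p, fmt)
    expect_identical(as.integer(back@labels), as.integer(ph@mask@labels))
    expect_identical(back@segments, ph@mask@segments)
  }
  py <- file.path(tmp, "planes.yaml")
  writePlanes(ph@planes, py)
  back <- readPlanes(py)
  expect_named(back, names(ph@planes))
  expect_equal(back$IVC@origin, ph@planes$IVC@origin)
  expect_equal(back$RPA@normal, ph@planes$RPA@normal)
})

test_that("incomplete or inconsistent field files are rejected by name", {
  tmp <- withr::local_tempdir()
  ph <- poiseuillePhantom(radius = 5, length = 10, vmax = 20)
  ## HDF5 with a missing component
  h5 <- file.path(tmp, "bad.h5")
  rhdf5::h5createFile(h5)
  rhdf5::h5createGroup(h5, "vel")
  a <- ph@field@velocities[, , , 1, ]
  dim(a) <- dim(ph@field@velocities)[c(1:3, 5)]
  rhdf5::h5write(a, h5, "vel/x")
  rhdf5::h5write(a, h5, "vel/y")
  rhdf5::h5closeAll()
  expect_error(readVelocityField(h5, "hdf5"), "incomplete field")
  ## NIfTI with 2 of 3 component files
  nb <- file.path(tmp, "f")
  writeVelocityField(ph@field, nb, "nifti")
  unlink(file.path(tmp, "f_vz.nii.gz"))
  expect_error(readVelocityField(nb, "nifti"), "incomplete field")
  ## inconsistent component shapes
  h52 <- file.path(tmp, "bad2.h5")
  rhdf5::h5createFile(h52)
  rhdf5::h5createGroup(h52, "vel")
  rhdf5::h5write(a, h52, "vel/x")
  rhdf5::h5write(a, h52, "vel/y")
  rhdf5::h5write(a[1:3, , , , drop = FALSE], h52, "vel/z")
  fid <- rhdf5::H5Fopen(h52); gid <- rhdf5::H5Gopen(fid, "vel")
  rhdf5::h5writeAttribute(c(1, 1, 1), gid, "spacing")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid); rhdf5::h5closeAll()
  expect_error(readVelocityField(h52, "hdf5"), "inconsistent grid")
})

test_that("the pipeline runs a phantom subject end to end and is deterministic", {
  tmp <- withr::local_tempdir()
  writePhantom(refTcpc(), file.path(tmp, "ph"), "hdf5")
  subj <- function(id) list(
    id = id,
    field = list(path = file.path(tmp, "ph", "field.h5"), format = "hdf5"),
    mask = list(path = file.path(tmp, "ph", "mask.h5"), format = "hdf5"),
    planes = file.path(tmp, "ph", "planes.yaml"),
    bsa = 1.5,
    streamlines = list(seeds = list("IVC"), n = 150),
    voi = list(segments = list("confluence")),
    shape = list("IVC"))
  cfg <- list(output_dir = file.path(tmp, "out"), seed = 11,
              subjects = list(subj("A"), subj("B")))
  res <- suppressWarnings(runPipeline(cfg))
  expect_true(all(c("flows", "streamlines", "energetics", "shape") %in%
                    names(res)))
  expect_true(file.exists(file.path(tmp, "out", "flows.csv")))
  ## identical subjects give identical rows
  fa <- res$flows[res$flows$subject == "A", -1]
  fb <- res$flows[res$flows$subject == "B", -1]
  rownames(fa) <- rownames(fb) <- NULL
  expect_identical(fa, fb)
  sa <- res$streamlines[res$streamlines$subject == "A", -1]
  sb <- res$streamlines[res$streamlines$subject == "B", -1]
  rownames(sa) <- rownames(sb) <- NULL
  expect_identical(sa, sb)
  ## output invariant under subject order
  cfg2 <- cfg
  cfg2$subjects <- rev(cfg2$subjects)
  cfg2$output_dir <- file.path(tmp, "out2")
  res2 <- suppressWarnings(runPipeline(cfg2))
  ord <- order(res2$flows$subject, res2$flows$vessel)
  ref <- order(res$flows$subject, res$flows$vessel)
  expect_equal(res$flows[ref, ], res2$flows[ord, ], ignore_attr = TRUE)
  ## configuration errors name the missing key
  cfgBad <- cfg
  cfgBad$subjects[[1]]$planes <- NULL
  expect_error(runPipeline(cfgBad), "'planes'")
  expect_error(runPipeline(list(output_dir = tmp)), "'subjects'")
})
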