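## Readers and writers for velocity fields (NIfTI, HDF5), lumen masks,
## analysis-plane configurations (YAML) and cohort tables (CSV).
##
## HDF5 layout: datasets /vel/x, /vel/y, /vel/z (one per component, phases
## in the last dimension), group attributes `spacing` (mm), `origin` (mm)
## and `phase_duration` (s); masks as /mask with `segment_names` /
## `segment_ids` attributes. NIfTI: one 4D file per component with suffixes
## _vx, _vy, _vz, spacing and time step in pixdim, origin in the sform
## (honored on read; only axis-aligned affines are supported).

.niftiComponentFiles <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, c("_vx", "_vy", "_vz"), ".nii.gz")
}

#' Write a velocity field
#'
#' @param field a \linkS4class{VelocityField4D}.
#' @param path output path. For HDF5 a single file; for NIfTI the base name
#'   from which the three component files \code{<base>_vx.nii.gz} etc. are
#'   derived.
#' @param format "hdf5" or "nifti".
#' @param dtype storage type: "double" (lossless) or "float".
#' @return the path, invisibly.
#' @export
writeVelocityField <- function(field, path, format = c("hdf5", "nifti"),
                               dtype = c("double", "float")) {
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  d <- dim(field@velocities)
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "vel")
    for (i in 1:3) {
      a <- field@velocities[, , , i, ]
      dim(a) <- d[c(1:3, 5)]
      rhdf5::h5write(a, path, c("vel/x", "vel/y", "vel/z")[i])
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "vel")
    rhdf5::h5writeAttribute(field@spacing, gid, "spacing")
    rhdf5::h5writeAttribute(field@origin, gid, "origin")
    rhdf5::h5writeAttribute(field@phaseDuration, gid, "phase_duration")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else {
    files <- .niftiComponentFiles(path)
    aff <- diag(c(field@spacing, 1))
    aff[1:3, 4] <- field@origin
    for (i in 1:3) {
      a <- field@velocities[, , , i, ]
      dim(a) <- d[c(1:3, 5)]
      img <- RNifti::asNifti(a)
      RNifti::pixdim(img) <- c(field@spacing, field@phaseDuration)
      RNifti::sform(img) <- structure(aff, code = 2L)
      RNifti::qform(img) <- structure(aff, code = 2L)
      RNifti::writeNifti(img, files[i], datatype = dtype)
    }
  }
  invisible(path)
}

#' Read a velocity field
#'
#' @param path file path (HDF5) or NIfTI base name as in
#'   [writeVelocityField()].
#' @param format "hdf5" or "nifti".
#' @return a \linkS4class{VelocityField4D} with velocities in cm/s, spacing
#'   in mm, components ordered (x, y, z).
#' @export
readVelocityField <- function(path, format = c("hdf5", "nifti")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    if (!file.exists(path)) stop("file not found: ", path)
    contents <- rhdf5::h5ls(path)
    have <- paste0(contents$group, "/", contents$name)
    need <- c("/vel/x", "/vel/y", "/vel/z")
    if (!all(need %in% have))
      stop("incomplete field: missing component dataset(s) ",
           paste(setdiff(need, have), collapse = ", "))
    comps <- lapply(need, function(ds) rhdf5::h5read(path, ds))
    att <- rhdf5::h5readAttributes(path, "vel")
    rhdf5::h5closeAll()
    spacing <- as.numeric(att$spacing)
    origin <- as.numeric(att$origin %||% c(0, 0, 0))
    pd <- as.numeric(att$phase_duration %||% 1)
  } else {
    files <- .niftiComponentFiles(path)
    if (!all(file.exists(files)))
      stop("incomplete field: missing component file(s) ",
           paste(files[!file.exists(files)], collapse = ", "))
    imgs <- lapply(files, RNifti::readNifti)
    comps <- lapply(imgs, function(i) as.array(i))
    pd4 <- RNifti::pixdim(imgs[[1]])
    spacing <- pd4[1:3]
    pd <- if (length(pd4) >= 4 && pd4[4] > 0) pd4[4] else 1
    xf <- RNifti::xform(imgs[[1]])
    rot <- abs(xf[1:3, 1:3]) - diag(abs(diag(xf[1:3, 1:3])))
    if (max(abs(rot)) > 1e-6 * max(abs(xf[1:3, 1:3])))
      stop("unsupported orientation: affine is not axis-aligned")
    origin <- xf[1:3, 4]
  }
  shapes <- vapply(comps, function(a) paste(dim(a), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("inconsistent grid: component shapes ",
         paste(shapes, collapse = " vs "))
  d <- dim(comps[[1]])
  if (length(d) == 3L) d <- c(d, 1L)
  np <- d[4]
  vel <- array(0, dim = c(d[1:3], 3, np))
  for (i in 1:3) {
    a <- comps[[i]]
    dim(a) <- d
    vel[, , , i, ] <- a
  }
  new("VelocityField4D", velocities = vel, spacing = spacing,
      origin = origin, phaseDuration = pd)
}

#' Write a lumen mask
#'
#' @param mask a \linkS4class{LumenMask}.
#' @param path output path (HDF5 file, or NIfTI file; for NIfTI segment
#'   names go to a YAML sidecar \code{<base>_segments.yaml}).
#' @param format "hdf5" or "nifti".
#' @return the path, invisibly.
#' @export
writeLumenMask <- function(mask, path, format = c("hdf5", "nifti")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    if (!file.exists(path)) rhdf5::h5createFile(path)
    rhdf5::h5write(mask@labels, path, "mask")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "mask")
    rhdf5::h5writeAttribute(names(mask@segments), did, "segment_names")
    rhdf5::h5writeAttribute(as.integer(mask@segments), did, "segment_ids")
    rhdf5::h5writeAttribute(mask@spacing, did, "spacing")
    rhdf5::h5writeAttribute(mask@origin, did, "origin")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else {
    aff <- diag(c(mask@spacing, 1))
    aff[1:3, 4] <- mask@origin
    img <- RNifti::asNifti(mask@labels)
    RNifti::pixdim(img) <- mask@spacing
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path, datatype = "int16")
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_segments.yaml")
    yaml::write_yaml(as.list(mask@segments), side)
  }
  invisible(path)
}

#' Read a lumen mask
#'
#' @param path path written by [writeLumenMask()].
#' @param format "hdf5" or "nifti".
#' @return a \linkS4class{LumenMask}.
#' @export
readLumenMask <- function(path, format = c("hdf5", "nifti")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    labels <- rhdf5::h5read(path, "mask")
    att <- rhdf5::h5readAttributes(path, "mask")
    rhdf5::h5closeAll()
    segs <- stats::setNames(as.integer(att$segment_ids),
                            as.character(att$segment_names))
    lumenMask(labels, segs, spacing = as.numeric(att$spacing),
              origin = as.numeric(att$origin))
  } else {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_segments.yaml")
    segs <- if (file.exists(side)) {
      s <- yaml::read_yaml(side)
      stats::setNames(as.integer(unlist(s)), names(s))
    } else NULL
    labels <- array(as.integer(img), dim = dim(img))
    lumenMask(labels, segs, spacing = RNifti::pixdim(img)[1:3],
              origin = xf[1:3, 4])
  }
}

#' Read analysis planes from a YAML config
#'
#' The file holds a list of entries with fields \code{vessel},
#' \code{origin} (mm), \code{normal} and \code{radius} (mm).
#'
#' @param path YAML file path.
#' @return named list of \linkS4class{AnalysisPlane} objects.
#' @export
readPlanes <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("configuration error: no planes in ", path)
  planes <- lapply(cfg, function(p) {
    for (f in c("origin", "normal", "radius"))
      if (is.null(p[[f]]))
        stop("configuration error: plane entry missing '", f, "'")
    analysisPlane(as.numeric(p$origin), as.numeric(p$normal),
                  as.numeric(p$radius), p$vessel %||% "")
  })
  names(planes) <- vapply(planes, function(p) p@vessel, character(1))
  planes
}

#' Write analysis planes to YAML
#'
#' @param planes list of \linkS4class{AnalysisPlane} objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePlanes <- function(planes, path) {
  yaml::write_yaml(lapply(planes, function(p)
    list(vessel = p@vessel, origin = as.numeric(p@origin),
         normal = as.numeric(p@normal), radius = as.numeric(p@radius))),
    path)
  invisible(path)
}

#' Read a cohort covariate table
#'
#' CSV with a header row, one row per subject. Empty cells and the explicit
#' sentinel "NA" are missing values (never silently zero).
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readCohortTable <- function(path) {
  utils::read.csv(path, header = TRUE, na.strings = c("", "NA"),
                  stringsAsFactors = FALSE)
}

#' Write a phantom to disk
#'
#' Writes field, mask, planes YAML and the ground-truth record
#' (\code{ground_truth.json}) into a directory.
#'
#' @param phantom a \linkS4class{FlowPhantom}.
#' @param dir output directory (created if absent).
#' @param format "hdf5" or "nifti" for field and mask.
#' @return \code{dir}, invisibly.
#' @export
writePhantom <- function(phantom, dir, format = c("hdf5", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "hdf5") {
    writeVelocityField(phantom@field, file.path(dir, "field.h5"), "hdf5")
    writeLumenMask(phantom@mask, file.path(dir, "mask.h5"), "hdf5")
  } else {
    writeVelocityField(phantom@field, file.path(dir, "field"), "nifti")
    writeLumenMask(phantom@mask, file.path(dir, "mask.nii.gz"), "nifti")
  }
  writePlanes(phantom@planes, file.path(dir, "planes.yaml"))
  truth <- phantom@truth
  truth$kind <- phantom@kind
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
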