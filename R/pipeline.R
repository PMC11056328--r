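## End-to-end per-subject pipeline: read field/mask/planes, quantify flows,
## derived circulation parameters, caval streamline distribution and
## confluence energetics, and write tidy CSV tables.

.planeOrStop <- function(planes, name, what, id) {
  if (is.null(planes[[name]]))
    stop(sprintf("subject %s: %s plane '%s' not defined", id, what, name))
  planes[[name]]
}

.stage <- function(id, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("subject %s, stage %s: %s", id, stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full hemodynamic pipeline
#'
#' Executes every configured stage for each subject — plane fluxes, derived
#' circulation parameters (QSPC, effective CI, branch asymmetry), caval
#' streamline distribution, volume-of-interest energetics and section shape
#' metrics — and writes one tidy CSV per stage into the output directory.
#' Deterministic for a fixed seed; subjects are processed independently, so
#' output rows do not depend on subject order.
#'
#' Config keys (YAML file or equivalent list): \code{output_dir},
#' \code{seed}, and \code{subjects}, each subject holding \code{id},
#' \code{field} (\code{path}, \code{format}), \code{mask}, \code{planes}
#' (YAML path), optional \code{bsa}, \code{voi} (\code{segments}),
#' \code{streamlines} (\code{seeds}, \code{outlets}, \code{n}),
#' \code{derived} (plane names \code{lpv}, \code{rpv}, \code{rpa},
#' \code{lpa}, optional \code{ao}) and \code{shape} (plane names).
#'
#' @param config path to a YAML pipeline config, or the equivalent list.
#' @param outDir overrides \code{output_dir}.
#' @param seed overrides the config seed.
#' @return invisibly, a named list of the result data.frames.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("subjects"))
    if (is.null(cfg[[key]]))
      stop("configuration error: missing '", key, "'")
  outDir <- outDir %||% cfg$output_dir %||%
    stop("configuration error: missing 'output_dir'")
  seed <- seed %||% cfg$seed %||% 1L
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  flows <- derived <- streams <- energ <- shape <- list()
  for (sub in cfg$subjects) {
    id <- sub$id %||% stop("configuration error: subject missing 'id'")
    for (key in c("field", "mask", "planes"))
      if (is.null(sub[[key]]))
        stop("configuration error: subject ", id, " missing '", key, "'")
    field <- .stage(id, "read_field",
                    readVelocityField(sub$field$path,
                                      sub$field$format %||% "hdf5"))
    mask <- .stage(id, "read_mask",
                   readLumenMask(sub$mask$path, sub$mask$format %||% "hdf5"))
    planes <- .stage(id, "read_planes", readPlanes(sub$planes))
    bsa <- sub$bsa %||% NA_real_

    fl <- .stage(id, "plane_flux", lapply(planes, function(p)
      planeFlux(field, mask, p, bsa = bsa)))
    flows[[id]] <- data.frame(
      subject = id, vessel = names(fl),
      q_net_lmin = vapply(fl, qNet, numeric(1)),
      q_indexed = vapply(fl, function(f) f@qIndexed, numeric(1)),
      mean_velocity_cms = vapply(fl, meanVelocity, numeric(1)))

    if (!is.null(sub$derived)) {
      dv <- sub$derived
      dc <- .stage(id, "derived", derivedCirculation(
        fl[[dv$lpv %||% "LPV"]], fl[[dv$rpv %||% "RPV"]],
        fl[[dv$rpa %||% "RPA"]], fl[[dv$lpa %||% "LPA"]],
        qAo = if (!is.null(dv$ao)) fl[[dv$ao]] else NULL, bsa = bsa))
      derived[[id]] <- data.frame(
        subject = id, qspc_lmin = dc@qspc, qspc_indexed = dc@qspcIndexed,
        effective_ci = dc@effectiveCi, rpa_lpa_ratio = dc@rpaLpaRatio,
        asymmetry = dc@asymmetryClass)
    }

    if (!is.null(sub$streamlines)) {
      sc <- sub$streamlines
      outlets <- unlist(sc$outlets) %||% c("RPA", "LPA")
      rows <- lapply(unlist(sc$seeds), function(sv) {
        sl <- .stage(id, paste0("streamlines_", sv), cavalDistribution(
          field, mask, .planeOrStop(planes, sv, "seed", id),
          nSeeds = sc$n %||% 500L, outletSegments = outlets, seed = seed))
        data.frame(subject = id, seed_vessel = sv,
                   outlet = names(distribution(sl)),
                   percent = as.numeric(distribution(sl)),
                   unresolved_pct = sl@unresolvedPct)
      })
      streams[[id]] <- do.call(rbind, rows)
    }

    if (!is.null(sub$voi)) {
      voi <- .stage(id, "voi",
                    voiFromSegments(mask, unlist(sub$voi$segments)))
      en <- .stage(id, "energetics", energetics(field, mask, voi))
      energ[[id]] <- data.frame(
        subject = id, ke_norm_uj_ml = keNorm(en), el_norm_uw_ml = elNorm(en),
        el_ke_index = elKeIndex(en), voi_volume_ml = en@voiVolume)
    }

    if (!is.null(sub$shape)) {
      rows <- lapply(unlist(sub$shape), function(pv) {
        sh <- .stage(id, paste0("shape_", pv), sectionShape(
          field, mask, .planeOrStop(planes, pv, "shape", id)))
        data.frame(subject = id, vessel = pv, wss_mean_pa = sh@wssMean,
                   jet_angle_deg = sh@jetAngle,
                   eccentricity = sh@eccentricity)
      })
      shape[[id]] <- do.call(rbind, rows)
    }
  }

  out <- list(flows = do.call(rbind, flows),
              derived = if (length(derived)) do.call(rbind, derived),
              streamlines = if (length(streams)) do.call(rbind, streams),
              energetics = if (length(energ)) do.call(rbind, energ),
              shape = if (length(shape)) do.call(rbind, shape))
  for (nm in names(out)) if (!is.null(out[[nm]]))
    utils::write.csv(out[[nm]], file.path(outDir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(out)
}

#' Generate a phantom from a YAML spec
#'
#' Spec fields: \code{kind} (poiseuille_tube, tilted_jet_tube,
#' tcpc_junction) plus the corresponding generator arguments; optional
#' \code{noise_sigma} (cm/s) and \code{seed}.
#'
#' @param spec path to a YAML phantom spec, or the equivalent list.
#' @return a \linkS4class{FlowPhantom}.
#' @export
phantomFromSpec <- function(spec) {
  cfg <- if (is.character(spec)) yaml::read_yaml(spec) else spec
  kind <- cfg$kind %||% stop("configuration error: missing 'kind'")
  args <- cfg[setdiff(names(cfg), c("kind", "noise_sigma", "seed"))]
  ph <- switch(kind,
    poiseuille_tube = do.call(poiseuillePhantom, args),
    tilted_jet_tube = do.call(tiltedJetPhantom, args),
    tcpc_junction   = do.call(tcpcPhantom, args),
    stop("configuration error: unknown phantom kind '", kind, "'"))
  if (!is.null(cfg$noise_sigma) && cfg$noise_sigma > 0) {
    noisy <- addVelocityNoise(ph@field, cfg$noise_sigma,
                              seed = cfg$seed, mask = ph@mask)
    ph <- new("FlowPhantom", field = noisy, mask = ph@mask,
              planes = ph@planes, truth = ph@truth, kind = ph@kind)
  }
  ph
}
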