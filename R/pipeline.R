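## End-to-end orchestration: images -> velocities -> shear rate; flow rates
## + interface -> apparent viscosity; images -> aggregate sizes.  Each
## experiment is processed independently; a stage failure aborts that row
## with a logged warning and the remaining rows continue.

.logStage <- function(verbose, level, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Build an experiment configuration
#'
#' Collects and validates the settings for a pipeline run.  `experiments`
#' is a list of per-experiment lists; each experiment describes a synthetic
#' co-flow measurement by its viscosity ratio and flow rates (the generator
#' replaces the microscope), or carries pre-built inputs under `bundle`.
#'
#' @param experiments list of experiment descriptions.  Recognized fields
#'   per experiment: `label`, `muRatio`, `qRatio`, `qTest`, `muRef`,
#'   `plasmaViscosity`, `hematocrit`, `temperature`, `nPairs`,
#'   `interfaceY` (optional override for the tracer-based estimate),
#'   `nRecordings`, `areaFraction`, `nFrames`.
#' @param width,depth channel dimensions (um).
#' @param pixelScalePIV um/px of the tracer camera (default 0.27).
#' @param pixelScaleBF um/px of the bright-field camera (default 0.2).
#' @param seed master seed; per-experiment seeds are derived from it.
#' @param gridShape finite-difference resolution for synthetic fields.
#' @param verbose emit per-stage log messages (default TRUE).
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(experiments, width = 110, depth = 60,
                             pixelScalePIV = 0.27, pixelScaleBF = 0.2,
                             seed = 1L, gridShape = c(201, 201),
                             verbose = TRUE) {
  if (!is.list(experiments) || !length(experiments))
    .rheoflowError("rheoflowConfigError", "experiments must be a non-empty list")
  vals <- list(experiments = experiments, width = width, depth = depth,
               pixelScalePIV = pixelScalePIV, pixelScaleBF = pixelScaleBF,
               seed = as.integer(seed), gridShape = gridShape,
               verbose = isTRUE(verbose))
  new("ExperimentConfig", values = vals)
}

#' Read an experiment configuration from a YAML file
#'
#' The file mirrors the arguments of [experimentConfig()]: top-level keys
#' `width`, `depth`, `pixel_scale_piv`, `pixel_scale_bf`, `seed`, and a list
#' `experiments` of per-experiment mappings.
#'
#' @param path YAML file path.
#' @return an [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  experimentConfig(
    experiments = y$experiments,
    width = y$width %||% 110, depth = y$depth %||% 60,
    pixelScalePIV = y$pixel_scale_piv %||% 0.27,
    pixelScaleBF = y$pixel_scale_bf %||% 0.2,
    seed = y$seed %||% 1L,
    verbose = y$verbose %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run one synthetic viscometry experiment end to end; returns a one-row
## data.frame.
.viscometryRow <- function(ex, cfg, expSeed) {
  verbose <- cfg$verbose
  label <- ex$label %||% sprintf("exp_seed%d", expSeed)
  muRef <- ex$muRef %||% 1
  qRatio <- ex$qRatio %||% 4
  qTest <- ex$qTest %||% 10

  if (!is.null(ex$bundle)) {
    gen <- ex$bundle
    if (!is.null(gen$truth)) {
      ## the synthetic "pumps" delivered the generated field's flow rates
      ## (the solved interface is snapped to the FD grid, so these can
      ## deviate slightly from the nominal ratio)
      qTest <- gen$truth@qTest
      qRatio <- gen$truth@qRef / gen$truth@qTest
      muRef <- gen$truth@muRef
    }
  } else {
    sim <- genCoflowExperiment(ex$muRatio, qRatio = qRatio, qTest = qTest,
                               muRef = muRef, width = cfg$width,
                               depth = cfg$depth, gridShape = cfg$gridShape,
                               seed = expSeed)
    gen <- list(truth = sim$truth,
                frames = genParticleFrames(sim$field,
                                           nPairs = ex$nPairs %||% 10,
                                           pixelScale = cfg$pixelScalePIV,
                                           seed = expSeed))
  }
  frames <- gen$frames
  .logStage(verbose, "INFO", "%s: PIV on %d pairs", label,
            length(frames$pairs))

  rawA <- lapply(frames$pairs, slot, "frameA")
  rawB <- lapply(frames$pairs, slot, "frameB")
  clean <- removeBackground(c(rawA, rawB))
  nP <- length(frames$pairs)
  fields <- vector("list", nP)
  for (k in seq_len(nP)) {
    pr <- particleImagePair(clean[[k]], clean[[nP + k]],
                            frames$dt, frames$pixelScale)
    vf <- pivMultipass(pr)
    fields[[k]] <- displacementToVelocity(vf, frames$dt, frames$pixelScale)
  }
  profile <- temporalAverageProfile(fields, pixelScale = frames$pixelScale)

  density <- tracerDensityProfile(rawA)
  yPx <- (seq_along(density) - 0.5) * frames$pixelScale
  layer <- detectBloodLayer(density, yPx)
  shear <- estimateShearRate(profile, layer)
  .logStage(verbose, "INFO", "%s: blood layer %.1f-%.1f um, shear %.2f 1/s",
            label, layer[1], layer[2], shearRate(shear))

  Yest <- ex$interfaceY %||% (layer[2] / cfg$width - 0.5)
  geom <- channelGeometry(cfg$width, cfg$depth, interfaceY = Yest)
  prob <- coflowProblem(muRef = muRef, qRef = qRatio * qTest, qTest = qTest)
  muApp <- as.numeric(apparentViscosity(prob, geom))

  muP <- ex$plasmaViscosity %||% NA_real_
  relVisc <- NA_real_
  if (is.na(muP)) {
    .logStage(verbose, "WARN",
              "%s: no plasma viscosity; relative viscosity left empty", label)
  } else {
    relVisc <- relativeViscosity(muApp, muP)
  }
  data.frame(sample = label,
             hematocrit_pct = ex$hematocrit %||% NA_real_,
             temperature_C = ex$temperature %||% NA_real_,
             shear_rate_s1 = shearRate(shear),
             interface_Y = Yest,
             apparent_viscosity_cP = muApp,
             relative_viscosity = relVisc,
             n_fields = length(fields),
             stringsAsFactors = FALSE)
}

#' Run the optical-viscometry pipeline over all configured experiments
#'
#' For each experiment: generate (or accept) tracer image pairs, run
#' background removal and multi-pass PIV, average the fields into a
#' profile, locate the blood layer from the tracer density, estimate the
#' shear rate from the profile slope, estimate the interface position from
#' the blood-layer edge (unless overridden), invert the stratified-flow
#' series for the apparent viscosity, and normalize by the plasma viscosity
#' when available.  A failing experiment is logged and skipped; the others
#' continue.
#'
#' @param config an [ExperimentConfig-class].
#' @return data.frame with one row per successful experiment.
#' @export
runViscometryPipeline <- function(config) {
  stopifnot(is(config, "ExperimentConfig"))
  cfg <- config@values
  rows <- list()
  for (i in seq_along(cfg$experiments)) {
    ex <- cfg$experiments[[i]]
    expSeed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
    row <- tryCatch(.viscometryRow(ex, cfg, expSeed),
                    error = function(e) {
                      .logStage(cfg$verbose, "WARN",
                                "experiment %d failed: %s", i,
                                conditionMessage(e))
                      NULL
                    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(.emptyResultRows())
  do.call(rbind, rows)
}

.emptyResultRows <- function() {
  data.frame(sample = character(0), hematocrit_pct = numeric(0),
             temperature_C = numeric(0), shear_rate_s1 = numeric(0),
             interface_Y = numeric(0), apparent_viscosity_cP = numeric(0),
             relative_viscosity = numeric(0), n_fields = integer(0),
             stringsAsFactors = FALSE)
}

#' Run the aggregate-sizing pipeline over all configured experiments
#'
#' For each experiment, generates (or accepts under `ex$stacks`) one or
#' more bright-field recordings, measures per-recording mean aggregate
#' areas with the detection chain, and reports the mean and the standard
#' error across the repeated recordings, joined with the experiment's shear
#' rate when one is supplied (`ex$shearRate`) or computable.
#'
#' @param config an [ExperimentConfig-class].
#' @return data.frame with one row per experiment.
#' @export
runAggregatePipeline <- function(config) {
  stopifnot(is(config, "ExperimentConfig"))
  cfg <- config@values
  rows <- list()
  for (i in seq_along(cfg$experiments)) {
    ex <- cfg$experiments[[i]]
    expSeed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
    row <- tryCatch({
      nRec <- ex$nRecordings %||% 1
      stacks <- ex$stacks %||% lapply(seq_len(nRec), function(r)
        genAggregateFrames(nFrames = ex$nFrames %||% 50,
                           areaFraction = ex$areaFraction %||% 0.05,
                           pixelScale = cfg$pixelScaleBF,
                           seed = expSeed + r)$stack)
      recs <- lapply(stacks, analyzeAggregateStack)
      means <- vapply(recs, recordingMean, numeric(1))
      means <- means[is.finite(means)]
      if (!length(means))
        .rheoflowError("rheoflowDetectionError", "all recordings empty")
      se <- if (length(means) > 1) stats::sd(means) / sqrt(length(means))
            else recs[[1]]@recordingStderr
      data.frame(sample = ex$label %||% sprintf("agg_seed%d", expSeed),
                 hematocrit_pct = ex$hematocrit %||% NA_real_,
                 temperature_C = ex$temperature %||% NA_real_,
                 shear_rate_s1 = ex$shearRate %||% NA_real_,
                 mean_aggregate_area_um2 = mean(means),
                 area_stderr_um2 = se,
                 n_recordings = length(means),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      .logStage(cfg$verbose, "WARN", "experiment %d failed: %s", i,
                conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows))
    return(data.frame(sample = character(0), hematocrit_pct = numeric(0),
                      temperature_C = numeric(0), shear_rate_s1 = numeric(0),
                      mean_aggregate_area_um2 = numeric(0),
                      area_stderr_um2 = numeric(0), n_recordings = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write pipeline result rows with provenance
#'
#' Writes a result table as CSV (units encoded in the column names, one
#' leading provenance comment line) or JSON (provenance object plus row
#' records).  Written files round-trip through [readResults()] up to float
#' formatting.
#'
#' @param rows data.frame of result rows.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param seed seed recorded in the provenance.
#' @return the path, invisibly.
#' @export
writeResults <- function(rows, path, format = c("csv", "json"), seed = NA) {
  format <- match.arg(format)
  prov <- list(package = "rheoflow",
               version = as.character(utils::packageVersion("rheoflow")),
               seed = seed,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ok <- tryCatch({
    if (format == "csv") {
      con <- file(path, "w")
      writeLines(sprintf("# rheoflow %s seed=%s", prov$version,
                         as.character(seed)), con)
      utils::write.csv(rows, con, row.names = FALSE)
      close(con)
    } else {
      jsonlite::write_json(list(provenance = prov, rows = rows), path,
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
    TRUE
  }, error = function(e) .rheoflowError("rheoflowIOError",
                                        conditionMessage(e)))
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return data.frame of result rows.
#' @export
readResults <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv")
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$rows)
}
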