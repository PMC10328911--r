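# Run configuration: a versioned, fully serializable description of one
# pipeline run. Every stage reads only this object plus its on-disk inputs,
# so a run is reproducible from (config, seed) alone.

#' Default run configuration
#'
#' Returns the complete nested configuration with every tunable of the
#' pipeline at its default: the simulation scenario, sampling design,
#' compositing thresholds, classifier hyperparameters (see
#' [classifierConfig()]), post-processing parameters (including the
#' year-to-cropland-mask schedule) and the reference-area noise level.
#'
#' @param seed integer seed governing all randomness of the run.
#' @param output output directory for stage artifacts.
#' @return Nested named list (schema version 1).
#' @export
#' @examples
#' str(defaultRunConfig(seed = 1), max.level = 2)
defaultRunConfig <- function(seed = 0L, output = "phenoMaize_run") {
  list(
    version = 1L,
    seed = as.integer(seed),
    output = output,
    scenario = list(gridShape = c(64L, 64L), revisitDays = 16L,
                    cloudProb = 0.05,
                    classFractions = c(maize = 0.35, soybean = 0.25,
                                       rice = 0.2, others = 0.2),
                    croplandFraction = 0.7, parcelSize = 5,
                    regionGrid = c(2L, 2L)),
    profiles = list(noiseSd = 0.02, nirSeparation = 1),
    samples = list(nPerClass = 400L, trainFraction = 0.7, year = 2019L),
    referenceAreas = list(errorSd = 0.05),
    compositing = list(maxCloudFraction = 0.8, useIndices = FALSE),
    classifier = list(recurrentLayers = 3L, hiddenDim = 128L,
                      headDims = c(128L, 128L, 64L), nClasses = 4L,
                      learningRate = 0.001, lrDecay = 0.98,
                      swaFrom = 0.5, batchSize = 20L, epochs = 250L,
                      centerLossWeight = -0.001, centerUpdateRate = 0.5,
                      outputActivation = "softmax"),
    postprocess = list(minPatchPx = 4L,
                       maskSchedule = list(
                         list(years = 2013:2015, mask = "mask_2015"),
                         list(years = 2016:2019, mask = "mask_2019"),
                         list(years = 2020:2021, mask = "mask_2020"))))
}

# Schema checks: field presence and basic types. Returns the config
# (invisibly) or stops with an informative message.
#' Validate a run configuration against the schema
#'
#' @param config nested list as produced by [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return The validated config, invisibly.
#' @export
validateRunConfig <- function(config) {
  fail <- function(...) stop("invalid run config: ", sprintf(...),
                             call. = FALSE)
  need <- c("version", "seed", "output", "scenario", "profiles", "samples",
            "referenceAreas", "compositing", "classifier", "postprocess")
  missing <- setdiff(need, names(config))
  if (length(missing)) fail("missing section(s): %s",
                            paste(missing, collapse = ", "))
  if (!identical(as.integer(config$version), 1L))
    fail("unsupported schema version %s", config$version)
  sc <- config$scenario
  scNeed <- c("gridShape", "revisitDays", "cloudProb", "classFractions",
              "croplandFraction", "parcelSize", "regionGrid")
  missing <- setdiff(scNeed, names(sc))
  if (length(missing)) fail("scenario missing: %s",
                            paste(missing, collapse = ", "))
  # construct the S4 scenario to run its validity method
  tryCatch(.scenarioFromConfig(config),
           error = function(e) fail("scenario: %s", conditionMessage(e)))
  cl <- config$classifier
  tryCatch(do.call(classifierConfig, c(cl, list(seed = config$seed))),
           error = function(e) fail("classifier: %s", conditionMessage(e)))
  if (!is.numeric(config$samples$nPerClass) ||
      any(config$samples$nPerClass < 10))
    fail("samples$nPerClass must be >= 10")
  if (config$samples$trainFraction <= 0 || config$samples$trainFraction >= 1)
    fail("samples$trainFraction must lie in (0, 1)")
  if (config$compositing$maxCloudFraction < 0 ||
      config$compositing$maxCloudFraction > 1)
    fail("compositing$maxCloudFraction must lie in [0, 1]")
  if (config$postprocess$minPatchPx < 1)
    fail("postprocess$minPatchPx must be >= 1")
  if (config$referenceAreas$errorSd < 0)
    fail("referenceAreas$errorSd must be >= 0")
  invisible(config)
}

.scenarioFromConfig <- function(config) {
  sc <- config$scenario
  cf <- unlist(sc$classFractions)
  simScenario(gridShape = sc$gridShape, revisitDays = sc$revisitDays,
              cloudProb = sc$cloudProb, classFractions = cf,
              croplandFraction = sc$croplandFraction,
              parcelSize = sc$parcelSize, regionGrid = sc$regionGrid,
              seed = config$seed)
}

# Deep-merge override list into base (named lists merged recursively).
.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the defaults of [defaultRunConfig()];
#' the merged configuration is validated before it is returned, so a
#' schema violation fails here rather than mid-pipeline.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding both the default and the file.
#' @return Validated nested configuration list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .mergeConfig(defaultRunConfig(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$scenario$classFractions))
    cfg$scenario$classFractions <- unlist(cfg$scenario$classFractions)
  validateRunConfig(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config nested configuration list.
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Cropland mask label for a map year
#'
#' Resolves the mask provenance label to use for a given map year from the
#' configured schedule (default: years 2013-2015 use `mask_2015`, 2016-2019
#' `mask_2019`, 2020-2021 `mask_2020`).
#'
#' @param schedule list of `list(years=, mask=)` entries
#'   (see [defaultRunConfig()]).
#' @param year map year.
#' @return Character mask label.
#' @export
#' @examples
#' maskForYear(defaultRunConfig()$postprocess$maskSchedule, 2017)
maskForYear <- function(schedule, year) {
  hits <- vapply(schedule, function(e) year %in% e$years, logical(1))
  if (sum(hits) != 1)
    stop(sprintf("mask schedule must assign exactly one mask to year %d %s",
                 year, sprintf("(found %d)", sum(hits))))
  schedule[[which(hits)]]$mask
}
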