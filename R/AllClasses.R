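#' PhenologyProfile: seasonal reflectance trajectory of one land-cover class
#'
#' A per-class, per-band piecewise-linear mean surface reflectance curve over
#' the April--November season, with additive per-band Gaussian noise and a
#' harvest date after which vegetated bands relax to bare-soil values (the
#' harvest transition is encoded directly in the curve knots; `harvestDoy`
#' records it for inspection).
#'
#' @slot classLabel one of `phenoClasses()`.
#' @slot bandCurves named list (one entry per band, canonical order) of
#'   two-column matrices `cbind(doy, value)` defining a piecewise-linear
#'   reflectance curve; knots must span the season and values lie in [0, 1].
#' @slot noiseSd named numeric vector of per-band additive noise standard
#'   deviations (reflectance units), all `>= 0`.
#' @slot harvestDoy day-of-year of harvest (crop classes) or season end.
#'
#' @details Crop-contrast invariants enforced by the validity method: maize
#' and soybean must show a NIR green-up of at least 0.2 reflectance between
#' early April and their June--September peak, while the `others` class must
#' have a seasonal NIR range below 0.1, so simulated crop and non-crop pixels
#' are distinguishable in the way real one-season cropland is.
#' @export
setClass("PhenologyProfile",
  representation(classLabel = "character", bandCurves = "list",
                 noiseSd = "numeric", harvestDoy = "numeric"))

setValidity("PhenologyProfile", function(object) {
  msgs <- character()
  if (!(object@classLabel %in% phenoClasses()))
    msgs <- c(msgs, "classLabel must be one of phenoClasses()")
  if (!identical(names(object@bandCurves), phenoBands()))
    msgs <- c(msgs, "bandCurves must be named by phenoBands() in order")
  for (b in names(object@bandCurves)) {
    k <- object@bandCurves[[b]]
    if (!is.matrix(k) || ncol(k) != 2)
      msgs <- c(msgs, sprintf("curve for %s must be a 2-column matrix", b))
    else {
      if (is.unsorted(k[, 1], strictly = TRUE))
        msgs <- c(msgs, sprintf("curve knots for %s must have increasing doy", b))
      if (any(k[, 2] < 0 | k[, 2] > 1))
        msgs <- c(msgs, sprintf("curve values for %s must lie in [0,1]", b))
    }
  }
  if (!identical(names(object@noiseSd), phenoBands()) ||
      any(object@noiseSd < 0))
    msgs <- c(msgs, "noiseSd must be named by band and non-negative")
  if (length(msgs) == 0 && object@classLabel %in% c("maize", "soybean")) {
    nir <- object@bandCurves[["nir"]]
    apr <- curveValue(nir, .SEASON_START)
    peak <- max(vapply(152:273, function(d) curveValue(nir, d), numeric(1)))
    if (peak - apr < 0.2)
      msgs <- c(msgs, sprintf(
        "%s NIR Jun-Sep peak must exceed its April value by >= 0.2",
        object@classLabel))
  }
  if (length(msgs) == 0 && object@classLabel == "others") {
    nir <- object@bandCurves[["nir"]]
    vals <- vapply(.SEASON_START:.SEASON_END, function(d) curveValue(nir, d),
                   numeric(1))
    if (diff(range(vals)) >= 0.1)
      msgs <- c(msgs, "'others' seasonal NIR range must be < 0.1")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimScenario: parameters of one synthetic mapping experiment
#'
#' Describes the grid, acquisition cadence, cloudiness, class mixture,
#' cropland extent, parcel geometry and region partition of a simulated
#' scene; together with a seed it determines every simulated artifact.
#'
#' @slot gridShape integer c(rows, cols); 30 m nominal pixels.
#' @slot revisitDays acquisition cadence in days (Landsat 8: 16).
#' @slot cloudProb per-scene, per-pixel probability that an observation is
#'   cloud-contaminated, in [0, 1).
#' @slot classFractions named numeric mixture over the four classes within
#'   cropland; sums to 1.
#' @slot croplandFraction fraction of parcels inside the cropland mask.
#' @slot parcelSize mean side length (pixels) of rectangular parcels.
#' @slot regionGrid integer c(rows, cols) of the block partition standing in
#'   for administrative regions; at least 4 pixels per region.
#' @slot seed integer controlling all randomness.
#' @export
setClass("SimScenario",
  representation(gridShape = "integer", revisitDays = "integer",
                 cloudProb = "numeric", classFractions = "numeric",
                 croplandFraction = "numeric", parcelSize = "numeric",
                 regionGrid = "integer", seed = "integer"))

setValidity("SimScenario", function(object) {
  msgs <- character()
  if (length(object@gridShape) != 2 || any(object@gridShape < 1))
    msgs <- c(msgs, "gridShape must be two positive integers")
  if (object@revisitDays < 1) msgs <- c(msgs, "revisitDays must be >= 1")
  if (object@cloudProb < 0 || object@cloudProb >= 1)
    msgs <- c(msgs, "cloudProb must lie in [0, 1)")
  if (!identical(names(object@classFractions), phenoClasses()) ||
      abs(sum(object@classFractions) - 1) > 1e-8 ||
      any(object@classFractions < 0))
    msgs <- c(msgs, "classFractions must be named by class and sum to 1")
  if (object@croplandFraction < 0 || object@croplandFraction > 1)
    msgs <- c(msgs, "croplandFraction must lie in [0, 1]")
  if (object@parcelSize < 1) msgs <- c(msgs, "parcelSize must be >= 1")
  if (length(object@regionGrid) != 2 || any(object@regionGrid < 1))
    msgs <- c(msgs, "regionGrid must be two positive integers")
  if (length(msgs) == 0) {
    px <- prod(object@gridShape %/% object@regionGrid)
    if (px < 4)
      msgs <- c(msgs, "each region must contain at least 4 pixels")
  }
  if (length(msgs)) msgs else TRUE
})

#' SceneStack: a time-ordered stack of six-band scenes with cloud flags
#'
#' @slot dates numeric vector of strictly increasing acquisition dates
#'   (day-of-year).
#' @slot refl numeric array `[rows, cols, band, date]` of surface reflectance
#'   in [0, 1]; `NA` marks observations with no valid value.
#' @slot cloud logical array with the same dimensions; `TRUE` flags a
#'   cloud-contaminated observation.
#' @export
setClass("SceneStack",
  representation(dates = "numeric", refl = "array", cloud = "array"))

setValidity("SceneStack", function(object) {
  msgs <- character()
  d <- dim(object@refl)
  if (length(d) != 4 || d[3] != 6)
    msgs <- c(msgs, "refl must be a [rows, cols, 6, dates] array")
  if (!identical(dim(object@cloud), d))
    msgs <- c(msgs, "cloud flags must match refl dimensions")
  if (length(object@dates) != d[4])
    msgs <- c(msgs, "length(dates) must equal the date dimension")
  if (is.unsorted(object@dates, strictly = TRUE))
    msgs <- c(msgs, "dates must be strictly increasing")
  if (any(object@refl < 0 | object@refl > 1, na.rm = TRUE))
    msgs <- c(msgs, "reflectance values must lie in [0,1] (or NA)")
  if (length(msgs)) msgs else TRUE
})

#' CompositeFeatures: 4-period x 6-band maximum-value composite
#'
#' Per-pixel features produced by two-month maximum-value compositing:
#' for every pixel, period and band, the maximum over all valid (non-cloud,
#' post-gap-filling) observations falling in the period window. A period with
#' no valid observation for a pixel is flagged invalid there.
#'
#' @slot values numeric array `[rows, cols, band, period]`.
#' @slot valid logical array `[rows, cols, period]`.
#' @slot periods the 4 x 2 day-of-year window matrix (see [defaultPeriods()]).
#' @export
setClass("CompositeFeatures",
  representation(values = "array", valid = "array", periods = "matrix"))

setValidity("CompositeFeatures", function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 4 || d[3] != 6)
    msgs <- c(msgs, "values must be a [rows, cols, 6, periods] array")
  if (!identical(dim(object@valid), d[c(1, 2, 4)]))
    msgs <- c(msgs, "valid must be a [rows, cols, periods] logical array")
  if (nrow(object@periods) != d[4] || ncol(object@periods) != 2)
    msgs <- c(msgs, "periods must be an nPeriods x 2 matrix")
  if (length(msgs)) msgs else TRUE
})

#' MaizeClassifier: recurrent classifier state
#'
#' Holds the LSTM feature extractor and fully connected head parameters, the
#' per-class feature centers used by the center loss, the optimizer state and
#' the training history.
#'
#' @slot config list of hyperparameters (see [classifierConfig()]).
#' @slot params named list of weight matrices and bias vectors.
#' @slot centers numeric matrix `[nClasses, featureDim]` of class centers.
#' @slot optState Adam first/second-moment accumulators (internal).
#' @slot norm optional input standardization: per-(period, band) `mean` and
#'   `sd` matrices estimated on the training set and applied to every
#'   input (empty list when disabled).
#' @slot history data.frame of per-epoch losses and training accuracy.
#' @slot trained logical.
#' @export
setClass("MaizeClassifier",
  representation(config = "list", params = "list", centers = "matrix",
                 optState = "list", norm = "list", history = "data.frame",
                 trained = "logical"))

setValidity("MaizeClassifier", function(object) {
  msgs <- character()
  if (!all(is.finite(object@centers)))
    msgs <- c(msgs, "centers must be finite")
  if (nrow(object@centers) != object@config$nClasses)
    msgs <- c(msgs, "centers must have one row per class")
  if (length(msgs)) msgs else TRUE
})
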