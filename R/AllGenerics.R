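#' @rdname sceneDates
#' @export
setGeneric("sceneDates", function(x) standardGeneric("sceneDates"))

#' @rdname sceneCloudFraction
#' @export
setGeneric("sceneCloudFraction",
           function(x) standardGeneric("sceneCloudFraction"))

#' @rdname nScenes
#' @export
setGeneric("nScenes", function(x) standardGeneric("nScenes"))

#' @rdname gridDim
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname classCenters
#' @export
setGeneric("classCenters", function(x) standardGeneric("classCenters"))

#' @rdname trainingHistory
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname nParameters
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' Acquisition dates of a scene stack
#'
#' @param x a [SceneStack-class].
#' @return Numeric vector of day-of-year acquisition dates.
#' @rdname sceneDates
#' @export
setMethod("sceneDates", "SceneStack", function(x) x@dates)

#' Per-scene cloud fraction
#'
#' Fraction of pixels in each scene with at least one cloud-flagged band.
#'
#' @param x a [SceneStack-class].
#' @return Numeric vector, one fraction per scene.
#' @rdname sceneCloudFraction
#' @export
setMethod("sceneCloudFraction", "SceneStack", function(x) {
  d <- dim(x@cloud)
  vapply(seq_len(d[4]), function(k) {
    anyband <- apply(x@cloud[, , , k, drop = FALSE], c(1, 2), any)
    mean(anyband)
  }, numeric(1))
})

#' Number of scenes in a stack
#' @param x a [SceneStack-class].
#' @return Integer scene count.
#' @rdname nScenes
#' @export
setMethod("nScenes", "SceneStack", function(x) length(x@dates))

#' Grid dimensions
#' @param x a [SceneStack-class] or [CompositeFeatures-class].
#' @return Integer c(rows, cols).
#' @rdname gridDim
#' @export
setMethod("gridDim", "SceneStack", function(x) dim(x@refl)[1:2])

#' @rdname gridDim
#' @export
setMethod("gridDim", "CompositeFeatures", function(x) dim(x@values)[1:2])

#' Class centers of a trained classifier
#' @param x a [MaizeClassifier-class].
#' @return Matrix `[nClasses, featureDim]`.
#' @rdname classCenters
#' @export
setMethod("classCenters", "MaizeClassifier", function(x) x@centers)

#' Training history of a classifier
#' @param x a [MaizeClassifier-class].
#' @return data.frame with columns epoch, ce, center, total, trainAcc.
#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "MaizeClassifier", function(x) x@history)

#' Total number of trainable parameters
#' @param x a [MaizeClassifier-class].
#' @return Integer parameter count (weights plus biases; centers excluded --
#'   they are updated by the explicit center rule, not the optimizer).
#' @rdname nParameters
#' @export
setMethod("nParameters", "MaizeClassifier", function(x) {
  sum(vapply(x@params, length, integer(1)))
})

setMethod("show", "PhenologyProfile", function(object) {
  nir <- object@bandCurves[["nir"]]
  cat("PhenologyProfile:", object@classLabel, "\n")
  cat("  NIR range over season: ",
      sprintf("%.3f-%.3f", min(nir[, 2]), max(nir[, 2])),
      "; harvest doy ", object@harvestDoy, "\n", sep = "")
  cat("  noise sd:", paste(sprintf("%s=%.3f", names(object@noiseSd),
                                   object@noiseSd), collapse = " "), "\n")
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", paste(object@gridShape, collapse = "x"), "grid,",
      "revisit", object@revisitDays, "d, cloudProb", object@cloudProb, "\n")
  cat("  class fractions:",
      paste(sprintf("%s=%.2f", names(object@classFractions),
                    object@classFractions), collapse = " "), "\n")
  cat("  cropland fraction", object@croplandFraction, ", parcel size",
      object@parcelSize, "px, regions",
      paste(object@regionGrid, collapse = "x"), ", seed",
      object@seed, "\n")
})

setMethod("show", "SceneStack", function(object) {
  d <- dim(object@refl)
  cat("SceneStack:", d[1], "x", d[2], "px,", d[4], "scenes, doy",
      min(object@dates), "-", max(object@dates), "\n")
  cf <- sceneCloudFraction(object)
  cat("  cloud fraction: mean", sprintf("%.3f", mean(cf)), "max",
      sprintf("%.3f", max(cf)), "\n")
})

setMethod("show", "CompositeFeatures", function(object) {
  d <- dim(object@values)
  cat("CompositeFeatures:", d[1], "x", d[2], "px,", d[4], "periods x",
      d[3], "bands (", d[3] * d[4], "features )\n")
  cat("  fully valid pixels:", sum(apply(object@valid, c(1, 2), all)),
      "/", d[1] * d[2], "\n")
})

setMethod("show", "MaizeClassifier", function(object) {
  cfg <- object@config
  cat("MaizeClassifier:", cfg$recurrentLayers, "LSTM layers x",
      cfg$hiddenDim, "units; head",
      paste(cfg$headDims, collapse = "-"), "->", cfg$nClasses,
      "classes (", cfg$outputActivation, ")\n")
  cat("  parameters:", nParameters(object),
      if (object@trained) sprintf("; trained %d epochs, final loss %.4f",
                                  nrow(object@history),
                                  object@history$total[nrow(object@history)])
      else "; untrained", "\n")
})
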