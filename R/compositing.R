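#' Drop scenes whose cloud fraction exceeds a threshold
#'
#' Scene-level cloud screening: retains exactly the scenes whose fraction of
#' cloud-flagged pixels is at most `maxCloudFraction`, preserving time order.
#'
#' @param stack a [SceneStack-class].
#' @param maxCloudFraction scalar in [0, 1]; scenes with a larger flagged
#'   fraction are removed. Default 0.8.
#' @param periods period windows used to check coverage after filtering.
#' @return The filtered [SceneStack-class].
#' @seealso [replaceCloudyBands()] for the per-observation gap filling that
#'   handles the residual clouds in retained scenes.
#' @export
dropCloudyScenes <- function(stack, maxCloudFraction = 0.8,
                             periods = defaultPeriods()) {
  stopifnot(maxCloudFraction >= 0, maxCloudFraction <= 1)
  keep <- sceneCloudFraction(stack) <= maxCloudFraction
  dates <- stack@dates[keep]
  for (p in seq_len(nrow(periods))) {
    if (!any(dates >= periods[p, 1] & dates <= periods[p, 2]))
      stop(sprintf(
        "no scene survives cloud screening in period %d (doy %d-%d)",
        p, periods[p, 1], periods[p, 2]))
  }
  new("SceneStack", dates = dates,
      refl = stack@refl[, , , keep, drop = FALSE],
      cloud = stack@cloud[, , , keep, drop = FALSE])
}

#' Replace cloud-contaminated observations from the nearest clean date
#'
#' For every flagged (pixel, band, date) observation, substitutes the value
#' of the same pixel and band from the nearest-in-time date at which that
#' observation is clean, then clears the flag. Ties in temporal distance are
#' broken toward the earlier date. If a pixel/band has no clean observation
#' at any date, the value becomes `NA` (invalid) and is excluded from
#' compositing downstream.
#'
#' @param stack a [SceneStack-class].
#' @param verbose if `TRUE`, message the count of irreplaceable observations.
#' @return A [SceneStack-class] with all replaceable flags resolved.
#' @export
replaceCloudyBands <- function(stack, verbose = FALSE) {
  nd <- length(stack@dates)
  if (nd == 0) stop("empty scene stack")
  if (!any(stack@cloud)) return(stack)
  d <- dim(stack@refl)
  n <- d[1] * d[2] * d[3]
  # view each (pixel, band) series as a row over dates
  refl <- matrix(stack@refl, n, nd)
  cloudm <- matrix(stack@cloud, n, nd)
  clean <- !cloudm & !is.na(refl)
  out <- refl
  for (t in seq_len(nd)) {
    need <- which(cloudm[, t])
    if (!length(need)) next
    # candidate dates by |dt| ascending, earlier date first on ties
    ord <- order(abs(stack@dates - stack@dates[t]), stack@dates)
    ord <- ord[ord != t]
    filled <- rep(FALSE, length(need))
    for (s in ord) {
      open <- !filled
      if (!any(open)) break
      ok <- open & clean[need, s]
      out[need[ok], t] <- refl[need[ok], s]
      filled <- filled | ok
    }
    out[need[!filled], t] <- NA_real_
  }
  nIrr <- sum(is.na(out) & cloudm)
  if (verbose && nIrr > 0)
    message(nIrr, " cloud-contaminated observation(s) had no clean ",
            "replacement and were marked invalid")
  new("SceneStack", dates = stack@dates,
      refl = array(out, d),
      cloud = array(FALSE, d))
}

#' Two-month maximum-value compositing
#'
#' Collapses a scene stack into per-pixel, per-period, per-band maxima over
#' all valid observations: the maximum-value composite that suppresses
#' residual clouds and shadows and stabilizes the seasonal signal. An
#' observation is valid if it is not cloud-flagged and not `NA`. The maximum
#' is taken independently per band. A (pixel, period) with no valid
#' observation in any band is flagged invalid.
#'
#' @param stack a [SceneStack-class] (normally after [replaceCloudyBands()]).
#' @param periods an nPeriods x 2 day-of-year window matrix; defaults to the
#'   four two-month windows of [defaultPeriods()].
#' @return A [CompositeFeatures-class].
#' @export
#' @examples
#' sc <- simScenario(gridShape = c(8, 8), cloudProb = 0, seed = 3)
#' sim <- simulateSceneStack(sc, defaultProfiles(3))
#' maxValueComposite(sim$stack)
maxValueComposite <- function(stack, periods = defaultPeriods()) {
  d <- dim(stack@refl)
  np <- nrow(periods)
  vals <- array(NA_real_, c(d[1], d[2], d[3], np))
  valid <- array(FALSE, c(d[1], d[2], np))
  for (p in seq_len(np)) {
    inWin <- which(stack@dates >= periods[p, 1] & stack@dates <= periods[p, 2])
    if (!length(inWin))
      stop(sprintf("period %d (doy %d-%d) contains no scenes", p,
                   periods[p, 1], periods[p, 2]))
    for (b in seq_len(d[3])) {
      obs <- stack@refl[, , b, inWin, drop = FALSE]
      obs[stack@cloud[, , b, inWin, drop = FALSE]] <- NA_real_
      m <- apply(obs, c(1, 2), function(v) {
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      })
      vals[, , b, p] <- m
    }
    valid[, , p] <- apply(!is.na(vals[, , , p, drop = FALSE]), c(1, 2), all)
  }
  new("CompositeFeatures", values = vals, valid = valid,
      periods = periods)
}

#' Flatten composite features to per-pixel 24-vectors
#'
#' Orders each pixel's features period-major: period 1 bands 1-6, period 2
#' bands 1-6, and so on (24 values for the default four periods). Pixels
#' with any invalid period receive `NA` rows; callers exclude them from
#' training and flag them in prediction output.
#'
#' @param composite a [CompositeFeatures-class].
#' @return Numeric matrix `[nPixels, nPeriods * 6]`; pixels are ordered
#'   column-major (R matrix order) so row `i` corresponds to
#'   `truth[[i]]` of the aligned rasters.
#' @export
flattenFeatures <- function(composite) {
  d <- dim(composite@values)
  npx <- d[1] * d[2]
  m <- matrix(NA_real_, npx, d[3] * d[4])
  for (p in seq_len(d[4]))
    for (b in seq_len(d[3]))
      m[, (p - 1L) * d[3] + b] <- as.vector(composite@values[, , b, p])
  bad <- !apply(composite@valid, c(1, 2), all)
  m[as.vector(bad), ] <- NA_real_
  colnames(m) <- as.vector(t(outer(seq_len(d[4]), phenoBands(),
                                   function(p, b) paste0("p", p, "_", b))))
  m
}

#' Reshape flat 24-vectors back to the period x band layout
#'
#' Inverse of [flattenFeatures()] at the pixel level: turns an
#' `[n, nPeriods * 6]` matrix into an `[n, nPeriods, 6]` array (the sequence
#' layout consumed by the classifier).
#'
#' @param x numeric matrix of flattened features.
#' @param nBands number of spectral bands (6).
#' @return Numeric array `[n, nPeriods, nBands]`.
#' @export
unflattenFeatures <- function(x, nBands = 6L) {
  np <- ncol(x) / nBands
  stopifnot(np == as.integer(np))
  arr <- array(NA_real_, c(nrow(x), np, nBands))
  for (p in seq_len(np))
    arr[, p, ] <- x[, (p - 1L) * nBands + seq_len(nBands)]
  arr
}

#' Spectral indices: NDVI, EVI, NDWI
#'
#' Standard vegetation and water indices computed from surface reflectance:
#' \deqn{NDVI = (\rho_{NIR} - \rho_{red}) / (\rho_{NIR} + \rho_{red})}
#' \deqn{EVI = 2.5 (\rho_{NIR} - \rho_{red}) /
#'       (\rho_{NIR} + 6\rho_{red} - 7.5\rho_{blue} + 1)}
#' \deqn{NDWI = (\rho_{green} - \rho_{NIR}) / (\rho_{green} + \rho_{NIR})}
#' Zero denominators yield `NA` rather than an error. These indices can be
#' stacked onto the composite features for ablation experiments; the default
#' classifier input is the raw 24-band composite.
#'
#' @param blue,green,red,nir numeric reflectance vectors in [0, 1].
#' @return data.frame with columns ndvi, evi, ndwi.
#' @export
#' @examples
#' computeIndices(blue = 0.04, green = 0.08, red = 0.1, nir = 0.5)
computeIndices <- function(blue, green, red, nir) {
  safeDiv <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(
    ndvi = safeDiv(nir - red, nir + red),
    evi = safeDiv(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1),
    ndwi = safeDiv(green - nir, green + nir))
}
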