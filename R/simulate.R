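#' Construct a simulation scenario
#'
#' @param gridShape integer c(rows, cols) of the pixel grid (30 m pixels).
#' @param revisitDays acquisition cadence in days; 16 matches Landsat 8.
#' @param cloudProb per-scene per-pixel cloud probability in [0, 1).
#' @param classFractions mixture over maize, soybean, rice, others within
#'   cropland (named or in canonical order); must sum to 1.
#' @param croplandFraction fraction of parcels belonging to cropland.
#' @param parcelSize mean parcel side length in pixels.
#' @param regionGrid block partition c(rows, cols) used as administrative
#'   regions for area aggregation.
#' @param seed integer seed controlling all randomness.
#' @return A validated [SimScenario-class].
#' @export
#' @examples
#' simScenario(gridShape = c(32, 32), seed = 1)
simScenario <- function(gridShape = c(64L, 64L), revisitDays = 16L,
                        cloudProb = 0.05,
                        classFractions = c(maize = 0.35, soybean = 0.25,
                                           rice = 0.2, others = 0.2),
                        croplandFraction = 0.7, parcelSize = 5,
                        regionGrid = c(2L, 2L), seed = 0L) {
  if (is.null(names(classFractions))) names(classFractions) <- phenoClasses()
  new("SimScenario", gridShape = as.integer(gridShape),
      revisitDays = as.integer(revisitDays), cloudProb = cloudProb,
      classFractions = classFractions[phenoClasses()],
      croplandFraction = croplandFraction, parcelSize = parcelSize,
      regionGrid = as.integer(regionGrid), seed = as.integer(seed))
}

#' Acquisition dates implied by a scenario
#'
#' @param scenario a [SimScenario-class].
#' @return Integer day-of-year vector from Apr 1 (doy 91) to Nov 30 (doy 334)
#'   at the scenario's revisit cadence.
#' @export
acquisitionDates <- function(scenario) {
  seq.int(.SEASON_START, .SEASON_END, by = scenario@revisitDays)
}

# Irregular 1-d tiling with segment lengths around `size`.
.randomBreaks <- function(n, size) {
  lens <- integer(0)
  total <- 0L
  lo <- max(1L, floor(size / 2))
  hi <- max(lo, ceiling(size * 3 / 2))
  while (total < n) {
    l <- sample(lo:hi, 1L)
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - n)
  lens <- lens[lens > 0L]
  rep(seq_along(lens), lens)
}

# Largest-remainder allocation of n items to fractions p.
.allocateCounts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a full synthetic scene: stack, truth, cropland mask and regions
#'
#' Generates a parcel-structured ground-truth class raster, a binary cropland
#' mask, a regular-block region raster, and the time-ordered six-band scene
#' stack implied by the phenology profiles. Each pixel's clean reflectance at
#' a date is its class profile curve value plus band-specific Gaussian noise
#' (truncated to [0, 1]). Cloud-contaminated observations (drawn per pixel
#' and scene) are flagged and overwritten by a bright cloud signature
#' (Blue >= 0.4) so that naive compositing without cloud handling is visibly
#' corrupted. Parcels are rectangles of a single class; the cropland fraction
#' is realized over parcels and class fractions by largest-remainder
#' allocation over cropland parcels, so realized pixel shares track the
#' requested mixture closely. Non-cropland parcels take the `others` profile
#' and sit outside the mask.
#'
#' @param scenario a [SimScenario-class].
#' @param profiles named list of the four [PhenologyProfile-class] objects,
#'   e.g. from [defaultProfiles()].
#' @return A list with elements `stack` ([SceneStack-class]), `truth`
#'   (integer matrix, values 1..4 indexing [phenoClasses()]), `cropland`
#'   (0/1 integer matrix) and `regions` (integer matrix of region ids).
#' @export
#' @examples
#' sc <- simScenario(gridShape = c(16, 16), seed = 1)
#' sim <- simulateSceneStack(sc, defaultProfiles(1))
#' sim$stack
simulateSceneStack <- function(scenario, profiles) {
  validObject(scenario)
  stopifnot(identical(sort(names(profiles)), sort(phenoClasses())))
  nr <- scenario@gridShape[1]; nc <- scenario@gridShape[2]
  dates <- acquisitionDates(scenario)
  nd <- length(dates)
  cls <- phenoClasses()

  withSeed(childSeed(scenario@seed, 101L), {
    # --- parcel tiling and class assignment ---------------------------------
    rowId <- .randomBreaks(nr, scenario@parcelSize)
    colId <- .randomBreaks(nc, scenario@parcelSize)
    parcel <- outer(rowId, colId, function(a, b) (a - 1L) * max(colId) + b)
    parcelIds <- sort(unique(as.vector(parcel)))
    np <- length(parcelIds)
    nCrop <- round(np * scenario@croplandFraction)
    cropParcels <- sample(parcelIds, nCrop)
    counts <- .allocateCounts(nCrop, scenario@classFractions)
    assignment <- sample(rep.int(seq_along(cls), counts))
    parcelClass <- setNames(rep.int(4L, np), parcelIds)   # others by default
    parcelClass[as.character(cropParcels)] <- assignment
    truth <- matrix(parcelClass[as.character(parcel)], nr, nc)
    cropland <- matrix(0L, nr, nc)
    cropland[matrix(parcel %in% cropParcels, nr, nc)] <- 1L

    # --- region raster: regular block partition -----------------------------
    rg <- scenario@regionGrid
    rr <- pmin(ceiling(seq_len(nr) / (nr / rg[1])), rg[1])
    cc <- pmin(ceiling(seq_len(nc) / (nc / rg[2])), rg[2])
    regions <- outer(rr, cc, function(a, b) (a - 1L) * rg[2] + b)
    storage.mode(regions) <- "integer"

    # --- reflectance stack --------------------------------------------------
    refl <- array(NA_real_, c(nr, nc, 6L, nd))
    cloud <- array(FALSE, c(nr, nc, 6L, nd))
    cloudSig <- c(blue = 0.62, green = 0.58, red = 0.55, nir = 0.50,
                  swir1 = 0.32, swir2 = 0.28)
    for (k in seq_len(nd)) {
      cl <- matrix(runif(nr * nc) < scenario@cloudProb, nr, nc)
      for (b in seq_len(6L)) {
        band <- phenoBands()[b]
        mu <- matrix(0, nr, nc)
        for (j in seq_along(cls)) {
          v <- profileReflectance(profiles[[cls[j]]], band, dates[k])
          mu[truth == j] <- v
        }
        sd <- profiles[[1]]@noiseSd[band]
        obs <- mu + rnorm(nr * nc, 0, sd)
        obs[cl] <- cloudSig[band] + rnorm(sum(cl), 0, sd)
        refl[, , b, k] <- pmin(1, pmax(0, obs))
        cloud[, , b, k] <- cl
      }
    }
    list(stack = new("SceneStack", dates = as.numeric(dates), refl = refl,
                     cloud = cloud),
         truth = truth, cropland = cropland, regions = regions)
  })
}

#' Draw labeled samples from a simulated truth raster
#'
#' Samples `nPerClass` pixel locations per class (without replacement) from
#' the ground-truth raster and splits each class into training and testing
#' sets. Split sizes follow `round(nPerClass * trainFraction)` per class, the
#' 70/30 convention by default.
#'
#' @param sim result of [simulateSceneStack()].
#' @param scenario the [SimScenario-class] used to build `sim` (seed source).
#' @param nPerClass samples per class (scalar, or named/positional vector of
#'   4 for unbalanced designs); each entry must be >= 10.
#' @param trainFraction fraction assigned to the training split, in (0, 1).
#' @param year nominal acquisition year recorded with each sample.
#' @return data.frame with columns row, col, year, class, split.
#' @export
simulateSamples <- function(sim, scenario, nPerClass = 400,
                            trainFraction = 0.7, year = 2019L) {
  stopifnot(all(nPerClass >= 10), trainFraction > 0, trainFraction < 1)
  n <- rep_len(as.integer(nPerClass), 4L)
  cls <- phenoClasses()
  withSeed(childSeed(scenario@seed, 202L), {
    out <- lapply(seq_along(cls), function(j) {
      idx <- which(sim$truth == j)
      if (length(idx) < n[j])
        stop(sprintf("class %s has only %d eligible pixels (< %d requested)",
                     cls[j], length(idx), n[j]))
      pick <- sample(idx, n[j])
      nTrain <- round(n[j] * trainFraction)
      split <- rep("test", n[j])
      split[seq_len(nTrain)] <- "train"
      data.frame(row = (pick - 1L) %% nrow(sim$truth) + 1L,
                 col = (pick - 1L) %/% nrow(sim$truth) + 1L,
                 year = year, class = cls[j], split = split,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate region-level reference maize areas
#'
#' Computes the true maize area per region from the truth raster (pixel
#' count x 900 m^2, reported in hectares) and perturbs it with multiplicative
#' lognormal noise of the given standard deviation, standing in for
#' independently surveyed statistical records. `errorSd = 0` returns exact
#' areas.
#'
#' @param truth integer truth raster (1 = maize).
#' @param regions integer region raster aligned with `truth`.
#' @param errorSd standard deviation of `log(reference / true)`.
#' @param seed integer seed.
#' @param year nominal year recorded with each record.
#' @param pixelAreaM2 area of one pixel in square meters (30 m pixels: 900).
#' @return data.frame with columns region, year, area_ha.
#' @export
simulateReferenceAreas <- function(truth, regions, errorSd = 0.05, seed = 0L,
                                   year = 2019L, pixelAreaM2 = 900) {
  stopifnot(identical(dim(truth), dim(regions)), errorSd >= 0)
  ids <- sort(unique(as.vector(regions)))
  withSeed(childSeed(seed, 303L), {
    area <- vapply(ids, function(r) {
      sum(truth == 1L & regions == r) * pixelAreaM2 / 1e4
    }, numeric(1))
    if (errorSd > 0) area <- area * rlnorm(length(area), 0, errorSd)
    data.frame(region = ids, year = year, area_ha = area)
  })
}
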