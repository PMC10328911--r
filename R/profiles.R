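# Linear interpolation on a knot matrix cbind(doy, value); constant beyond
# the first/last knot.
curveValue <- function(knots, doy) {
  stats::approx(knots[, 1], knots[, 2], xout = doy, rule = 2)$y
}

#' Mean reflectance of a profile at given dates
#'
#' @param profile a [PhenologyProfile-class].
#' @param band one of [phenoBands()].
#' @param doy numeric day-of-year value(s).
#' @return Numeric vector of mean reflectances (no noise).
#' @export
profileReflectance <- function(profile, band, doy) {
  stopifnot(band %in% phenoBands())
  curveValue(profile@bandCurves[[band]], doy)
}

# Knot tables for the four default classes. Values are plausible Landsat 8
# surface reflectances for one-season cropland: crops green up in June,
# peak in July-August (high NIR, depressed red and SWIR) and collapse to
# bare-soil reflectance at harvest; rice starts flooded (very low SWIR);
# the "others" class mixes weakly seasonal natural vegetation.
.baseCurves <- function() {
  k <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("doy", "value")
    m
  }
  list(
    maize = list(
      blue  = k(91, .08, 140, .08, 200, .040, 235, .040, 278, .08, 334, .08),
      green = k(91, .10, 140, .10, 200, .080, 235, .080, 278, .10, 334, .10),
      red   = k(91, .12, 140, .12, 170, .080, 200, .050, 235, .050, 270, .090,
                278, .12, 334, .12),
      nir   = k(91, .18, 140, .18, 170, .320, 200, .450, 235, .450, 270, .300,
                278, .18, 334, .18),
      swir1 = k(91, .25, 140, .25, 200, .160, 235, .160, 278, .25, 334, .25),
      swir2 = k(91, .20, 140, .20, 200, .110, 235, .110, 278, .20, 334, .20)),
    soybean = list(
      blue  = k(91, .08, 150, .08, 205, .035, 230, .035, 258, .08, 334, .08),
      green = k(91, .10, 150, .10, 205, .090, 230, .090, 258, .10, 334, .10),
      red   = k(91, .12, 150, .12, 205, .040, 230, .040, 258, .12, 334, .12),
      nir   = k(91, .18, 150, .18, 180, .350, 205, .500, 230, .500, 250, .300,
                258, .18, 334, .18),
      swir1 = k(91, .25, 150, .25, 205, .120, 230, .120, 258, .25, 334, .25),
      swir2 = k(91, .20, 150, .20, 205, .080, 230, .080, 258, .20, 334, .20)),
    rice = list(
      blue  = k(91, .06, 190, .040, 225, .040, 270, .07, 334, .07),
      green = k(91, .08, 190, .070, 225, .070, 270, .09, 334, .09),
      red   = k(91, .06, 135, .06, 190, .050, 225, .050, 270, .10, 334, .10),
      nir   = k(91, .10, 135, .10, 160, .200, 190, .420, 225, .420, 250, .300,
                270, .18, 334, .18),
      swir1 = k(91, .06, 135, .06, 190, .100, 225, .100, 270, .20, 334, .20),
      swir2 = k(91, .04, 135, .04, 190, .070, 225, .070, 270, .16, 334, .16)),
    others = list(
      blue  = k(91, .07, 334, .07),
      green = k(91, .09, 180, .10, 334, .09),
      red   = k(91, .10, 180, .09, 334, .10),
      nir   = k(91, .22, 180, .28, 270, .26, 334, .22),
      swir1 = k(91, .22, 180, .20, 334, .22),
      swir2 = k(91, .18, 180, .16, 334, .18))
  )
}

.harvestDoy <- c(maize = 278, soybean = 258, rice = 270, others = 334)

#' Default phenology profiles for the four classes
#'
#' Builds one [PhenologyProfile-class] per class (maize, soybean, rice,
#' others) with piecewise-linear seasonal reflectance curves qualitatively
#' matching one-season cropland: maize and soybean show a strong NIR green-up
#' (>= 0.2 above their April value) peaking in July--August with depressed
#' red/SWIR, rice starts flooded with very low SWIR, and the non-crop
#' `others` class is nearly aseasonal (NIR range < 0.1). Knot values receive
#' a small seed-controlled perturbation (uniform within +/- 0.008) so that
#' different seeds give slightly different, invariant-preserving profiles.
#'
#' @param seed integer seed controlling the knot perturbations.
#' @param noiseSd per-band additive noise standard deviation used when pixels
#'   are simulated from the profile; recycled across the six bands.
#' @param nirSeparation multiplicative dial (>= 1) on the seasonal departure
#'   of each crop class's NIR curve from its April value (the aseasonal
#'   `others` class is left untouched); larger values increase the spectral
#'   contrast between classes.
#' @return Named list of four `PhenologyProfile` objects.
#' @export
#' @examples
#' pr <- defaultProfiles(seed = 0)
#' profileReflectance(pr$maize, "nir", c(100, 220))
defaultProfiles <- function(seed = 0L, noiseSd = 0.02, nirSeparation = 1) {
  stopifnot(nirSeparation >= 1)
  curves <- .baseCurves()
  sds <- rep_len(noiseSd, 6L)
  names(sds) <- phenoBands()
  withSeed(childSeed(seed, 11L), {
    out <- lapply(names(curves), function(cl) {
      bc <- curves[[cl]]
      bc <- lapply(bc, function(kn) {
        kn[, 2] <- pmin(1, pmax(0, kn[, 2] + runif(nrow(kn), -0.008, 0.008)))
        kn
      })
      if (nirSeparation != 1 && cl != "others") {
        kn <- bc[["nir"]]
        apr <- kn[1, 2]
        kn[, 2] <- pmin(1, pmax(0, apr + nirSeparation * (kn[, 2] - apr)))
        bc[["nir"]] <- kn
      }
      new("PhenologyProfile", classLabel = cl, bandCurves = bc[phenoBands()],
          noiseSd = sds, harvestDoy = unname(.harvestDoy[cl]))
    })
    names(out) <- names(curves)
    out
  })
}
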