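wholeSeason <- matrix(c(91, 334), 1, 2,
                      dimnames = list("all", c("start", "end")))

test_that("scene-level cloud screening keeps exactly the scenes under the
           threshold", {
  # 10 single-column scenes with cloud fractions 0.0, 0.1, ..., 0.9
  nr <- 10
  refl <- array(0.5, c(nr, 1, 6, 10))
  cloud <- array(FALSE, c(nr, 1, 6, 10))
  for (k in 1:10) if (k > 1) cloud[1:(k - 1), 1, , k] <- TRUE
  st <- makeStack(seq(100, by = 10, length.out = 10), refl, cloud)
  expect_equal(sceneCloudFraction(st), seq(0, 0.9, by = 0.1))

  kept <- dropCloudyScenes(st, 0.45, periods = wholeSeason)
  expect_equal(nScenes(kept), 5)
  expect_equal(sceneDates(kept), seq(100, 140, by = 10))
  # threshold 1 is the identity; threshold 0 keeps the one clean scene
  expect_identical(dropCloudyScenes(st, 1, periods = wholeSeason), st)
  expect_equal(nScenes(dropCloudyScenes(st, 0, periods = wholeSeason)), 1)
  # emptying a period errors
  expect_error(dropCloudyScenes(st, 0.45), "no scene survives")
})

test_that("cloud replacement takes the nearest clean date, earlier on ties", {
  refl <- array(0.5, c(1, 1, 6, 3))
  refl[1, 1, 4, ] <- c(0.30, 0.99, 0.32)     # NIR series
  cloud <- array(FALSE, c(1, 1, 6, 3))
  cloud[1, 1, 4, 2] <- TRUE                  # day 150 contaminated
  st <- makeStack(c(134, 150, 166), refl, cloud)
  out <- replaceCloudyBands(st)
  expect_equal(out@refl[1, 1, 4, 2], 0.30)   # tie 16 d both sides -> earlier
  expect_false(any(out@cloud))

  # asymmetric gap: nearest wins regardless of direction
  st2 <- makeStack(c(120, 150, 160), refl, cloud)
  expect_equal(replaceCloudyBands(st2)@refl[1, 1, 4, 2], 0.32)

  # a stack without flags is returned unchanged
  clean <- makeStack(c(134, 150, 166), refl)
  expect_identical(replaceCloudyBands(clean), clean)
})

test_that("a pixel cloudy at every date becomes invalid but the period
           composite falls back to other pixels' own clean dates", {
  refl <- array(0.2, c(2, 1, 6, 3))
  cloud <- array(FALSE, c(2, 1, 6, 3))
  cloud[1, 1, , ] <- TRUE                     # pixel 1: always cloudy
  st <- makeStack(c(100, 120, 140), refl, cloud)
  out <- replaceCloudyBands(st)
  expect_true(all(is.na(out@refl[1, 1, , ])))
  expect_true(all(out@refl[2, 1, , ] == 0.2))
  comp <- maxValueComposite(out, periods = wholeSeason)
  expect_true(all(is.na(comp@values[1, 1, , ])))
  expect_false(comp@valid[1, 1, 1])
  expect_true(comp@valid[2, 1, 1])
})

test_that("maximum-value composite equals the per-band maximum of valid
           observations", {
  # hand-traced toy: NIR observations {0.12, 0.30, 0.25} in one window
  refl <- array(0.1, c(1, 1, 6, 3))
  refl[1, 1, 4, ] <- c(0.12, 0.30, 0.25)
  st <- makeStack(c(160, 180, 200), refl)
  comp <- maxValueComposite(st, periods = matrix(c(152, 212), 1))
  expect_equal(comp@values[1, 1, 4, 1], 0.30)
  # single scene per period: composite equals that scene
  one <- makeStack(170, array(runif(6), c(1, 1, 6, 1)))
  comp1 <- maxValueComposite(one, periods = matrix(c(152, 212), 1))
  expect_equal(as.vector(comp1@values[1, 1, , 1]),
               as.vector(one@refl[1, 1, , 1]))
  # empty window errors
  expect_error(maxValueComposite(st, periods = matrix(c(274, 334), 1)),
               "no scenes")
})

test_that("composite matches brute-force enumeration on random toy stacks", {
  set.seed(42)
  periods <- defaultPeriods()
  for (i in 1:100) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    nd <- sample(4:8, 1)
    dates <- sort(sample(91:334, nd))
    # guarantee every period holds at least one date
    dates <- sort(unique(c(dates, c(100, 160, 220, 280))))
    st <- randomStack(nr, nc, dates, cloudProb = 0.3)
    # exercise the replacement path on half the cases
    if (i %% 2 == 0) st <- replaceCloudyBands(st)
    comp <- maxValueComposite(st, periods = periods)
    expect_equal(comp@values, bruteForceComposite(st, periods))
  }
})

test_that("adding a valid observation never decreases composite values", {
  set.seed(7)
  for (i in 1:20) {
    st <- randomStack(3, 3, c(100, 160, 220, 280), cloudProb = 0.2)
    comp <- maxValueComposite(st)
    extra <- array(runif(3 * 3 * 6), c(3, 3, 6, 1))
    refl2 <- array(c(st@refl, extra), c(3, 3, 6, 5))
    cloud2 <- array(c(st@cloud, array(FALSE, c(3, 3, 6, 1))),
                    c(3, 3, 6, 5))
    st2 <- makeStack(c(st@dates, 300), refl2, cloud2)
    comp2 <- maxValueComposite(st2)
    ok <- !is.na(comp@values)
    expect_true(all(comp2@values[ok] >= comp@values[ok]))
  }
})

test_that("compositing one scene per period is idempotent", {
  set.seed(8)
  st <- makeStack(c(100, 160, 220, 280),
                  array(runif(2 * 2 * 6 * 4), c(2, 2, 6, 4)))
  comp <- maxValueComposite(st)
  again <- maxValueComposite(makeStack(c(100, 160, 220, 280),
                                       comp@values))
  expect_equal(again@values, comp@values)
})

test_that("cloud handling restores the clean composite wherever a clean
           replacement exists", {
  set.seed(9)
  clean <- randomStack(4, 4, c(100, 120, 160, 180, 220, 240, 280, 300),
                       cloudProb = 0)
  # inject a bright cloud signature on flagged observations
  dirty <- clean
  flags <- array(runif(length(clean@refl)) < 0.3, dim(clean@refl))
  dirty@cloud <- flags
  dirty@refl[flags] <- 0.95
  naive <- maxValueComposite(makeStack(dirty@dates, dirty@refl))
  cleanComp <- maxValueComposite(clean)
  # the naive composite ignoring flags is visibly corrupted ...
  expect_gt(mean(naive@values), mean(cleanComp@values))
  # ... replacement within a single window only duplicates in-window clean
  # values, so the pipeline composite equals the clean composite restricted
  # to unflagged dates, exactly
  whole <- matrix(c(91, 334), 1, 2)
  restricted <- clean
  restricted@refl[flags] <- NA_real_
  expect_equal(maxValueComposite(replaceCloudyBands(dirty), whole)@values,
               maxValueComposite(restricted, whole)@values)
  # against the fully clean composite, the pipeline agrees wherever the
  # clean maximum happens to fall on an unflagged date (most cells here)
  piped <- maxValueComposite(replaceCloudyBands(dirty))
  agree <- mean(abs(piped@values - cleanComp@values) < 1e-12, na.rm = TRUE)
  expect_gt(agree, 0.7)
})

test_that("flattening is period-major and invertible", {
  comp <- maxValueComposite(makeStack(c(100, 160, 220, 280),
                                      array(0, c(2, 2, 6, 4))))
  comp@values[1, 1, 4, 2] <- 0.7              # period 2, NIR
  flat <- flattenFeatures(comp)
  expect_equal(ncol(flat), 24)
  expect_equal(unname(flat[1, (2 - 1) * 6 + 4]), 0.7) # 1-based element 10
  expect_equal(colnames(flat)[10], "p2_nir")
  expect_true(all(flat[, setdiff(1:24, 10)] == 0))
  # round trip
  arr <- unflattenFeatures(flat)
  for (p in 1:4)
    for (b in 1:6)
      expect_equal(arr[, p, b], as.vector(comp@values[, , b, p]))
  # invalid pixels flatten to NA rows
  comp@valid[2, 2, 3] <- FALSE
  flat2 <- flattenFeatures(comp)
  expect_true(all(is.na(flat2[4, ])))
})

test_that("spectral indices match their closed forms and mark undefined
           values", {
  # symmetric cases
  expect_equal(computeIndices(0.1, 0.3, 0.5, 0.5)$ndvi, 0)
  expect_equal(computeIndices(0.1, 0.4, 0.2, 0.4)$ndwi, 0)
  # hand-computed values
  idx <- computeIndices(blue = 0.04, green = 0.08, red = 0.1, nir = 0.5)
  expect_equal(idx$ndvi, 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(idx$evi, 2.5 * 0.4 / (0.5 + 0.6 - 0.3 + 1), tolerance = 1e-12)
  expect_equal(round(idx$ndvi, 4), 0.6667)
  expect_equal(round(idx$evi, 4), 0.5556)
  # zero denominators give NA, not an error
  z <- computeIndices(blue = 0, green = 0, red = 0, nir = 0)
  expect_true(is.na(z$ndvi) && is.na(z$ndwi))
  ze <- computeIndices(blue = 1 / 7.5 * (1 + 0.5 + 6 * 0.2) / 1,
                       green = 0.1, red = 0.2, nir = 0.5)
  expect_true(is.na(ze$evi))
})
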