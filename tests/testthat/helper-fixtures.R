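# Shared fixture builders. Everything is generated in code at test time.

# A toy SceneStack with full control over values and flags.
# refl/cloud: arrays [rows, cols, 6, nDates]; dates: doy vector.
makeStack <- function(dates, refl, cloud = NULL) {
  if (is.null(cloud)) cloud <- array(FALSE, dim(refl))
  new("SceneStack", dates = as.numeric(dates), refl = refl, cloud = cloud)
}

# Random small stack for oracle comparisons: values uniform, flags Bernoulli.
randomStack <- function(nr, nc, dates, cloudProb = 0.2) {
  nd <- length(dates)
  refl <- array(runif(nr * nc * 6 * nd), c(nr, nc, 6, nd))
  cloud <- array(runif(nr * nc * 6 * nd) < cloudProb, c(nr, nc, 6, nd))
  makeStack(dates, refl, cloud)
}

# Brute-force maximum-value composite: independent triple loop over
# (pixel, band, period), ignoring flagged and NA observations.
bruteForceComposite <- function(stack, periods) {
  d <- dim(stack@refl)
  np <- nrow(periods)
  vals <- array(NA_real_, c(d[1], d[2], d[3], np))
  for (r in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      for (b in seq_len(d[3]))
        for (p in seq_len(np)) {
          best <- NA_real_
          for (k in seq_len(d[4])) {
            if (stack@dates[k] < periods[p, 1] ||
                stack@dates[k] > periods[p, 2]) next
            if (stack@cloud[r, cc, b, k]) next
            v <- stack@refl[r, cc, b, k]
            if (is.na(v)) next
            if (is.na(best) || v > best) best <- v
          }
          vals[r, cc, b, p] <- best
        }
  vals
}

# Separable 4-class sequence fixture for classifier tests: one random
# prototype per class plus Gaussian noise, values kept in [0, 1].
makeSeparableSequences <- function(n, noise = 0.02, seed = 1) {
  set.seed(seed)
  proto <- array(runif(4 * 4 * 6, 0.1, 0.9), c(4, 4, 6))
  y <- rep(1:4, length.out = n)
  X <- array(0, c(n, 4, 6))
  for (i in seq_len(n))
    X[i, , ] <- pmin(1, pmax(0, proto[y[i], , ] + rnorm(24, 0, noise)))
  list(X = X, y = y)
}

# End-to-end synthetic experiment at a chosen scale: simulate, composite,
# train, predict, clean (cropland mask + minimum mapping unit), and score
# the final map on the held-out test samples. Used by acceptance and
# property tests.
runSyntheticExperiment <- function(seed, nPerClass = 400, epochs = 50,
                                   grid = c(64L, 64L), cloudProb = 0.05,
                                   centerLossWeight = -0.001,
                                   minPatchPx = 4L) {
  sc <- simScenario(gridShape = grid, cloudProb = cloudProb, seed = seed)
  sim <- simulateSceneStack(sc, defaultProfiles(seed))
  st <- replaceCloudyBands(dropCloudyScenes(sim$stack))
  comp <- maxValueComposite(st)
  samples <- simulateSamples(sim, sc, nPerClass = nPerClass)
  fl <- flattenFeatures(comp)
  idx <- (samples$col - 1L) * grid[1] + samples$row
  X <- unflattenFeatures(fl[idx, , drop = FALSE])
  y <- samples$class
  tr <- samples$split == "train"
  cfg <- classifierConfig(epochs = epochs, seed = seed,
                          centerLossWeight = centerLossWeight)
  model <- trainClassifier(buildClassifier(cfg), X[tr, , , drop = FALSE],
                           y[tr])
  map <- predictBinary(model, comp)
  map <- applyCroplandMask(map, sim$cropland)
  map <- removeSpeckle(map, minPatchPx)
  test <- samples[!tr, , drop = FALSE]
  mapPred <- map[cbind(test$row, test$col)]
  ok <- !is.na(mapPred)
  truthBin <- ifelse(test$class == "maize", "maize", "nonmaize")
  cm2 <- confusionCounts(truthBin[ok],
                         c("nonmaize", "maize")[mapPred[ok] + 1L],
                         classes = c("maize", "nonmaize"))
  met <- accuracyMetrics(cm2)
  list(model = model, sim = sim, composite = comp, samples = samples,
       map = map, testX = X[!tr, , , drop = FALSE], testY = y[!tr],
       oa = met$oa, maizeF1 = met$perClass$f1[1])
}

# Mean distance of features to their class mean (intraclass compactness).
meanIntraclassDistance <- function(feat, labels) {
  mean(vapply(unique(labels), function(j) {
    f <- feat[labels == j, , drop = FALSE]
    mu <- colMeans(f)
    mean(sqrt(rowSums((f - matrix(mu, nrow(f), ncol(f),
                                  byrow = TRUE))^2)))
  }, numeric(1)))
}
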